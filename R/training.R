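# Optimization: binary cross-entropy on the class head plus mean absolute
# error on the distance head, weighted 1:1, minimized with Adam. MAE (rather
# than MSE) keeps the small distances near region edges — the ones the
# watershed depends on — from being drowned out by the capped plateau.

#' Combined training loss
#'
#' `BCE(class_label, p) + MAE(dist_label, d_hat)` with equal weighting,
#' averaged over the batch. Probabilities are clamped to `[1e-7, 1 - 1e-7]`
#' for numerical safety.
#'
#' @param prob Predicted class probabilities.
#' @param dist_hat Predicted distances (raw head output).
#' @param class_label Binary labels (0/1).
#' @param dist_label Distance labels in `[0, d_max]`.
#' @return A list with `bce`, `mae` and `total` (all scalars).
#' @export
bb_loss <- function(prob, dist_hat, class_label, dist_label) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  bce <- mean(-class_label * log(p) - (1 - class_label) * log(1 - p))
  mae <- mean(abs(dist_hat - dist_label))
  list(bce = bce, mae = mae, total = bce + mae)
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

#' Train the network on a sample set
#'
#' Runs `epochs` passes over the drawn training pixels with Adam
#' (learning rate `params$learning_rate`, batch size `params$batch_size`),
#' reshuffling each epoch with the seeded RNG. When `params$augment` is on,
#' each presentation applies a uniformly drawn dihedral symmetry to the
#' patch stack (the class and distance labels are rotation/flip invariant).
#' One "training step" is one sample presentation, so the completed total is
#' `T = epochs * N`.
#'
#' @param net An untrained (or previously trained) `bb_network`.
#' @param stacks Feature matrix from [extract_stacks()] (one column per
#'   sample).
#' @param y_class Binary class labels, length `ncol(stacks)`.
#' @param y_dist Distance labels, length `ncol(stacks)`.
#' @param params A `bb_params` list.
#' @param seed RNG seed for shuffling/augmentation (default `params$seed`).
#' @param checkpoint_dir If non-`NULL`, weights are saved there after each
#'   completed epoch.
#' @return A list with `net` (trained) and `log` (data.frame with one row
#'   per optimizer update: `epoch`, `step` = presentations completed, `bce`,
#'   `mae`, `loss`).
#' @export
fit_network <- function(net, stacks, y_class, y_dist,
                        params = default_params(), seed = params$seed,
                        checkpoint_dir = NULL) {
  N <- ncol(stacks)
  if (is.null(N) || N == 0) stop("empty training stream")
  stopifnot(length(y_class) == N, length(y_dist) == N)
  spec <- net$spec
  set.seed(seed)
  state <- adam_init(net$weights)
  weights <- net$weights
  bs <- params$batch_size
  perms <- NULL
  if (isTRUE(params$augment)) {
    perms <- lapply(0:7, function(k)
      dihedral_row_perm(spec$patch_side, spec$n_channels, k))
  }
  log_rows <- vector("list", params$epochs * ceiling(N / bs))
  li <- 0L
  steps <- 0L
  for (epoch in seq_len(params$epochs)) {
    ord <- sample.int(N)
    kaug <- if (is.null(perms)) NULL else sample(0:7, N, replace = TRUE)
    for (start in seq(1, N, by = bs)) {
      idx <- ord[start:min(start + bs - 1, N)]
      Xb <- stacks[, idx, drop = FALSE]
      if (!is.null(perms)) {
        ks <- kaug[idx]
        for (k in unique(ks)) {
          if (k == 0) next
          sel <- which(ks == k)
          Xb[, sel] <- Xb[perms[[k + 1]], sel, drop = FALSE]
        }
      }
      r <- cpp_net_pass(weights, Xb, spec$patch_side, spec$n_channels,
                        spec$conv_widths[1], spec$conv_widths[2],
                        spec$conv_widths[3],
                        y_class[idx], y_dist[idx], TRUE)
      upd <- adam_step(weights, r$grads, state, params$learning_rate)
      weights <- upd$weights
      state <- upd$state
      steps <- steps + length(idx)
      li <- li + 1L
      log_rows[[li]] <- data.frame(epoch = epoch, step = steps,
                                   bce = r$bce, mae = r$mae,
                                   loss = r$bce + r$mae)
    }
    if (!is.null(checkpoint_dir)) {
      saveRDS(weights,
              file.path(checkpoint_dir, sprintf("weights_epoch%03d.rds", epoch)))
    }
  }
  net$weights <- weights
  net$trained <- TRUE
  net$provenance <- c(net$provenance,
                      list(train_seed = seed, n_samples = N,
                           presentations = steps, epochs = params$epochs))
  list(net = net, log = do.call(rbind, log_rows[seq_len(li)]))
}
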