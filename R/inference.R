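#' Training configuration for the dense networks
#'
#' Defaults follow the published architecture: 3 hidden layers of 32 relu
#' units; classifier head softmax over the 3 topologies, trained with
#' categorical cross-entropy for 1000 epochs at batch size 20000 with a 25\%
#' test split and 5\% validation split; regressor head a single rectified
#' unit trained with mean absolute percentage error for 3000 epochs at
#' batch size 10000 with a 0.1 validation split, averaged over 10
#' replicates. Reduce \code{epochs}/\code{n_sims}-scale settings for
#' desk-scale runs.
#'
#' @param hidden hidden layer sizes.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param test_split held-out test fraction.
#' @param validation_split validation fraction of the training data.
#' @param replicates regressor replicates averaged for prediction.
#' @return list of class \code{nn_config}.
#' @export
nn_config <- function(hidden = c(32, 32, 32), epochs = 1000,
                      batch_size = 20000, lr = 1e-3, test_split = 0.25,
                      validation_split = 0.05, replicates = 10) {
  structure(list(hidden = hidden, epochs = epochs, batch_size = batch_size,
                 lr = lr, test_split = test_split,
                 validation_split = validation_split,
                 replicates = replicates), class = "nn_config")
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  keep <- which(scl > 0 & is.finite(scl))
  list(center = ctr[keep], scale = scl[keep], keep = keep,
       dropped = colnames(X)[setdiff(seq_len(ncol(X)), keep)])
}

standardize_apply <- function(std, X) {
  X <- X[, std$keep, drop = FALSE]
  X <- sweep(X, 2L, std$center)
  sweep(X, 2L, std$scale, "/")
}

#' Train the topology classifier
#'
#' Dense softmax network mapping feature vectors to the 3-model simplex.
#' Features are z-scored with constants estimated from the training split
#' only; zero-variance features are dropped from both simulated and
#' observed vectors. Held-out accuracy and categorical cross-entropy are
#' reported on the test split.
#'
#' @param features numeric matrix, one simulated dataset per row.
#' @param labels topology labels (values 1..3), one per row; every class
#'   must be present in the training split.
#' @param cfg an \code{\link{nn_config}}.
#' @param seed optional integer; seeds the split and the weight
#'   initialization.
#' @return object of class \code{genarch_classifier}.
#' @export
train_classifier <- function(features, labels, cfg = nn_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 3L) stop("need all 3 topology classes")
  n <- nrow(features)
  test_idx <- sample.int(n, round(cfg$test_split * n))
  train_idx <- setdiff(seq_len(n), test_idx)
  if (!all(classes %in% labels[train_idx]))
    stop("a class is absent from the training split")
  std <- standardize_fit(features[train_idx, , drop = FALSE])
  Xtr <- standardize_apply(std, features[train_idx, , drop = FALSE])
  Xte <- standardize_apply(std, features[test_idx, , drop = FALSE])
  Y <- matrix(0, length(train_idx), length(classes))
  Y[cbind(seq_along(train_idx), match(labels[train_idx], classes))] <- 1
  net <- mlp_train(Xtr, Y, head = "softmax", hidden = cfg$hidden,
                   epochs = cfg$epochs,
                   batch_size = min(cfg$batch_size, nrow(Xtr)), lr = cfg$lr)
  p <- mlp_predict(net, Xte)
  pred <- classes[apply(p, 1L, which.max)]
  acc <- mean(pred == labels[test_idx])
  ce <- -mean(log(pmax(p[cbind(seq_len(nrow(p)),
                               match(labels[test_idx], classes))], 1e-12)))
  structure(list(net = net, std = std, classes = classes, cfg = cfg,
                 metrics = list(test_accuracy = acc, cross_entropy = ce,
                                n_train = length(train_idx),
                                n_test = length(test_idx))),
            class = "genarch_classifier")
}

#' @exportS3Method base::print
print.genarch_classifier <- function(x, ...) {
  cat(sprintf(
    "genarch_classifier: %d features -> %s -> %d classes\n",
    length(x$std$keep), paste(x$cfg$hidden, collapse = "-"),
    length(x$classes)))
  cat(sprintf("  held-out accuracy %.4f, cross-entropy %.4f (n_test = %d)\n",
              x$metrics$test_accuracy, x$metrics$cross_entropy,
              x$metrics$n_test))
  invisible(x)
}

#' @exportS3Method base::summary
summary.genarch_classifier <- function(object, ...) {
  c(object$metrics, list(classes = object$classes,
                         dropped_features = object$std$dropped))
}

#' Classify observed feature vectors
#'
#' @param model a \code{\link{train_classifier}} fit.
#' @param obs a feature vector or matrix (same feature order as training).
#' @return matrix of class probabilities (rows sum to 1), columns named by
#'   topology.
#' @export
classify <- function(model, obs) {
  stopifnot(inherits(model, "genarch_classifier"))
  if (is.null(dim(obs))) obs <- matrix(obs, 1L,
                                       dimnames = list(NULL, names(obs)))
  if (ncol(obs) < max(model$std$keep)) stop("feature length mismatch")
  p <- mlp_predict(model$net, standardize_apply(model$std, as.matrix(obs)))
  colnames(p) <- paste0("topology", model$classes)
  p
}

#' @export
predict.genarch_classifier <- function(object, newdata, ...) {
  classify(object, newdata)
}

#' Train a parameter regressor
#'
#' Dense network with a single rectified output, trained with mean absolute
#' percentage error on a strictly positive target. The target is scaled by
#' its training mean (undone at prediction); features are z-scored from the
#' training split. Training runs \code{cfg$replicates} independently seeded
#' replicates; the prediction is the replicate mean. Held-out R-squared,
#' MAPE and MAE are reported.
#'
#' @param features numeric matrix of simulated feature vectors.
#' @param target positive numeric vector of generating parameter values.
#' @param cfg an \code{\link{nn_config}}.
#' @param seed optional integer seed (split + replicate initializations).
#' @return object of class \code{genarch_regressor}.
#' @export
train_regressor <- function(features, target, cfg = nn_config(epochs = 3000,
                                                              batch_size = 10000,
                                                              validation_split = 0.1),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(target <= 0))
    stop("rectified output requires positive targets; transform first")
  features <- as.matrix(features)
  n <- nrow(features)
  test_idx <- sample.int(n, round(cfg$test_split * n))
  train_idx <- setdiff(seq_len(n), test_idx)
  std <- standardize_fit(features[train_idx, , drop = FALSE])
  Xtr <- standardize_apply(std, features[train_idx, , drop = FALSE])
  Xte <- standardize_apply(std, features[test_idx, , drop = FALSE])
  y_scale <- mean(target[train_idx])
  Ytr <- matrix(target[train_idx] / y_scale, ncol = 1L)
  nets <- lapply(seq_len(cfg$replicates), function(rep)
    mlp_train(Xtr, Ytr, head = "relu", hidden = cfg$hidden,
              epochs = cfg$epochs,
              batch_size = min(cfg$batch_size, nrow(Xtr)), lr = cfg$lr))
  pred_all <- vapply(nets, function(nt) mlp_predict(nt, Xte)[, 1L],
                     numeric(nrow(Xte)))
  if (is.null(dim(pred_all))) pred_all <- matrix(pred_all, nrow = nrow(Xte))
  pred <- rowMeans(pred_all) * y_scale
  truth <- target[test_idx]
  r2 <- if (sd(truth) > 0 && sd(pred) > 0) cor(pred, truth)^2 else NA_real_
  mape <- mean(abs(truth - pred) / truth)
  mae <- mean(abs(truth - pred))
  structure(list(nets = nets, std = std, y_scale = y_scale, cfg = cfg,
                 metrics = list(test_r2 = r2, mape = mape, mae = mae,
                                n_test = length(test_idx))),
            class = "genarch_regressor")
}

#' @exportS3Method base::print
print.genarch_regressor <- function(x, ...) {
  cat(sprintf(
    "genarch_regressor: %d features -> %s -> 1 (%d replicates)\n",
    length(x$std$keep), paste(x$cfg$hidden, collapse = "-"),
    length(x$nets)))
  cat(sprintf("  held-out R2 %.3f, MAPE %.3f, MAE %.4g\n",
              x$metrics$test_r2, x$metrics$mape, x$metrics$mae))
  invisible(x)
}

#' @export
predict.genarch_regressor <- function(object, newdata, ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, 1L, dimnames = list(NULL, names(newdata)))
  X <- standardize_apply(object$std, as.matrix(newdata))
  preds <- vapply(object$nets, function(nt) mlp_predict(nt, X)[, 1L],
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  rowMeans(preds) * object$y_scale
}

#' Goodness of fit of simulations to an observed feature vector
#'
#' Test statistic: the median distance from the observed vector to its
#' \code{k} nearest simulated vectors in standardized feature space. The
#' null distribution re-computes the statistic for \code{n_null} held-out
#' simulated vectors against the remaining simulations; the p-value is the
#' fraction of null statistics at least as large as the observed one. Also
#' returns the first 4 principal components of the simulations with the
#' observation projected in, for overlay plots.
#'
#' @param sims matrix of simulated feature vectors (>= 100 rows).
#' @param obs observed feature vector.
#' @param n_null null replicates (default 200).
#' @param k nearest neighbours (default 10).
#' @return list with \code{p_value, stat_obs, stat_null, pca_sims,
#'   pca_obs}.
#' @export
goodness_of_fit <- function(sims, obs, n_null = 200, k = 10) {
  sims <- as.matrix(sims)
  if (nrow(sims) < 100L) stop("need at least 100 simulations")
  std <- standardize_fit(sims)
  Z <- standardize_apply(std, sims)
  zo <- standardize_apply(std, matrix(obs, 1L))
  knn_stat <- function(point, ref) {
    d2 <- sqrt(colSums((t(ref) - as.numeric(point))^2))
    median(sort(d2)[seq_len(k)])
  }
  stat_obs <- knn_stat(zo, Z)
  null_idx <- sample.int(nrow(Z), min(n_null, nrow(Z) %/% 2L))
  stat_null <- vapply(null_idx, function(i)
    knn_stat(Z[i, , drop = FALSE], Z[-i, , drop = FALSE]), numeric(1))
  pca <- prcomp(Z, rank. = 4L)
  list(p_value = mean(stat_null >= stat_obs), stat_obs = stat_obs,
       stat_null = stat_null, pca_sims = pca$x,
       pca_obs = predict(pca, zo))
}

#' Selection-class-stratified parameter estimates
#'
#' Applies trained single-window regressors to subsets of windows assigned
#' with high probability to each selection class, reporting the per-class
#' mean estimate with a bootstrap standard error. Classes larger than
#' \code{cap} windows are subsampled (seeded by the caller's RNG state);
#' empty classes yield NA rows rather than errors.
#'
#' @param window_features matrix of single-window feature vectors (one row
#'   per window).
#' @param class_track data frame with one probability column per class in
#'   \code{hard, linked_hard, soft, linked_soft, neutral}, one row per
#'   window.
#' @param regressors named list of \code{\link{train_regressor}} fits (one
#'   per parameter).
#' @param threshold assignment probability threshold (default 0.7, strict).
#' @param cap maximum windows per class (default 1000).
#' @param n_boot bootstrap resamples (default 200).
#' @return data frame: class, parameter, n windows used, estimate,
#'   bootstrap SE.
#' @export
stratified_estimates <- function(window_features, class_track, regressors,
                                 threshold = 0.7, cap = 1000, n_boot = 200) {
  p <- as.matrix(class_track[, CLASSES5, drop = FALSE])
  conf <- apply(p, 1L, max) > threshold
  assigned <- CLASSES5[apply(p, 1L, which.max)]
  rows <- list()
  for (cls in CLASSES5) {
    idx <- which(conf & assigned == cls)
    if (length(idx) > cap) idx <- sort(sample(idx, cap))
    for (par in names(regressors)) {
      if (!length(idx)) {
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, parameter = par, n = 0L, estimate = NA_real_,
          se = NA_real_)
        next
      }
      est_w <- predict(regressors[[par]],
                       window_features[idx, , drop = FALSE])
      boots <- vapply(seq_len(n_boot), function(b)
        mean(est_w[sample.int(length(est_w), replace = TRUE)]), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, parameter = par, n = length(idx),
        estimate = mean(est_w), se = sd(boots))
    }
  }
  do.call(rbind, rows)
}
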