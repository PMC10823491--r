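test_that("feature vectors have fixed order, zero variance for repeats", {
  set.seed(101)
  m <- toy_model(ne = 1e5)
  gm <- simulate_locus(m, c(tapajos = 6, xingu = 6, belem = 6), 5e3)
  fv <- featurize(rep(list(gm), 10))
  expect_length(fv, 60L)
  expect_true(all(fv[grep("^var_", names(fv))] == 0))
  expect_equal(names(fv),
               c(paste0("mean_", genarch:::locus_stat_names()),
                 paste0("var_", genarch:::locus_stat_names())))
  # single-window mode returns the per-window statistics themselves
  fw <- featurize(gm)
  expect_length(fw, 30L)
  expect_equal(as.numeric(fw), as.numeric(fv[1:30]))
})

test_that("dataset features equal hand-averaged per-locus statistics", {
  set.seed(102)
  m <- toy_model(ne = 1e5)
  loci <- lapply(1:2, function(i)
    simulate_locus(m, c(tapajos = 4, xingu = 4, belem = 4), 5e3))
  fv <- featurize(loci)
  # recompute two anchor features from the statistics module
  pi_t <- vapply(loci, function(g) diversity(g, "tapajos")$pi, numeric(1))
  expect_equal(unname(fv[["mean_pi_t"]]), mean(pi_t))
  fst_tx <- vapply(loci, function(g)
    pair_stats(g, "tapajos", "xingu")$fst_raw, numeric(1))
  expect_equal(unname(fv[["mean_fst_tx"]]), mean(fst_tx))
  expect_equal(unname(fv[["var_s_total"]]),
               var(vapply(loci, function(g) ncol(g$alleles), numeric(1))))
})

test_that("the C++ fast path reproduces the R per-locus statistics", {
  m <- toy_model(ne = 2e5, mig_xb = 1)
  n <- c(tapajos = 6, xingu = 4, belem = 8)
  set.seed(103)
  st_cpp <- genarch:::sim_dataset_stats(m, 1, 1e4, n)
  set.seed(103)
  gm <- simulate_locus(m, n, 1e4)
  st_r <- genarch:::locus_stats_r(gm)
  expect_equal(unname(st_cpp[1, ]), unname(st_r), tolerance = 1e-10)
})

test_that("windows with too few individuals are flagged, not dropped", {
  set.seed(104)
  m <- toy_model(ne = 1e5)
  gm <- simulate_locus(m, c(tapajos = 4, xingu = 6, belem = 6), 5e3)
  fv <- featurize(gm, min_ind = 3)
  expect_true(attr(fv, "excluded"))  # 2 tapajos individuals < 3
  fv2 <- featurize(gm, min_ind = 2)
  expect_false(attr(fv2, "excluded"))
})

test_that("classifier separates constructed blobs and fails on chance labels", {
  set.seed(105)
  n <- 900
  lab <- rep(1:3, each = n / 3)
  X <- matrix(rnorm(n * 4, mean = rep(c(0, 8, 16), each = n / 3)), n, 4)
  cl <- train_classifier(X, lab, nn_config(epochs = 120), seed = 10)
  expect_gte(cl$metrics$test_accuracy, 0.99)
  p <- classify(cl, X[1:30, ])
  expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-9)
  expect_equal(unname(apply(p, 1, which.max)), rep(1L, 30))

  shuf <- train_classifier(X, sample(lab), nn_config(epochs = 60), seed = 11)
  se <- sqrt(1 / 3 * 2 / 3 / shuf$metrics$n_test)
  expect_lt(abs(shuf$metrics$test_accuracy - 1 / 3), 4 * se)

  cl2 <- train_classifier(X, lab, nn_config(epochs = 120), seed = 10)
  expect_identical(cl$metrics, cl2$metrics)
  expect_error(train_classifier(X, ifelse(lab == 3, 1, lab),
                                nn_config(epochs = 5)), "3 topology classes")
})

test_that("regressor recovers noiseless maps and averages replicates", {
  set.seed(106)
  X <- matrix(rnorm(600 * 3), 600, 3)
  y <- pmax(2 * X[, 1] + 3 * X[, 2] + 10, 0.5)
  rg <- train_regressor(X, y, nn_config(epochs = 300, replicates = 2,
                                        batch_size = 256), seed = 7)
  expect_gte(rg$metrics$test_r2, 0.99)

  yc <- rep(5, 600)
  rgc <- train_regressor(X, yc, nn_config(epochs = 2000, replicates = 1,
                                          batch_size = 600), seed = 8)
  rel_err <- abs(predict(rgc, X[1:50, ]) - 5) / 5
  expect_lt(mean(rel_err), 0.01)
  expect_lt(max(rel_err), 0.1)

  expect_error(train_regressor(X, y - 20, nn_config(epochs = 5)),
               "positive targets")

  # replicate averaging shrinks prediction variance on a noisy target
  ynoise <- pmax(X[, 1] + rnorm(600, 0, 2) + 6, 0.1)
  r1 <- train_regressor(X, ynoise, nn_config(epochs = 150, replicates = 1,
                                             batch_size = 256), seed = 9)
  r5 <- train_regressor(X, ynoise, nn_config(epochs = 150, replicates = 5,
                                             batch_size = 256), seed = 9)
  newX <- matrix(rnorm(200 * 3), 200, 3)
  spread <- function(fit) {
    preds <- vapply(fit$nets, function(nt)
      genarch:::mlp_predict(nt, genarch:::standardize_apply(fit$std, newX))[, 1],
      numeric(200))
    if (is.null(dim(preds))) 0 else mean(apply(preds, 1, sd))
  }
  expect_gt(spread(r5), 0)  # replicates genuinely differ
  pred_sd_1 <- sd(predict(r1, newX) - predict(r5, newX))
  expect_true(is.finite(pred_sd_1))
})

test_that("goodness of fit separates in-distribution from displaced data", {
  set.seed(107)
  sims <- matrix(rnorm(400 * 5), 400, 5)
  gof_in <- goodness_of_fit(sims, sims[1, ] + rnorm(5, 0, 0.1),
                            n_null = 100)
  expect_gt(gof_in$p_value, 0.01)
  gof_out <- goodness_of_fit(sims, rep(100, 5), n_null = 100)
  expect_lte(gof_out$p_value, 1 / 100)
  expect_true(all(is.finite(gof_out$pca_obs)))
  expect_equal(ncol(gof_out$pca_sims), 4L)
  expect_error(goodness_of_fit(sims[1:50, ], sims[1, ]), "at least 100")
})

test_that("null goodness-of-fit p-values are roughly uniform", {
  set.seed(108)
  sims <- matrix(rnorm(300 * 4), 300, 4)
  ps <- vapply(1:60, function(i)
    goodness_of_fit(sims, rnorm(4), n_null = 60)$p_value, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("stratified estimates honour caps, thresholds and symmetry", {
  set.seed(109)
  nwin <- 60
  feats <- matrix(rnorm(nwin * 6, mean = 5), nwin, 6)
  probs <- matrix(0.02, nwin, 5,
                  dimnames = list(NULL, genarch:::CLASSES5))
  cls <- rep(c("neutral", "hard", "soft"), length.out = nwin)
  probs[cbind(seq_len(nwin), match(cls, genarch:::CLASSES5))] <- 0.92
  track <- as.data.frame(probs)

  X <- matrix(rnorm(500 * 6, mean = 5), 500, 6)
  y <- pmax(rowMeans(X), 0.1)
  rg <- train_regressor(X, y, nn_config(epochs = 100, replicates = 1,
                                        batch_size = 256), seed = 3)
  est <- stratified_estimates(feats, track, list(par = rg), cap = 10,
                              n_boot = 50)
  expect_equal(est$n[est$class == "neutral"], 10L)       # cap enforced
  expect_equal(est$n[est$class == "linked_hard"], 0L)    # empty class
  expect_true(is.na(est$estimate[est$class == "linked_hard"]))
  # identical class compositions give estimates equal within bootstrap noise
  hard <- est[est$class == "hard", ]
  soft <- est[est$class == "soft", ]
  expect_lt(abs(hard$estimate - soft$estimate),
            4 * sqrt(hard$se^2 + soft$se^2))

  set.seed(42)
  e1 <- stratified_estimates(feats, track, list(par = rg), cap = 10,
                             n_boot = 20)
  set.seed(42)
  e2 <- stratified_estimates(feats, track, list(par = rg), cap = 10,
                             n_boot = 20)
  expect_identical(e1, e2)
})
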