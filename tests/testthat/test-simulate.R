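test_that("prior draws respect bounds, moments and determinism", {
  degenerate <- prior_set(ne_tapajos = c(1e5, 1e5), t_recent = c(2e5, 2e5))
  set.seed(1)
  m <- sample_prior(degenerate)
  expect_equal(unname(m$ne[["tapajos"]]), 1e5)
  expect_equal(m$t_recent, 2e5)

  pri <- prior_set(ne_tapajos = c(1e4, 1e6))
  set.seed(2)
  draws <- replicate(1000, sample_prior(pri)$ne[["tapajos"]])
  expect_gte(min(draws), 1e4)
  expect_lte(max(draws), 1e6)
  se <- sqrt((1e6 - 1e4)^2 / 12 / 1000)
  expect_lt(abs(mean(draws) - 5.05e5), 3 * se)

  set.seed(99)
  a <- sample_prior(pri)
  set.seed(99)
  b <- sample_prior(pri)
  expect_identical(a, b)

  expect_error(prior_set(ne_tapajos = c(2, 1)), "lo > hi")
})

test_that("pairwise TMRCA matches 2N under a constant-size history", {
  m <- toy_model(ne = 1e4)
  set.seed(3)
  tm <- replicate(2000, {
    tr <- simulate_genealogy(m, c(tapajos = 2))
    max(ape::node.depth.edgelength(tr))
  })
  expect_lt(abs(mean(tm) - 2e4), 3 * sd(tm) / sqrt(2000))
})

test_that("with no migration, cross-population coalescence waits for the merge", {
  m <- toy_model(ne = 5e4, t_deep = 4e5)
  set.seed(4)
  for (rep in 1:20) {
    tr <- simulate_genealogy(m, c(tapajos = 3, belem = 3))
    tmrca <- ape::cophenetic.phylo(tr) / 2
    cross <- tmrca[grep("tapajos", rownames(tmrca)),
                   grep("belem", colnames(tmrca))]
    expect_true(all(cross > m$t_deep))
  }
})

test_that("migration permits cross-deme coalescence before the split", {
  set.seed(5)
  frac_before <- function(mig) {
    m <- toy_model(ne = 5e4, mig_tx = mig, t_recent = 1e6, t_deep = 2e6)
    mean(replicate(150, {
      tr <- simulate_genealogy(m, c(tapajos = 2, xingu = 2))
      tmrca <- ape::cophenetic.phylo(tr) / 2
      cross <- tmrca[grep("tapajos", rownames(tmrca)),
                     grep("xingu", colnames(tmrca))]
      any(cross < 1e6)
    }))
  }
  expect_equal(frac_before(0), 0)
  expect_gt(frac_before(1), 0.2)
})

test_that("mutation dropping matches theta and infinite-sites invariants", {
  m <- toy_model(ne = 1e4)
  set.seed(6)
  tr <- simulate_genealogy(m, c(tapajos = 6))
  gm0 <- drop_mutations(tr, 0, 1e4)
  expect_equal(ncol(gm0$alleles), 0L)

  diffs <- replicate(2000, {
    tr <- simulate_genealogy(m, c(tapajos = 2))
    gm <- drop_mutations(tr, 1e-8, 1e4)
    expect_false(any(duplicated(gm$positions)))
    ncol(gm$alleles)
  })
  expected <- 4 * 1e4 * 1e-8 * 1e4
  expect_lt(abs(mean(diffs) - expected), 3 * sd(diffs) / sqrt(2000))
})

test_that("r = 0 loci pass the four-gamete test; seeds reproduce exactly", {
  m <- toy_model(ne = 2e5)
  set.seed(7)
  gm <- simulate_locus(m, c(tapajos = 6, xingu = 6, belem = 6), 1e4)
  al <- gm$alleles
  S <- ncol(al)
  expect_gt(S, 10)
  for (s1 in seq_len(min(S, 40) - 1)) for (s2 in (s1 + 1):min(S, 40)) {
    gam <- unique(paste(al[, s1], al[, s2]))
    expect_lt(length(gam), 4L)
  }
  set.seed(123)
  a <- simulate_locus(m, c(tapajos = 4), 1e4)
  set.seed(123)
  b <- simulate_locus(m, c(tapajos = 4), 1e4)
  expect_identical(a, b)
})

test_that("linkage decays with distance under intralocus recombination", {
  m <- toy_model(ne = 1e5, r = 1e-8)
  set.seed(8)
  near <- far <- c()
  for (rep in 1:120) {
    gm <- simulate_locus(m, c(tapajos = 12), 2e4, with_recombination = TRUE)
    al <- gm$alleles
    pos <- gm$positions
    freq <- colMeans(al)
    use <- freq > 0.1 & freq < 0.9
    al <- al[, use, drop = FALSE]
    pos <- pos[use]
    if (ncol(al) < 4) next
    r2 <- suppressWarnings(cor(al))^2
    dmat <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(r2)
    near <- c(near, r2[ut & dmat < 1e3])
    far <- c(far, r2[ut & dmat > 1e4])
  }
  expect_gt(mean(near, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("datasets carry consistent labels and truth records", {
  m <- toy_model()
  set.seed(9)
  ds <- simulate_dataset(m, 3, 5e3, c(tapajos = 4, xingu = 4, belem = 4))
  expect_length(ds$loci, 3L)
  for (gm in ds$loci)
    expect_equal(table(gm$pops), table(ds$loci[[1]]$pops))
  expect_equal(ds$truth$topology, 1)
})

test_that("deeper splits give larger cross-population Dxy; topology is honoured", {
  set.seed(10)
  n <- c(tapajos = 6, xingu = 6, belem = 6)
  mean_dxy <- function(topology) {
    m <- toy_model(topology, ne = 1e5, t_recent = 1e5, t_deep = 1.2e6)
    st <- genarch:::sim_dataset_stats(m, 150, 1e4, n)
    # pair order: tx, tb, xb -> return named means of between-pop pi proxies
    colMeans(st[, c("fst_tx", "fst_tb", "fst_xb")])
  }
  f1 <- mean_dxy(1)  # tapajos-xingu sister: tx least differentiated
  expect_lt(f1[["fst_tx"]], f1[["fst_tb"]])
  expect_lt(f1[["fst_tx"]], f1[["fst_xb"]])
  f2 <- mean_dxy(2)  # xingu-belem sister
  expect_lt(f2[["fst_xb"]], f2[["fst_tb"]])
  expect_lt(f2[["fst_xb"]], f2[["fst_tx"]])
})

test_that("suppressed landscape classes lose diversity; tracks round-trip", {
  base <- toy_model(ne = 2e5)
  cfg <- landscape_config(60, 1e4, base,
                          class_of_window = rep(c("neutral", "hard"), 30),
                          suppression = c(hard = 0.1, linked_hard = 0.3,
                                          soft = 0.3, linked_soft = 0.6,
                                          neutral = 1))
  set.seed(11)
  ls <- generate_landscape(cfg, c(tapajos = 8, xingu = 4, belem = 4))
  pi_w <- vapply(ls$windows, function(w) diversity(w, "tapajos")$pi,
                 numeric(1))
  neutral <- pi_w[ls$truth == "neutral"]
  hard <- pi_w[ls$truth == "hard"]
  expect_lt(wilcox.test(hard, neutral, alternative = "less", exact = FALSE)$p.value, 0.01)

  f <- tempfile(fileext = ".tsv")
  write_track(ls$class_track, f)
  back <- read_track(f)
  expect_equal(back$value, ls$class_track$value)
  expect_equal(back$assigned_class, ls$class_track$assigned_class)

  # all multipliers 1: no systematic class difference
  cfg1 <- landscape_config(40, 1e4, base,
                           class_of_window = rep(c("neutral", "hard"), 20),
                           suppression = c(hard = 1, linked_hard = 1,
                                           soft = 1, linked_soft = 1,
                                           neutral = 1))
  ls1 <- generate_landscape(cfg1, c(tapajos = 8, xingu = 4, belem = 4))
  pi1 <- vapply(ls1$windows, function(w) diversity(w, "tapajos")$pi,
                numeric(1))
  expect_gt(wilcox.test(pi1[ls1$truth == "hard"],
                        pi1[ls1$truth == "neutral"], exact = FALSE)$p.value, 0.01)
})

test_that("directional migration accepts 4-rate parameterizations", {
  m <- demographic_model(
    1, ne = c(tapajos = 1e5, xingu = 1e5, belem = 1e5, anc_recent = 1e5,
              anc_deep = 1e5, outgroup = 1e5),
    t_recent = 1e5, t_deep = 5e5,
    mig = c(tapajos_from_xingu = 1, xingu_from_tapajos = 0,
            xingu_from_belem = 2, belem_from_xingu = 0))
  set.seed(12)
  gm <- simulate_locus(m, c(tapajos = 4, xingu = 4, belem = 4), 5e3)
  expect_s3_class(gm, "genotype_matrix")
  expect_error(demographic_model(
    1, ne = c(tapajos = 1, xingu = 1, belem = 1, anc_recent = 1,
              anc_deep = 1, outgroup = 1),
    t_recent = 1, t_deep = 2, mig = c(a = 1, b = 2, c = 3)), "directional")
})
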