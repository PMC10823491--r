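test_that("SNP windows hold exactly n qualifying SNPs and drop the remainder", {
  set.seed(71)
  gm <- random_gm(n_hap = 10, S = 25, L = 5000, miss = 0)
  win <- snp_windows(gm, 10)
  expect_equal(nrow(win), 2L)  # floor(25 / 10)
  expect_equal(win$n_sites, c(10L, 10L))
  # spans match first/last SNP positions
  expect_equal(win$start[1], gm$positions[1] - 1L)
  expect_equal(win$end[1], gm$positions[10])
  expect_equal(win$end[2], gm$positions[20])

  # a SNP above the missingness bound does not count toward n_snps
  al <- gm$alleles
  al[1:6, 3] <- NA_integer_  # 60% missing at site 3
  gm2 <- genotype_matrix(al, gm$positions, gm$seq_length, gm$pops)
  win2 <- snp_windows(gm2, 10, max_missing = 0.3)
  expect_equal(win2$site_index[[1]], setdiff(1:11, 3L))
})

test_that("fixed windows tile the chromosome and flag sparse windows", {
  set.seed(72)
  gm <- random_gm(n_hap = 6, S = 30, L = 3e5, miss = 0)
  win <- fixed_windows(gm, 1e5, min_sites = 500)
  expect_equal(nrow(win), 3L)
  expect_equal(win$end - win$start, rep(1e5, 3))
  expect_true(all(win$ok))

  # boundary: a window with exactly min_sites - 1 callable sites is missing
  al <- matrix(NA_integer_, 4, 999)
  al[1, ] <- 0L  # 1 called haplotype everywhere: all SNP columns skipped
  gm2 <- genotype_matrix(al, 1:999, 1000, rep("popA", 4))
  win2 <- fixed_windows(gm2, 1000, min_sites = 500)
  expect_equal(win2$n_sites, 1L)  # only the invariant base at position 1000
  expect_false(win2$ok)

  # callable counts match a brute-force recount
  set.seed(73)
  gm3 <- random_gm(n_hap = 8, S = 40, L = 2e3, miss = 0.5)
  win3 <- fixed_windows(gm3, 1e3, min_sites = 1)
  for (i in seq_len(nrow(win3))) {
    inw <- which(gm3$positions > win3$start[i] & gm3$positions <= win3$end[i])
    skipped <- sum(vapply(inw, function(s)
      sum(!is.na(gm3$alleles[, s])) < 2L, logical(1)))
    expect_equal(win3$n_sites[i], 1e3 - skipped)
  }
})

test_that("weighted regridding averages by overlap and conserves the mean", {
  tr <- window_track("c1", c(0, 40000), c(40000, 100000), value = c(1, 2))
  rg <- regrid_weighted(tr, 1e5)
  expect_equal(rg$value, 0.4 * 1 + 0.6 * 2)

  # constant tracks stay constant on any grid
  tr2 <- window_track("c1", seq(0, 90000, 1e4), seq(1e4, 1e5, 1e4), value = 7)
  expect_true(all(regrid_weighted(tr2, 25000)$value == 7))

  # cells with no overlap are missing
  tr3 <- window_track("c1", 0, 1e4, value = 3)
  rg3 <- regrid_weighted(tr3, 1e4, chrom_length = 3e4)
  expect_equal(rg3$value, c(3, NA, NA))

  # conservation of the global length-weighted mean
  set.seed(74)
  starts <- cumsum(c(0, sample(5e3:2e4, 20)))
  gaps <- diff(starts)
  lens <- pmax(1e3, round(gaps * runif(20, 0.3, 0.9)))
  tr4 <- window_track("c1", starts[-21], starts[-21] + lens,
                      value = rnorm(20))
  rg4 <- regrid_weighted(tr4, 3e4)
  w_in <- tr4$end - tr4$start
  w_out <- rg4$n_sites
  expect_equal(sum(tr4$value * w_in) / sum(w_in),
               sum(rg4$value * w_out, na.rm = TRUE) / sum(w_out),
               tolerance = 1e-10)

  over <- window_track("c1", c(0, 500), c(1000, 1500), value = 1)
  expect_error(regrid_weighted(over, 1e3), "overlap")
})

test_that("quantile subsets pick the right tails with genomic tie-breaks", {
  set.seed(75)
  tr <- window_track("c1", (0:99) * 1e3, (1:100) * 1e3, value = sample(100))
  up <- quantile_subset(tr, 0.1, "upper")
  expect_equal(sort(up$value), 91:100)
  lo <- quantile_subset(tr, 0.1, "lower")
  expect_equal(sort(lo$value), 1:10)
  expect_length(intersect(rownames(up), rownames(lo)), 0L)

  # full sort oracle under missing values
  tr$value[sample(100, 20)] <- NA
  up2 <- quantile_subset(tr, 0.25, "upper")
  k <- ceiling(0.25 * sum(!is.na(tr$value)))
  expect_equal(sort(up2$value, decreasing = TRUE),
               sort(tr$value[!is.na(tr$value)], decreasing = TRUE)[1:k])

  # ties broken by genomic order
  tr2 <- window_track("c1", (0:9) * 1e3, (1:10) * 1e3, value = 5)
  sel <- quantile_subset(tr2, 0.3, "upper")
  expect_equal(sel$start, c(0, 1000, 2000))

  allna <- window_track("c1", 0, 1e3, value = NA_real_)
  expect_error(quantile_subset(allna, 0.1), "missing")
})

test_that("selection summaries threshold strictly and average species", {
  mk_track <- function(frac_nonneutral, n = 10000) {
    n_nn <- round(frac_nonneutral * n)
    cls <- c(rep("hard", n_nn), rep("neutral", n - n_nn))
    p <- matrix(0.02, n, 5, dimnames = list(NULL, genarch:::CLASSES5))
    p[cbind(seq_len(n), match(cls, genarch:::CLASSES5))] <- 0.92
    as.data.frame(p)
  }
  tracks <- list(a = mk_track(0.3029), b = mk_track(0.4483),
                 c = mk_track(0.5477))
  sm <- selection_summary(tracks)
  expect_equal(sm$prop_nonneutral[sm$species == "mean"],
               mean(c(30.29, 44.83, 54.77)), tolerance = 1e-10)

  # max probability exactly at the threshold -> not confident
  p <- matrix(c(0.7, 0.1, 0.1, 0.05, 0.05), 1,
              dimnames = list(NULL, genarch:::CLASSES5))
  sm2 <- selection_summary(list(sp = as.data.frame(p)), threshold = 0.7)
  expect_equal(sm2$prop_confident[1], 0)

  # all neutral with probability 1 -> nonneutral fraction 0
  p3 <- matrix(0, 5, 5, dimnames = list(NULL, genarch:::CLASSES5))
  p3[, "neutral"] <- 1
  sm3 <- selection_summary(list(sp = as.data.frame(p3)))
  expect_equal(sm3$prop_nonneutral[1], 0)

  # FPR adjustment multiplies the nonneutral fraction
  sm4 <- selection_summary(tracks, fpr = 0.15)
  expect_equal(sm4$prop_nonneutral_adj[1],
               sm4$prop_nonneutral[1] * 0.85)
  expect_error(selection_summary(tracks, threshold = 1.2), "threshold")
})

test_that("track correlations use complete pairs only", {
  set.seed(76)
  v <- rnorm(50)
  a <- window_track("c1", (0:49) * 1e3, (1:50) * 1e3, value = v)
  b <- a
  expect_equal(track_correlation(a, b)$pearson_r, 1)
  b$value <- -v
  expect_equal(track_correlation(a, b)$pearson_r, -1)

  b$value <- rnorm(50)
  a$value[sample(50, 10)] <- NA
  got <- track_correlation(a, b)
  ok <- !is.na(a$value)
  expect_equal(got$pearson_r, cor(a$value[ok], b$value[ok]))
  expect_equal(got$n, sum(ok))

  short <- window_track("c1", 0:1 * 1e3, 1:2 * 1e3, value = c(1, 2))
  expect_error(track_correlation(short, short), "fewer than 3")
})

test_that("thinning keeps the first qualifying window per interval", {
  grid <- window_track("c1", seq(0, 9.9e5, 1e4), seq(1e4, 1e6, 1e4),
                       value = 1)
  th <- thin_windows(grid, 1e5)
  expect_equal(nrow(th), 10L)
  expect_true(all(diff(th$start) >= 1e5 - 1e4))
  expect_equal(th$start, seq(0, 9e5, 1e5))
  # brute force: first non-missing window in each bin
  grid$value[c(1, 2, 11)] <- NA
  th2 <- thin_windows(grid, 1e5)
  expect_equal(th2$start[1:2], c(2e4, 1.1e5))
  expect_error(thin_windows(grid, 5e3), "step")
})
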