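# Canonical per-locus summary-statistic layout shared by the C++ fast path
# (.cpp_sim_dataset_stats) and the R implementation for observed data.
# Pairs are ordered (tapajos,xingu), (tapajos,belem), (xingu,belem).
locus_stat_names <- function() {
  pair <- c("tx", "tb", "xb")
  pop <- c("t", "x", "b")
  c(paste0("s_", c(pop, "total")), paste0("pi_", c(pop, "total")),
    paste0("thetaw_", c(pop, "total")), paste0("fst_", pair),
    paste0("shared_", pair), paste0("private_", pop),
    paste0("pairpriv_", pair), paste0("fixedpop_", pop),
    paste0("fixeddiff_", pair))
}

# 30 per-locus statistics for a genotype matrix holding the three ingroup
# populations; per-site sample sizes under missing data (a site is counted
# when every population has >= 2 called haplotypes). Reduces exactly to the
# C++ definitions on complete data.
locus_stats_r <- function(gm) {
  pops <- c("tapajos", "xingu", "belem")
  L <- gm$seq_length
  cnt <- lapply(pops, function(p)
    site_counts(gm$alleles[haps_of_pop(gm, p), , drop = FALSE]))
  names(cnt) <- pops
  use <- Reduce(`&`, lapply(cnt, `[[`, "counted"))
  n <- lapply(cnt, function(s) s$n[use])
  d <- lapply(cnt, function(s) s$c[use])
  ct <- d$tapajos + d$xingu + d$belem
  nt <- n$tapajos + n$xingu + n$belem
  seg_tot <- ct > 0L & ct < nt
  het <- function(c2, n2) 2 * c2 * (n2 - c2) / (n2 * pmax(n2 - 1, 1))
  poly <- lapply(pops, function(p) d[[p]] > 0L & d[[p]] < n[[p]])
  names(poly) <- pops
  st <- setNames(numeric(30), locus_stat_names())
  for (i in 1:3) {
    p <- pops[i]
    st[i] <- sum(poly[[p]])
    st[4 + i] <- sum(het(d[[p]], n[[p]])[poly[[p]]]) / L
    a1s <- vapply(n[[p]][poly[[p]]], harmonic, numeric(1))
    st[8 + i] <- sum(1 / pmax(a1s, 1e-12)) / L
  }
  st[4] <- sum(seg_tot)
  st[8] <- sum(het(ct, nt)[seg_tot]) / L
  a1t <- vapply(nt[seg_tot], harmonic, numeric(1))
  st[12] <- sum(1 / pmax(a1t, 1e-12)) / L
  pairs <- list(c("tapajos", "xingu"), c("tapajos", "belem"),
                c("xingu", "belem"))
  for (q in 1:3) {
    p1 <- pairs[[q]][1]; p2 <- pairs[[q]][2]
    po <- setdiff(pops, pairs[[q]])
    f1 <- d[[p1]] / n[[p1]]; f2 <- d[[p2]] / n[[p2]]
    hw <- sum((het(d[[p1]], n[[p1]]) + het(d[[p2]], n[[p2]])) / 2)
    hb <- sum(f1 * (1 - f2) + f2 * (1 - f1))
    st[12 + q] <- if (hb > 0) 1 - hw / hb else 0
    st[15 + q] <- sum(poly[[p1]] & poly[[p2]])
    st[21 + q] <- sum(d[[p1]] > 0L & d[[p2]] > 0L & d[[po]] == 0L)
    st[27 + q] <- sum((d[[p1]] == n[[p1]] & d[[p2]] == 0L) |
                        (d[[p1]] == 0L & d[[p2]] == n[[p2]]))
  }
  for (i in 1:3) {
    p <- pops[i]
    others <- setdiff(pops, p)
    mono_others <- !poly[[others[1]]] & !poly[[others[2]]]
    st[18 + i] <- sum(poly[[p]] & mono_others)
    st[24 + i] <- sum(d[[p]] == n[[p]] & d[[others[1]]] == 0L &
                        d[[others[2]]] == 0L)
  }
  st
}

#' Summary-statistic feature vector of a dataset or single window
#'
#' For a multi-locus dataset (list of genotype matrices over the three
#' ingroup populations): the mean and variance across loci of 30 per-locus
#' summary statistics — segregating sites, pi and Watterson's theta per
#' population and combined, Hudson's Fst per pair, and shared / private /
#' pair-private / fixed-derived / fixed-difference site counts — giving a
#' fixed-order length-60 vector. For a single window (one genotype matrix):
#' the 30 per-window statistics themselves. Windows with fewer than
#' \code{min_ind} called individuals in any population are flagged
#' \code{excluded} (attribute), not silently dropped.
#'
#' @param x a \code{\link{genotype_matrix}} or a list of them (also accepts
#'   the \code{loci} element of \code{\link{simulate_dataset}} output).
#' @param min_ind minimum called individuals per population (default 3).
#' @return named numeric feature vector; attribute \code{excluded}.
#' @export
featurize <- function(x, min_ind = 3) {
  if (inherits(x, "genotype_matrix")) {
    st <- locus_stats_r(x)
    attr(st, "excluded") <- window_excluded(x, min_ind)
    return(st)
  }
  if (is.list(x) && !is.null(x$loci)) x <- x$loci
  stats_mat <- t(vapply(x, locus_stats_r, numeric(30)))
  out <- c(setNames(colMeans(stats_mat),
                    paste0("mean_", locus_stat_names())),
           setNames(apply(stats_mat, 2L, var),
                    paste0("var_", locus_stat_names())))
  attr(out, "excluded") <- any(vapply(x, window_excluded, logical(1), min_ind))
  out
}

window_excluded <- function(gm, min_ind = 3) {
  any(vapply(c("tapajos", "xingu", "belem"), function(p) {
    idx <- haps_of_pop(gm, p)
    al <- gm$alleles[idx, , drop = FALSE]
    n_ind <- length(idx) %/% 2L
    if (ncol(al) && n_ind > 0L) {
      has_data <- vapply(seq_len(n_ind), function(i)
        any(!is.na(al[c(2L * i - 1L, 2L * i), ])), logical(1))
      n_ind <- sum(has_data)
    }
    n_ind < min_ind
  }, logical(1)))
}

#' Thin a window grid to one window per step
#'
#' Keeps the first qualifying window (column \code{ok}, if present,
#' otherwise non-missing \code{value}) whose start falls in each
#' \code{step}-bp interval — e.g. one 10 kb window every 100 kb to limit
#' linkage between windows.
#'
#' @param grid window track data frame.
#' @param step interval in bp; must exceed the window length.
#' @return the selected rows.
#' @export
thin_windows <- function(grid, step) {
  if (any(step <= grid$end - grid$start))
    stop("step must exceed the window length")
  qual <- if ("ok" %in% names(grid)) grid$ok else !is.na(grid$value)
  g <- grid[qual, , drop = FALSE]
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  bin <- paste(g$chrom, g$start %/% step)
  g[!duplicated(bin), , drop = FALSE]
}
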