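# Per-site allele summaries for a set of haplotype rows: derived count and
# called sample size per column, plus which columns are "counted" (>= 2
# called haplotypes). Missingness is handled per site.
site_counts <- function(alleles) {
  called <- colSums(!is.na(alleles))
  derived <- colSums(alleles == 1L, na.rm = TRUE)
  list(n = called, c = derived, counted = called >= 2L)
}

harmonic <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1))

#' Within-population diversity statistics
#'
#' Computes segregating sites, nucleotide diversity per bp, Watterson's
#' theta per bp and Tajima's D for one population, with per-site sample
#' sizes under missing data. Sites with fewer than two called haplotypes in
#' the population are skipped (and subtracted from the callable length).
#' The callable length is \code{seq_length} minus the skipped SNP columns,
#' i.e. invariant positions are assumed callable. Watterson's theta uses a
#' per-site harmonic correction \eqn{\theta_W = \sum_s 1/a_1(n_s) / L};
#' Tajima's D uses the standard constants evaluated at the mean sample size
#' over counted sites, and is NA when S = 0 or fewer than 4 haplotypes.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param pop population name.
#' @return list with \code{S, pi, theta_w, tajimas_d, n_eff_sites,
#'   n_skipped}.
#' @export
diversity <- function(gm, pop) {
  al <- gm$alleles[haps_of_pop(gm, pop), , drop = FALSE]
  sc <- site_counts(al)
  n <- sc$n[sc$counted]
  d <- sc$c[sc$counted]
  L_eff <- gm$seq_length - sum(!sc$counted)
  seg <- d > 0L & d < n
  S <- sum(seg)
  pi_sum <- sum(2 * d * (n - d) / (n * (n - 1)))
  tw_sum <- sum(vapply(n[seg], function(ns) 1 / harmonic(ns), numeric(1)))
  nbar <- if (length(n)) mean(n) else 0
  td <- tajima_d(S, pi_sum, nbar)
  list(S = S, pi = pi_sum / L_eff, theta_w = tw_sum / L_eff,
       tajimas_d = td, n_eff_sites = L_eff, n_skipped = sum(!sc$counted))
}

tajima_d <- function(S, pi_sum, n) {
  if (S == 0 || n < 4) return(NA_real_)
  a1 <- harmonic(round(n))
  a2 <- sum(1 / seq_len(round(n) - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Between-population differentiation statistics
#'
#' Dxy per bp, Hudson's Fst (ratio of sums over the window: one minus the
#' ratio of summed mean within-population heterozygosity to summed
#' between-population diversity), and the classification of counted
#' segregating sites into shared polymorphisms, private polymorphisms of
#' either population, and fixed differences. Sites need at least two called
#' haplotypes in each population.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param popA,popB population names.
#' @return list with \code{dxy, fst, fst_raw, shared, private_a, private_b,
#'   fixed, n_eff_sites}.
#' @export
pair_stats <- function(gm, popA, popB) {
  alA <- gm$alleles[haps_of_pop(gm, popA), , drop = FALSE]
  alB <- gm$alleles[haps_of_pop(gm, popB), , drop = FALSE]
  sa <- site_counts(alA)
  sb <- site_counts(alB)
  if (ncol(gm$alleles) && (all(sa$n == 0L) || all(sb$n == 0L)))
    stop("a population has no called haplotypes at any site")
  use <- sa$counted & sb$counted
  nA <- sa$n[use]; cA <- sa$c[use]
  nB <- sb$n[use]; cB <- sb$c[use]
  L_eff <- gm$seq_length - sum(!use)
  pA <- cA / nA
  pB <- cB / nB
  dxy_site <- pA * (1 - pB) + pB * (1 - pA)
  hA <- 2 * cA * (nA - cA) / (nA * (nA - 1))
  hB <- 2 * cB * (nB - cB) / (nB * (nB - 1))
  hw <- sum((hA + hB) / 2)
  hb <- sum(dxy_site)
  fst_raw <- if (hb > 0) 1 - hw / hb else NA_real_
  polyA <- cA > 0L & cA < nA
  polyB <- cB > 0L & cB < nB
  fixed_diff <- (cA == nA & cB == 0L) | (cA == 0L & cB == nB)
  list(dxy = hb / L_eff,
       fst = if (is.na(fst_raw)) NA_real_ else min(max(fst_raw, 0), 1),
       fst_raw = fst_raw,
       shared = sum(polyA & polyB),
       private_a = sum(polyA & !polyB),
       private_b = sum(polyB & !polyA),
       fixed = sum(fixed_diff),
       n_eff_sites = L_eff)
}

#' Patterson's D (ABBA/BABA) and the fdM introgression fraction
#'
#' Frequency-based four-taxon test for introgression. Per site with
#' alternate-allele frequencies \eqn{p_1..p_4} (the fourth group is the
#' outgroup): ABBA = \eqn{(1-p_1)p_2p_3(1-p_4)},
#' BABA = \eqn{p_1(1-p_2)p_3(1-p_4)}; D = (ABBA-BABA)/(ABBA+BABA).
#' fdM uses the dynamic-donor denominator: when \eqn{p_2 \ge p_1} the donor
#' frequency \eqn{p_D = \max(p_2, p_3)} replaces both \eqn{p_2} and
#' \eqn{p_3}; otherwise \eqn{p_D = \max(p_1, p_3)} replaces \eqn{p_1} and
#' \eqn{p_3} and the denominator term is negated, making fdM negative for
#' P1-P3 sharing. Sites where any group has no called haplotype are skipped
#' and counted.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param p1,p2,p3,outgroup population names for the four groups.
#' @return list with \code{abba, baba, d_stat, f_dm, n_sites, n_skipped}.
#' @export
patterson_d <- function(gm, p1, p2, p3, outgroup) {
  freqs <- lapply(c(p1, p2, p3, outgroup), function(p) {
    al <- gm$alleles[haps_of_pop(gm, p), , drop = FALSE]
    sc <- site_counts(al)
    f <- sc$c / sc$n
    f[sc$n == 0L] <- NA_real_
    f
  })
  f <- do.call(cbind, freqs)
  ok <- rowSums(is.na(f)) == 0L
  n_skipped <- sum(!ok)
  f <- f[ok, , drop = FALSE]
  abba_t <- (1 - f[, 1]) * f[, 2] * f[, 3] * (1 - f[, 4])
  baba_t <- f[, 1] * (1 - f[, 2]) * f[, 3] * (1 - f[, 4])
  num <- abba_t - baba_t
  pD23 <- pmax(f[, 2], f[, 3])
  pD13 <- pmax(f[, 1], f[, 3])
  den <- ifelse(f[, 2] >= f[, 1],
                (1 - f[, 1]) * pD23 * pD23 * (1 - f[, 4]) -
                  f[, 1] * (1 - pD23) * pD23 * (1 - f[, 4]),
                -((1 - pD13) * f[, 2] * pD13 * (1 - f[, 4]) -
                    pD13 * (1 - f[, 2]) * pD13 * (1 - f[, 4])))
  abba <- sum(abba_t)
  baba <- sum(baba_t)
  list(abba = abba, baba = baba,
       d_stat = if (abba + baba > 0) (abba - baba) / (abba + baba)
                else NA_real_,
       f_dm = if (sum(den) != 0) sum(num) / sum(den) else NA_real_,
       n_sites = sum(ok), n_skipped = n_skipped)
}

#' Mean pairwise haplotype-homozygosity tract length (H-scan H)
#'
#' For every pair of phased haplotypes, the identity tract containing the
#' focal SNP is bounded by the nearest flanking positions where the pair
#' mismatches (window edges 0 and \code{seq_length} otherwise) and is
#' truncated at any gap between neighbouring SNPs longer than
#' \code{max_gap} bp. A pair that mismatches at the focal SNP contributes a
#' tract of length 0. H is the mean tract length in bp over all pairs.
#' Sites with a missing call in either haplotype are ignored for that pair.
#'
#' @param gm a phased \code{\link{genotype_matrix}}.
#' @param focal_index column index of the focal SNP.
#' @param max_gap maximum inter-SNP gap in bp (default 1e5).
#' @return H in bp.
#' @export
hscan_h <- function(gm, focal_index, max_gap = 1e5) {
  if (!gm$phased) stop("hscan_h requires phased haplotypes")
  al <- gm$alleles
  pos <- gm$positions
  S <- ncol(al)
  stopifnot(focal_index >= 1, focal_index <= S)
  n <- nrow(al)
  tracts <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- al[i, ]; b <- al[j, ]
      mm <- which(!is.na(a) & !is.na(b) & a != b)
      if (focal_index %in% mm) { tracts <- c(tracts, 0); next }
      left_mm <- mm[mm < focal_index]
      right_mm <- mm[mm > focal_index]
      lb <- if (length(left_mm)) pos[max(left_mm)] else 0
      lim <- if (length(left_mm)) max(left_mm) else 1L
      k <- focal_index
      while (k > lim) {  # walk outward; cut at the first oversized gap
        if (pos[k] - pos[k - 1] > max_gap) { lb <- pos[k]; break }
        k <- k - 1L
      }
      rb <- if (length(right_mm)) pos[min(right_mm)] else gm$seq_length
      lim <- if (length(right_mm)) min(right_mm) else S
      k <- focal_index
      while (k < lim) {
        if (pos[k + 1] - pos[k] > max_gap) { rb <- pos[k]; break }
        k <- k + 1L
      }
      tracts <- c(tracts, rb - lb)
    }
  }
  mean(tracts)
}

#' GC content of a nucleotide sequence
#'
#' @param sequence a character string of nucleotides (case-insensitive);
#'   ambiguity codes are excluded from the denominator.
#' @return (G+C)/(A+C+G+T), or NA for an empty/denominator-free sequence.
#' @export
gc_content <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  acgt <- sum(ch %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(NA_real_)
  sum(ch %in% c("G", "C")) / acgt
}
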