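#' Windows with a fixed number of qualifying SNPs
#'
#' Splits the SNPs of a genotype matrix into consecutive non-overlapping
#' windows of exactly \code{n_snps} qualifying SNPs (missingness fraction
#' \code{<= max_missing}); the trailing remainder is dropped so every window
#' carries the same amount of information. The physical span of each window
#' is the interval covered by its first and last SNP.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param n_snps SNPs per window (>= 2).
#' @param max_missing maximum fraction of missing calls for a SNP to
#'   qualify (default 0.3).
#' @return data frame: \code{chrom, start, end} (0-based half-open span),
#'   \code{n_sites}, and \code{site_index} (list column of SNP column
#'   indices).
#' @export
snp_windows <- function(gm, n_snps, max_missing = 0.3) {
  stopifnot(n_snps >= 2)
  missfrac <- colMeans(is.na(gm$alleles))
  qual <- which(missfrac <= max_missing)
  nw <- length(qual) %/% n_snps
  if (nw == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0)))
  idx <- split(qual[seq_len(nw * n_snps)], rep(seq_len(nw), each = n_snps))
  out <- data.frame(
    chrom = gm$chrom,
    start = vapply(idx, function(i) gm$positions[i[1]] - 1L, integer(1)),
    end = vapply(idx, function(i) gm$positions[i[length(i)]], integer(1)),
    n_sites = n_snps)
  out$site_index <- unname(idx)
  rownames(out) <- NULL
  out
}

#' Fixed-size window grid over a chromosome
#'
#' Non-overlapping windows of \code{size} bp covering \code{[0,
#' seq_length)}; windows whose callable-site count falls below
#' \code{min_sites} are flagged missing (\code{ok = FALSE}). Callable sites
#' are the invariant positions plus SNPs with at least two called
#' haplotypes, as in \code{\link{diversity}}.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param size window size in bp.
#' @param min_sites minimum callable sites (default 500).
#' @return data frame \code{chrom, start, end, n_sites, ok}.
#' @export
fixed_windows <- function(gm, size, min_sites = 500) {
  stopifnot(size > 0)
  starts <- seq(0L, gm$seq_length - 1L, by = size)
  ends <- pmin(starts + size, gm$seq_length)
  called2 <- colSums(!is.na(gm$alleles)) >= 2L
  n_sites <- vapply(seq_along(starts), function(i) {
    inw <- gm$positions > starts[i] & gm$positions <= ends[i]
    (ends[i] - starts[i]) - sum(inw & !called2)
  }, numeric(1))
  data.frame(chrom = gm$chrom, start = starts, end = ends,
             n_sites = as.integer(n_sites), ok = n_sites >= min_sites)
}

#' Regrid a variable-window track onto a fixed grid by weighted average
#'
#' Every grid cell takes the overlap-length-weighted mean of the input
#' windows that intersect it; cells with no overlap are missing. Input
#' windows must not overlap each other (the weights would be ambiguous).
#'
#' @param track window track data frame (chrom, start, end, value).
#' @param grid_size grid cell size in bp.
#' @param chrom_length optional; defaults to the largest input end.
#' @return a window track on the fixed grid.
#' @export
regrid_weighted <- function(track, grid_size, chrom_length = NULL) {
  if (length(unique(track$chrom)) > 1L)
    stop("regrid_weighted expects a single chromosome")
  o <- order(track$start)
  track <- track[o, ]
  if (any(track$start[-1] < track$end[-nrow(track)]))
    stop("input windows overlap; weighted regridding is ambiguous")
  if (is.null(chrom_length)) chrom_length <- max(track$end)
  starts <- seq(0L, chrom_length - 1L, by = grid_size)
  ends <- pmin(starts + grid_size, chrom_length)
  val <- wsum <- numeric(length(starts))
  for (i in seq_len(nrow(track))) {
    if (is.na(track$value[i])) next
    lo <- track$start[i]; hi <- track$end[i]
    cells <- seq(lo %/% grid_size, (hi - 1L) %/% grid_size) + 1L
    for (cc in cells) {
      ov <- min(hi, ends[cc]) - max(lo, starts[cc])
      if (ov > 0) {
        val[cc] <- val[cc] + track$value[i] * ov
        wsum[cc] <- wsum[cc] + ov
      }
    }
  }
  window_track(track$chrom[1], starts, ends,
               value = ifelse(wsum > 0, val / wsum, NA_real_),
               n_sites = as.integer(wsum))
}

#' Upper or lower quantile subset of a window track
#'
#' Selects the \code{ceiling(fraction * n_valid)} windows with the largest
#' (\code{tail = "upper"}) or smallest (\code{"lower"}) values; ties are
#' broken by genomic order (chromosome, start).
#'
#' @param track window track with a \code{value} column.
#' @param fraction fraction in (0, 1).
#' @param tail "upper" or "lower".
#' @return the selected rows of \code{track} (original row order).
#' @export
quantile_subset <- function(track, fraction, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(fraction > 0, fraction < 1)
  valid <- which(!is.na(track$value))
  if (!length(valid)) stop("all window values are missing")
  k <- ceiling(fraction * length(valid))
  v <- track$value[valid]
  genomic <- order(track$chrom[valid], track$start[valid])
  rank_pos <- integer(length(valid))
  rank_pos[genomic] <- seq_along(genomic)
  o <- if (tail == "upper") order(-v, rank_pos) else order(v, rank_pos)
  sel <- sort(valid[o[seq_len(k)]])
  track[sel, , drop = FALSE]
}

#' Summarize selection-class probability tracks across species
#'
#' For each species track: the fraction of windows whose maximum class
#' probability exceeds \code{threshold} (strictly), and, among those
#' confidently assigned windows, the fraction assigned to a nonneutral
#' class. Reports the cross-species arithmetic mean and an FPR-adjusted
#' nonneutral fraction, \code{nonneutral * (1 - fpr)}, treating all
#' potential false positives as neutral windows classified as selected.
#'
#' @param tracks named list of per-species data frames with one probability
#'   column per class in \code{hard, linked_hard, soft, linked_soft,
#'   neutral}.
#' @param threshold assignment probability threshold (default 0.7; a window
#'   at exactly the threshold is "low_probability").
#' @param fpr named per-species false-positive rate(s) (default 0).
#' @return data frame, one row per species plus a \code{"mean"} row, with
#'   \code{prop_confident, prop_nonneutral, prop_nonneutral_adj} (percent).
#' @export
selection_summary <- function(tracks, threshold = 0.7, fpr = 0) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(names(tracks))) names(tracks) <- paste0("species", seq_along(tracks))
  fpr <- rep_len(fpr, length(tracks))
  rows <- lapply(seq_along(tracks), function(i) {
    p <- as.matrix(tracks[[i]][, CLASSES5, drop = FALSE])
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities outside [0, 1]")
    pmax_ <- apply(p, 1L, max)
    conf <- pmax_ > threshold
    cls <- CLASSES5[apply(p, 1L, which.max)]
    nn <- mean(cls[conf] != "neutral") * 100
    data.frame(species = names(tracks)[i],
               prop_confident = mean(conf) * 100,
               prop_nonneutral = nn,
               prop_nonneutral_adj = nn * (1 - fpr[i]))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(species = "mean",
                        prop_confident = mean(out$prop_confident),
                        prop_nonneutral = mean(out$prop_nonneutral),
                        prop_nonneutral_adj = mean(out$prop_nonneutral_adj)))
}

#' Pearson correlation between two window tracks on the same grid
#'
#' @param a,b window tracks joined on identical (chrom, start, end) grids;
#'   only pairwise-complete windows enter the correlation.
#' @return list with \code{pearson_r, n, p}.
#' @export
track_correlation <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$start != b$start) || any(a$chrom != b$chrom))
    stop("tracks must be on an identical grid")
  ok <- !is.na(a$value) & !is.na(b$value)
  if (sum(ok) < 3L) stop("fewer than 3 complete window pairs")
  ct <- cor.test(a$value[ok], b$value[ok])
  list(pearson_r = unname(ct$estimate), n = sum(ok), p = ct$p.value)
}
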