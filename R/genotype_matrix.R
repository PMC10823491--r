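#' Haplotype genotype matrix with positions and population labels
#'
#' The central container of the package: a haplotypes x sites matrix of
#' biallelic allele codes (0 = reference/ancestral, 1 = alternate/derived,
#' NA = missing), physical positions for every site, the total sequence
#' length, and a population label for every haplotype. Unphased diploid data
#' are stored as two pseudo-haplotypes per sample with \code{phased = FALSE};
#' statistics that require phase (e.g. \code{\link{hscan_h}}) refuse such
#' input.
#'
#' @param alleles integer matrix, rows = haplotypes, columns = sites, values
#'   in \{0, 1, NA\}.
#' @param positions integer vector of strictly increasing 1-based physical
#'   positions, one per column.
#' @param seq_length total length of the sequence in bp; all positions must
#'   be \code{<= seq_length}.
#' @param pops character vector of population names, one per haplotype.
#' @param chrom chromosome/scaffold label.
#' @param phased logical; whether haplotypes are phased.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(alleles, positions, seq_length, pops,
                            chrom = "chr1", phased = TRUE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  if (ncol(alleles) != length(positions))
    stop("number of columns must equal number of positions")
  if (length(positions) && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(positions) && (positions[1] < 1L ||
                            positions[length(positions)] > seq_length))
    stop("positions must lie in [1, seq_length]")
  if (length(pops) != nrow(alleles))
    stop("one population label per haplotype required")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("allele codes must be 0, 1 or NA")
  if (is.null(rownames(alleles)))
    rownames(alleles) <- paste0(pops, "_", stats::ave(seq_along(pops), pops,
                                                      FUN = seq_along))
  structure(list(alleles = alleles, positions = positions,
                 seq_length = as.integer(seq_length),
                 pops = as.character(pops), chrom = chrom,
                 phased = isTRUE(phased)),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d haplotypes x %d sites on %s (%d bp, %s)\n",
              nrow(x$alleles), ncol(x$alleles), x$chrom, x$seq_length,
              if (x$phased) "phased" else "unphased"))
  tab <- table(x$pops)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$alleles)

#' Subset a genotype matrix to a physical interval
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param start,end 0-based half-open interval in bp.
#' @return A \code{genotype_matrix} holding only sites with
#'   \code{start < position <= end} (1-based positions), with positions kept
#'   on the original coordinate system.
#' @export
gm_window <- function(gm, start, end) {
  keep <- gm$positions > start & gm$positions <= end
  genotype_matrix(gm$alleles[, keep, drop = FALSE], gm$positions[keep],
                  gm$seq_length, gm$pops, gm$chrom, gm$phased)
}

#' Collapse haplotypes to diploid dosages
#'
#' Pairs consecutive haplotypes (1,2), (3,4), ... into individuals and
#' returns an individuals x sites matrix of alternate-allele dosages 0/1/2
#' (NA where either haplotype is missing).
#'
#' @param gm a \code{\link{genotype_matrix}} with an even number of haplotypes.
#' @return list with \code{dosage} matrix and per-individual \code{pops}.
#' @export
gm_dosage <- function(gm) {
  n <- nrow(gm$alleles)
  if (n %% 2L != 0L) stop("odd number of haplotypes cannot be paired")
  a <- gm$alleles[seq(1L, n, by = 2L), , drop = FALSE]
  b <- gm$alleles[seq(2L, n, by = 2L), , drop = FALSE]
  list(dosage = a + b, pops = gm$pops[seq(1L, n, by = 2L)])
}

haps_of_pop <- function(gm, pop) {
  idx <- which(gm$pops == pop)
  if (!length(idx)) stop(sprintf("unknown population '%s'", pop))
  idx
}
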