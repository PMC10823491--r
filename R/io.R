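#' Read biallelic SNPs from a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeps biallelic SNP records only
#' (multiallelic and indel records are skipped and counted in a message),
#' drops sites called in fewer than \code{min_presence} of the samples, and
#' splits each diploid genotype into two haplotypes in sample order. If any
#' genotype is unphased ("/" separator) the whole matrix is flagged
#' \code{phased = FALSE}: alleles are taken in VCF order as pseudo-haplotypes.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param pops named character vector or data frame (sample, population)
#'   assigning samples to populations; samples absent from it are dropped.
#' @param region optional \code{c(chrom, start, end)} (1-based, inclusive)
#'   restricting the records kept; a region with no records yields an empty
#'   matrix, not an error.
#' @param min_presence minimum fraction of samples with a called genotype
#'   for a site to be kept (default 0.5, i.e. at most 50\% missing).
#' @return A \code{\link{genotype_matrix}} (haplotypes = 2 x samples).
#' @export
read_vcf <- function(path, pops, region = NULL, min_presence = 0.5) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    keep <- chrom == region[[1]] & pos >= as.integer(region[[2]]) &
      pos <= as.integer(region[[3]])
  } else if (length(unique(chrom)) > 1L) {
    stop("VCF spans multiple chromosomes; supply `region`")
  }
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_skip <- sum(keep & !snp)
  if (n_skip > 0)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skip))
  keep <- keep & snp

  if (is.data.frame(pops)) pops <- stats::setNames(as.character(pops[[2]]),
                                                   as.character(pops[[1]]))
  samples <- colnames(v@gt)[-1]
  use_samp <- samples %in% names(pops)
  samples <- samples[use_samp]
  if (!length(samples)) stop("no VCF sample matches the population map")

  gt <- v@gt[keep, -1, drop = FALSE][, use_samp, drop = FALSE]
  pos <- pos[keep]
  chrom_lab <- if (!is.null(region)) region[[1]] else unique(chrom)[1]
  seq_len_guess <- if (!is.null(region)) as.integer(region[[3]]) else
    max(pos, 0L)

  nsite <- length(pos)
  nh <- 2L * length(samples)
  if (nsite == 0L) {
    return(genotype_matrix(matrix(integer(0), nh, 0), integer(0),
                           max(seq_len_guess, 1L),
                           rep(pops[samples], each = 2L), chrom_lab, TRUE))
  }
  gtf <- sub(":.*", "", gt)
  phased <- !any(grepl("/", gtf[gtf != "" & !is.na(gtf)], fixed = TRUE))
  a1 <- substr(gtf, 1L, 1L)
  a2 <- substr(gtf, 3L, 3L)
  conv <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out[!(a %in% c("0", "1"))] <- NA_integer_
    out
  }
  h <- matrix(NA_integer_, nh, nsite)
  h[seq(1L, nh, 2L), ] <- t(matrix(conv(a1), nsite, length(samples)))
  h[seq(2L, nh, 2L), ] <- t(matrix(conv(a2), nsite, length(samples)))

  called <- colSums(!is.na(h[seq(1L, nh, 2L), , drop = FALSE]) &
                    !is.na(h[seq(2L, nh, 2L), , drop = FALSE]))
  keep_site <- called / length(samples) >= min_presence
  h <- h[, keep_site, drop = FALSE]
  pos <- pos[keep_site]
  ord <- order(pos)
  h <- h[, ord, drop = FALSE]
  pos <- pos[ord]
  dup <- duplicated(pos)
  if (any(dup)) { h <- h[, !dup, drop = FALSE]; pos <- pos[!dup] }
  hap_pops <- rep(pops[samples], each = 2L)
  rownames(h) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  genotype_matrix(h, pos, max(seq_len_guess, max(pos)), hap_pops, chrom_lab,
                  phased)
}

#' Write / read the tab-separated "geno" dialect
#'
#' One row per site: chromosome, 1-based position, then one diploid genotype
#' per sample coded as allele pairs joined by "|" (phased) or "/" (unphased);
#' missing alleles use the token \code{N}, a fully missing genotype \code{N/N}.
#' The pair of functions round-trips losslessly.
#'
#' @param gm a \code{\link{genotype_matrix}} with an even haplotype count.
#' @param path output / input file.
#' @return \code{read_geno} returns a \code{genotype_matrix};
#'   \code{write_geno} returns \code{path} invisibly.
#' @export
write_geno <- function(gm, path) {
  n <- nrow(gm$alleles)
  if (n %% 2L != 0L) stop("geno format is diploid: odd haplotype count")
  sep <- if (gm$phased) "|" else "/"
  samp <- rownames(gm$alleles)[seq(1L, max(n, 1L), 2L)]
  samp <- sub("_1$", "", samp)
  a <- gm$alleles[seq(1L, n, 2L), , drop = FALSE]
  b <- gm$alleles[seq(2L, n, 2L), , drop = FALSE]
  tok <- function(m) { m2 <- as.character(m); m2[is.na(m2)] <- "N"; m2 }
  body <- matrix(paste0(tok(t(a)), sep, tok(t(b))), ncol = n %/% 2L)
  hdr <- c("#CHROM", "POS", samp)
  meta <- sprintf("##genarch seq_length=%d phased=%s pops=%s", gm$seq_length,
                  gm$phased, paste(gm$pops[seq(1L, n, 2L)], collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(hdr, collapse = "\t"), con)
  if (length(gm$positions))
    writeLines(paste(gm$chrom, gm$positions,
                     apply(body, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_geno
#' @export
read_geno <- function(path) {
  lines <- readLines(path)
  meta <- lines[1]
  m <- regmatches(meta, regexec(
    "seq_length=(\\d+) phased=(TRUE|FALSE) pops=([^ ]*)", meta))[[1]]
  if (length(m) != 4L) stop("not a genarch geno file: missing metadata header")
  seq_length <- as.integer(m[2])
  phased <- m[3] == "TRUE"
  ind_pops <- strsplit(m[4], ",", fixed = TRUE)[[1]]
  hdr <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  samp <- hdr[-(1:2)]
  body <- lines[-(1:2)]
  nh <- 2L * length(samp)
  if (!length(body)) {
    return(genotype_matrix(matrix(integer(0), nh, 0), integer(0), seq_length,
                           rep(ind_pops, each = 2L), "chr1", phased))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  chrom <- fields[[1]][1]
  pos <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  conv <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- x %in% c("0", "1")
    out[ok] <- as.integer(x[ok])
    out
  }
  h <- matrix(NA_integer_, nh, length(body))
  for (i in seq_along(fields)) {
    g <- fields[[i]][-(1:2)]
    h[seq(1L, nh, 2L), i] <- conv(substr(g, 1L, 1L))
    h[seq(2L, nh, 2L), i] <- conv(substr(g, 3L, 3L))
  }
  rownames(h) <- paste0(rep(samp, each = 2L), c("_1", "_2"))
  genotype_matrix(h, pos, seq_length, rep(ind_pops, each = 2L), chrom, phased)
}

#' Export haplotypes as a FASTA alignment
#'
#' Writes one record per haplotype. SNP alleles are encoded as the reference
#' base \code{A} (allele 0) and alternate base \code{T} (allele 1); missing
#' calls become \code{N}. With \code{include_monomorphic = TRUE} every
#' non-SNP position of the \code{seq_length}-bp sequence is filled with the
#' reference base so the alignment length equals the sequence length;
#' otherwise the alignment holds only the SNP columns.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param path output FASTA file.
#' @param include_monomorphic fill invariant positions (default TRUE).
#' @return \code{path}, invisibly.
#' @export
geno_to_fasta <- function(gm, path, include_monomorphic = TRUE) {
  if (length(gm$positions) && max(gm$positions) > gm$seq_length)
    stop("positions exceed seq_length")
  n <- nrow(gm$alleles)
  code <- c("A", "T")
  if (include_monomorphic) {
    L <- gm$seq_length
    seqs <- vapply(seq_len(n), function(h) {
      s <- rep("A", L)
      al <- gm$alleles[h, ]
      s[gm$positions] <- ifelse(is.na(al), "N", code[al + 1L])
      paste(s, collapse = "")
    }, character(1))
  } else {
    seqs <- vapply(seq_len(n), function(h) {
      al <- gm$alleles[h, ]
      paste(ifelse(is.na(al), "N", code[al + 1L]), collapse = "")
    }, character(1))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- rownames(gm$alleles)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read / write Newick tree files
#'
#' Thin wrappers over \pkg{ape} with a light well-formedness check so a
#' malformed file fails with the offending character position rather than a
#' parser crash. Branch lengths and polytomies are supported.
#'
#' @param path Newick file with one or more trees.
#' @param trees a \code{phylo} or \code{multiPhylo} object.
#' @return \code{read_newick} returns a \code{multiPhylo} list of trees.
#' @export
read_newick <- function(path) {
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  for (ln in txt) {
    bal <- cumsum(ifelse(strsplit(ln, "")[[1]] == "(", 1L,
                         ifelse(strsplit(ln, "")[[1]] == ")", -1L, 0L)))
    if (any(bal < 0L) || bal[length(bal)] != 0L)
      stop(sprintf("unbalanced parentheses near character %d of: %s",
                   which(bal < 0L)[1], substr(ln, 1, 40)))
    bad <- regmatches(ln, gregexpr(":[^,()0-9.eE+-]", ln))[[1]]
    if (length(bad))
      stop(sprintf("non-numeric branch length at character %d",
                   regexpr(":[^,()0-9.eE+-]", ln)))
  }
  tr <- ape::read.tree(text = paste(txt, collapse = "\n"))
  if (inherits(tr, "phylo")) tr <- c(tr)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Write / read a dataset in ms output format
#'
#' Serializes a list of \code{\link{genotype_matrix}} loci as the classic
#' "//", "segsites:", "positions:" blocks with 0/1 haplotype rows (positions
#' scaled to (0, 1)). \code{read_ms} inverts the writer given the locus
#' length in bp.
#'
#' @param dataset list of \code{genotype_matrix} objects.
#' @param path output / input file.
#' @param L locus length in bp used to rescale positions on reading.
#' @param pops population labels per haplotype for reading.
#' @return \code{read_ms} returns a list of \code{genotype_matrix}.
#' @export
write_ms <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("genarch ms %d %d", nrow(dataset[[1]]$alleles),
                     length(dataset)), con)
  writeLines("", con)
  for (gm in dataset) {
    writeLines("//", con)
    S <- ncol(gm$alleles)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", gm$positions / gm$seq_length),
                             collapse = " ")), con)
      al <- gm$alleles
      al[is.na(al)] <- 0L  # ms has no missing-data token
      writeLines(apply(al, 1L, paste, collapse = ""), con)
    } else writeLines("positions:", con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_ms
#' @export
read_ms <- function(path, L, pops) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    S <- as.integer(sub("segsites: *", "", lines[i + 1L]))
    if (S == 0L) {
      out[[k]] <- genotype_matrix(matrix(integer(0), length(pops), 0),
                                  integer(0), L, pops)
      next
    }
    posf <- as.numeric(strsplit(sub("positions: *", "", lines[i + 2L]),
                                " +")[[1]])
    pos <- unique_int_positions(posf * L, L)
    rows <- lines[(i + 3L):(i + 2L + length(pops))]
    al <- do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]])))
    out[[k]] <- genotype_matrix(al, pos, L, pops)
  }
  out
}

#' Write / read a per-window genomic track
#'
#' Tab-separated, with header \code{chrom start end value n_sites}; windows
#' use 0-based half-open coordinates. Missing values are written as
#' \code{NA}. This is the join format for every per-window quantity in the
#' package (statistics, topology weights, class probabilities, recombination
#' rates). Extra columns are preserved.
#'
#' @param track data frame with at least the columns above.
#' @param path file path.
#' @return \code{read_track} returns the track data frame.
#' @export
write_track <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(track)))
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  tr <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(tr)))
    stop("track file must have columns chrom, start, end")
  if (any(tr$start >= tr$end)) stop("track windows must satisfy start < end")
  tr
}

#' Build a window track data frame
#'
#' @param chrom,start,end,value,n_sites column vectors (recycled as needed).
#' @return data frame with the canonical track columns.
#' @export
window_track <- function(chrom, start, end, value = NA_real_,
                         n_sites = NA_integer_) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             value = value, n_sites = n_sites, stringsAsFactors = FALSE)
}

# map continuous positions to unique strictly-increasing 1-based integers
unique_int_positions <- function(posf, L) {
  pos <- floor(sort(posf)) + 1
  pos <- pmin(pmax(pos, 1), L)
  n <- length(pos)
  if (n > L) stop("more segregating sites than integer positions")
  for (i in seq_len(n)[-1]) if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1
  if (n && pos[n] > L) {
    pos[n] <- L
    for (i in rev(seq_len(n - 1))) if (pos[i] >= pos[i + 1]) pos[i] <- pos[i + 1] - 1
  }
  as.integer(pos)
}
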