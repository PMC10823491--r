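#' Local PCA of one genomic window
#'
#' Eigen-decomposition of the individual x individual covariance of centred
#' genotype dosages (0/1/2), with missing dosages mean-imputed per site —
#' standard local-PCA practice. The top \code{k} eigenvalues/vectors are
#' retained.
#'
#' @param gm a \code{\link{genotype_matrix}} window (haplotypes are paired
#'   into individuals).
#' @param k number of components (default 2).
#' @return object of class \code{window_pca}: \code{values} (length k,
#'   descending), \code{vectors} (individuals x k, orthonormal),
#'   \code{total_variance}, \code{n_ind}, \code{zero_variance} flag.
#' @export
window_pca <- function(gm, k = 2) {
  d <- gm_dosage(gm)
  X <- d$dosage
  if (nrow(X) < k + 1) stop("need at least k+1 individuals")
  for (s in seq_len(ncol(X))) {
    m <- is.na(X[, s])
    if (any(m)) X[m, s] <- mean(X[, s], na.rm = TRUE)
  }
  X[is.na(X)] <- 0  # all-missing site
  Xc <- sweep(X, 2L, colMeans(X))
  C <- tcrossprod(Xc) / max(1L, ncol(X))
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(values = vals[seq_len(k)],
                 vectors = e$vectors[, seq_len(k), drop = FALSE],
                 total_variance = sum(vals), n_ind = nrow(X),
                 zero_variance = sum(vals) < .Machine$double.eps * nrow(X)),
            class = "window_pca")
}

#' Dissimilarity between two window PCAs
#'
#' Frobenius distance between the rank-k covariance approximations of two
#' windows over the same individuals:
#' \eqn{d^2 = \sum_i \lambda_i^2 + \sum_j \mu_j^2 -
#'   2 \sum_{ij} \lambda_i \mu_j (u_i \cdot v_j)^2}.
#'
#' @param a,b \code{window_pca} objects with identical individuals and k.
#' @return the distance (a non-negative scalar).
#' @export
window_distance <- function(a, b) {
  if (a$n_ind != b$n_ind || length(a$values) != length(b$values))
    stop("window PCAs must share individuals and k")
  cross <- crossprod(a$vectors, b$vectors)^2
  d2 <- sum(a$values^2) + sum(b$values^2) -
    2 * sum(outer(a$values, b$values) * cross)
  sqrt(max(d2, 0))
}

#' Classical multidimensional scaling of a window distance matrix
#'
#' Double-centring plus eigen-decomposition (via \code{stats::cmdscale});
#' axes are ordered by eigenvalue.
#'
#' @param dmat square symmetric distance matrix with zero diagonal.
#' @param d number of output axes (default 2).
#' @return object of class \code{mds_embedding}: \code{points} (n x d),
#'   \code{eig}.
#' @export
mds <- function(dmat, d = 2) {
  dmat <- as.matrix(dmat)
  if (any(is.na(dmat)) || any(!is.finite(dmat))) stop("distance matrix has NA/Inf")
  if (nrow(dmat) != ncol(dmat) || any(abs(dmat - t(dmat)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  fit <- suppressWarnings(stats::cmdscale(dmat, k = d, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < d) {  # degenerate: pad with zeros
    pts <- cbind(pts, matrix(0, nrow(dmat), d - NCOL(pts)))
  }
  structure(list(points = pts, eig = fit$eig), class = "mds_embedding")
}

#' Corner windows of an MDS embedding
#'
#' Picks 3 mutually distant extreme points on the first two MDS axes
#' (greedy: farthest from the centroid, then twice the point farthest from
#' the already chosen set; \code{exact = TRUE} instead maximizes the
#' summed pairwise distance over all triples) and returns, for each, the
#' \code{ceiling(fraction * n)} windows nearest to it. A window may fall in
#' more than one corner; overlaps are reported.
#'
#' @param embedding an \code{mds_embedding} with d >= 2.
#' @param fraction fraction of windows per corner (default 0.1).
#' @param exact use the O(n^3) exact triple search (small n only).
#' @return list with \code{corners} (list of 3 index vectors),
#'   \code{extremes} (indices of the 3 extreme windows), \code{overlap}
#'   (indices in more than one corner).
#' @export
corners <- function(embedding, fraction = 0.1, exact = FALSE) {
  xy <- embedding$points[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 windows")
  D <- as.matrix(dist(xy))
  if (exact) {
    best <- c(1L, 2L, 3L); bestv <- -Inf
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (l in (j + 1):n) {
      v <- D[i, j] + D[i, l] + D[j, l]
      if (v > bestv) { bestv <- v; best <- c(i, j, l) }
    }
    ext <- best
  } else {
    cen <- colMeans(xy)
    e1 <- which.max(sqrt(rowSums(sweep(xy, 2L, cen)^2)))
    e2 <- which.max(D[e1, ])
    e3 <- which.max(pmin(D[e1, ], D[e2, ]))
    ext <- c(e1, e2, e3)
  }
  k <- ceiling(fraction * n)
  corner_sets <- lapply(ext, function(e) sort(order(D[e, ])[seq_len(k)]))
  tab <- table(unlist(corner_sets))
  list(corners = corner_sets, extremes = ext,
       overlap = as.integer(names(tab)[tab > 1L]))
}

#' Greedy LD pruning
#'
#' Left-to-right scan: a SNP is kept iff its squared correlation (on
#' dosages, complete pairs) with every previously kept SNP inside the
#' lookback window is at most \code{r2_threshold}.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param r2_threshold squared-correlation threshold in (0, 1]
#'   (default 0.2).
#' @param window lookback span in bp (default 1e5).
#' @return the pruned \code{genotype_matrix}.
#' @export
ld_prune <- function(gm, r2_threshold = 0.2, window = 1e5) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  X <- gm_dosage(gm)$dosage
  S <- ncol(X)
  keep <- logical(S)
  kept <- integer(0)
  for (s in seq_len(S)) {
    inwin <- kept[gm$positions[kept] >= gm$positions[s] - window]
    ok <- TRUE
    for (t in inwin) {
      r <- suppressWarnings(cor(X[, s], X[, t],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_threshold) { ok <- FALSE; break }
    }
    if (ok) { keep[s] <- TRUE; kept <- c(kept, s) }
  }
  genotype_matrix(gm$alleles[, keep, drop = FALSE], gm$positions[keep],
                  gm$seq_length, gm$pops, gm$chrom, gm$phased)
}

#' Identity-by-state matrix between individuals
#'
#' Mean per-site allele-sharing fraction over sites where both individuals
#' are called: per site \code{1 - |g_i - g_j| / 2} on dosages 0/1/2.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @return individuals x individuals symmetric matrix (NA where a pair
#'   shares no complete site).
#' @export
ibs_matrix <- function(gm) {
  X <- gm_dosage(gm)$dosage
  n <- nrow(X)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    out[i, i] <- 1
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- !is.na(X[i, ]) & !is.na(X[j, ])
      if (!any(ok)) next
      out[i, j] <- out[j, i] <- mean(1 - abs(X[i, ok] - X[j, ok]) / 2)
    }
  }
  out
}

#' Local-PCA scan of a chromosome (lostruct-style)
#'
#' Convenience pipeline: SNP windows, per-window PCA, pairwise window
#' distances, classical MDS, and corner extraction.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param n_snps SNPs per window (default 1000).
#' @param k PCs per window (default 2).
#' @param d MDS axes (default 2).
#' @param fraction corner fraction (default 0.1).
#' @param max_missing per-SNP missingness bound (default 0.3).
#' @return list with \code{windows}, \code{pcas}, \code{dist},
#'   \code{embedding}, \code{corners}.
#' @export
local_pca_scan <- function(gm, n_snps = 1000, k = 2, d = 2, fraction = 0.1,
                           max_missing = 0.3) {
  win <- snp_windows(gm, n_snps, max_missing)
  if (nrow(win) < 3) stop("fewer than 3 windows; reduce n_snps")
  pcas <- lapply(win$site_index, function(idx)
    window_pca(genotype_matrix(gm$alleles[, idx, drop = FALSE],
                               gm$positions[idx], gm$seq_length, gm$pops,
                               gm$chrom, gm$phased), k))
  nw <- nrow(win)
  dm <- matrix(0, nw, nw)
  for (i in seq_len(nw - 1)) for (j in (i + 1):nw)
    dm[i, j] <- dm[j, i] <- window_distance(pcas[[i]], pcas[[j]])
  emb <- mds(dm, d)
  list(windows = win, pcas = pcas, dist = dm, embedding = emb,
       corners = corners(emb, fraction))
}

#' @exportS3Method base::plot
#' @rdname mds
#' @param x an \code{mds_embedding}.
#' @param col point colours (e.g. corner membership).
#' @param ... passed to \code{plot.default}.
plot.mds_embedding <- function(x, col = 1, ...) {
  graphics::plot(x$points[, 1], x$points[, 2], col = col,
                 xlab = "MDS 1", ylab = "MDS 2", ...)
  invisible(x)
}
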