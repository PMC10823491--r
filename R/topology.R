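GROUPS4 <- c("tapajos", "xingu", "belem", "outgroup")
# unrooted ingroup topologies: which pair is sister
TOPO_PAIRS <- list(c("tapajos", "xingu"), c("xingu", "belem"),
                   c("tapajos", "belem"))

#' Unrooted topology of a single quartet
#'
#' For a 4-tip tree: the unique unrooted split. For a 4x4 distance matrix:
#' the four-point condition — the topology whose within-pair distance sum
#' is strictly minimal. Equal minima (e.g. a star quartet) return the tie
#' set. Topologies are 1 = (tapajos,xingu | belem,outgroup),
#' 2 = (xingu,belem | tapajos,outgroup), 3 = (tapajos,belem |
#' xingu,outgroup).
#'
#' @param x a \code{phylo} with the 4 tips named \code{tapajos, xingu,
#'   belem, outgroup}, or a 4x4 distance matrix with those dimnames.
#' @return integer vector: a single topology or the tie set.
#' @export
quartet_topology <- function(x) {
  if (inherits(x, "phylo")) {
    if (length(x$tip.label) != 4L) stop("quartet tree must have 4 tips")
    D <- unit_dist(x)
  } else {
    D <- as.matrix(x)
    if (any(abs(D - t(D)) > 1e-12)) stop("distance matrix must be symmetric")
  }
  if (!all(GROUPS4 %in% rownames(D)))
    stop("tips must be named tapajos, xingu, belem, outgroup")
  s <- vapply(TOPO_PAIRS, function(p) {
    rest <- setdiff(GROUPS4, p)
    D[p[1], p[2]] + D[rest[1], rest[2]]
  }, numeric(1))
  which(s <= min(s) + 1e-12)
}

# edge-count distance matrix of an unrooted copy of a tree; zero-length
# internal branches are collapsed first so they count as unresolved
unit_dist <- function(tree) {
  tr <- ape::unroot(tree)
  if (!is.null(tr$edge.length)) tr <- ape::di2multi(tr, tol = 1e-12)
  tr$edge.length <- rep(1, nrow(tr$edge))
  ape::cophenetic.phylo(tr)
}

weights_from_combos <- function(D, combos, groups, ties = "split") {
  t_ <- groups$tapajos[combos[, 1]]
  x_ <- groups$xingu[combos[, 2]]
  b_ <- groups$belem[combos[, 3]]
  o_ <- groups$outgroup[combos[, 4]]
  s1 <- D[cbind(t_, x_)] + D[cbind(b_, o_)]
  s2 <- D[cbind(x_, b_)] + D[cbind(t_, o_)]
  s3 <- D[cbind(t_, b_)] + D[cbind(x_, o_)]
  S <- unname(cbind(s1, s2, s3))
  mins <- S <= apply(S, 1L, min) + 1e-12
  nmin <- rowSums(mins)
  if (ties == "split") {
    w <- colSums(mins / nmin)
    n_used <- nrow(S)
  } else {  # discard tied quartets
    keep <- nmin == 1L
    w <- colSums(mins[keep, , drop = FALSE])
    n_used <- sum(keep)
    if (n_used == 0L) return(list(w = rep(1 / 3, 3), n = 0L))
  }
  list(w = w / n_used, n = nrow(S))
}

check_groups <- function(tree, groups) {
  if (!all(GROUPS4 %in% names(groups)))
    stop("groups must name tapajos, xingu, belem, outgroup")
  groups <- groups[GROUPS4]
  if (any(!lengths(groups))) stop("every group must be non-empty")
  missing_tips <- setdiff(unlist(groups), tree$tip.label)
  if (length(missing_tips))
    stop("tips absent from tree: ", paste(missing_tips, collapse = ", "))
  groups
}

#' Exact quartet topology weights of a window genealogy
#'
#' Enumerates every one-tip-per-group quartet of the tree, determines each
#' quartet's unrooted topology, and returns the fraction of quartets voting
#' for each of the three population topologies. Tied (unresolved) quartets
#' split their vote equally by default, keeping the weights on the simplex;
#' \code{ties = "discard"} drops them instead.
#'
#' @param tree a \code{phylo} genealogy.
#' @param groups named list (\code{tapajos, xingu, belem, outgroup}) of tip
#'   label vectors.
#' @param ties "split" (default) or "discard".
#' @return list with \code{w} (length-3 weights summing to 1),
#'   \code{n_quartets}, \code{method = "exact"}.
#' @export
weights_exact <- function(tree, groups, ties = c("split", "discard")) {
  ties <- match.arg(ties)
  groups <- check_groups(tree, groups)
  D <- unit_dist(tree)
  combos <- as.matrix(expand.grid(lapply(lengths(groups), seq_len),
                                  KEEP.OUT.ATTRS = FALSE))
  res <- weights_from_combos(D, combos, groups, ties)
  list(w = res$w, n_quartets = nrow(combos), method = "exact")
}

#' Monte Carlo quartet topology weights
#'
#' Uniform sampling of one-tip-per-group combinations with replacement;
#' converges to \code{\link{weights_exact}} as \code{n_samples} grows.
#'
#' @inheritParams weights_exact
#' @param n_samples number of sampled quartets.
#' @return as \code{\link{weights_exact}} with \code{method =
#'   "montecarlo"}.
#' @export
weights_mc <- function(tree, groups, n_samples = 10000,
                       ties = c("split", "discard")) {
  ties <- match.arg(ties)
  stopifnot(n_samples >= 1)
  groups <- check_groups(tree, groups)
  D <- unit_dist(tree)
  combos <- vapply(lengths(groups), function(k)
    sample.int(k, n_samples, replace = TRUE), integer(n_samples))
  if (n_samples == 1L) combos <- matrix(combos, 1L)
  res <- weights_from_combos(D, combos, groups, ties)
  list(w = res$w, n_quartets = n_samples, method = "montecarlo")
}

#' Topology weights of a window genealogy, choosing exact or Monte Carlo
#'
#' Exact enumeration when the combination count is at most
#' \code{max_exact}; Monte Carlo with \code{n_mc} samples otherwise.
#'
#' @inheritParams weights_exact
#' @param max_exact combination-count cutoff (default 50000).
#' @param n_mc Monte Carlo sample size (default 10000).
#' @export
topology_weights <- function(tree, groups, max_exact = 50000, n_mc = 10000) {
  n_comb <- prod(lengths(groups))
  if (n_comb <= max_exact) weights_exact(tree, groups)
  else weights_mc(tree, groups, n_mc)
}

#' Neighbor-joining tree of a genotype window
#'
#' Builds a window genealogy from pairwise Hamming distances (mismatch
#' fraction over sites called in both haplotypes) with \pkg{ape}'s
#' neighbor-joining; negative branch lengths are clamped to zero and
#' flagged. An unphased matrix has its allele pairs randomly re-shuffled
#' per individual and site first (seeded by the caller's RNG state),
#' mirroring random resolution of heterozygous genotypes.
#'
#' @param gm a \code{\link{genotype_matrix}} with >= 4 haplotypes, or a
#'   symmetric distance matrix with row names.
#' @return a \code{phylo}; attribute \code{"clamped"} counts clamped
#'   branches.
#' @export
nj_tree <- function(gm) {
  if (inherits(gm, "genotype_matrix")) {
    al <- gm$alleles
    if (nrow(al) < 4L) stop("need at least 4 haplotypes")
    if (!gm$phased) {
      for (i in seq(1L, nrow(al) - 1L, 2L)) {
        flip <- runif(ncol(al)) < 0.5
        tmp <- al[i, flip]
        al[i, flip] <- al[i + 1L, flip]
        al[i + 1L, flip] <- tmp
      }
    }
    n <- nrow(al)
    D <- matrix(0, n, n, dimnames = list(rownames(al), rownames(al)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- !is.na(al[i, ]) & !is.na(al[j, ])
      D[i, j] <- D[j, i] <- if (any(ok)) mean(al[i, ok] != al[j, ok]) else 0
    }
  } else {
    D <- as.matrix(gm)
    if (any(abs(D - t(D)) > 1e-12)) stop("distance matrix must be symmetric")
  }
  tr <- ape::nj(D)
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Mean topology weights for window subsets with bootstrap CIs
#'
#' @param weights data frame / matrix with columns \code{w1, w2, w3}, one
#'   row per window.
#' @param subsets named list of window index vectors (drawn from the same
#'   window universe).
#' @param n_boot bootstrap resamples for the CIs (default 1000).
#' @param conf confidence level (default 0.95).
#' @return data frame with subset, topology, mean weight, and CI bounds.
#' @export
weights_by_subset <- function(weights, subsets, n_boot = 1000, conf = 0.95) {
  W <- as.matrix(as.data.frame(weights)[, c("w1", "w2", "w3")])
  if (is.null(names(subsets))) names(subsets) <- paste0("subset", seq_along(subsets))
  a <- (1 - conf) / 2
  rows <- list()
  for (nm in names(subsets)) {
    idx <- subsets[[nm]]
    if (!length(idx)) stop(sprintf("subset '%s' is empty", nm))
    sub <- W[idx, , drop = FALSE]
    boots <- vapply(seq_len(n_boot), function(b)
      colMeans(sub[sample.int(nrow(sub), replace = TRUE), , drop = FALSE]),
      numeric(3))
    for (k in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        subset = nm, topology = k, mean = mean(sub[, k]),
        lo = unname(quantile(boots[k, ], a)),
        hi = unname(quantile(boots[k, ], 1 - a)), n = length(idx))
    }
  }
  do.call(rbind, rows)
}
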