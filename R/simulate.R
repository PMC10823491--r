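# Translate a demographic_model into the engine's deme/event tables.
# Demes (0-based in C++): 0 = tapajos, 1 = xingu, 2 = belem, 3 = outgroup.
# Backward per-lineage migration rate for a lineage in deme i exchanging
# with j at 2Nm = Mn is Mn / (2 Ne_i).
build_engine_args <- function(model, n_per_pop) {
  pops <- c(POPS3, "outgroup")
  n <- setNames(integer(4), pops)
  n[names(n_per_pop)] <- as.integer(n_per_pop)
  use_out <- n[["outgroup"]] > 0L
  D <- if (use_out) 4L else 3L
  nv <- n[seq_len(D)]

  pair_recent <- switch(model$topology, c(1L, 2L), c(2L, 3L), c(1L, 3L))
  third <- setdiff(1:3, pair_recent)
  anc_deme <- pair_recent[1]

  ne_now <- c(model$ne[POPS3], model$ne[["outgroup"]])[seq_len(D)]

  mig_mat <- function(pairs, ne_vec) {
    # pairs: list of c(i, j, Mn_ij, Mn_ji) with Mn_ij = migrants/gen into i
    m <- matrix(0, D, D)
    for (p in pairs) {
      m[p[1], p[2]] <- p[3] / (2 * ne_vec[p[1]])
      m[p[2], p[1]] <- p[4] / (2 * ne_vec[p[2]])
    }
    m
  }
  if (length(model$mig) == 2L) {
    m_tx_t <- m_tx_x <- model$mig[["tapajos_xingu"]]
    m_xb_x <- m_xb_b <- model$mig[["xingu_belem"]]
  } else {
    m_tx_t <- model$mig[["tapajos_from_xingu"]]
    m_tx_x <- model$mig[["xingu_from_tapajos"]]
    m_xb_x <- model$mig[["xingu_from_belem"]]
    m_xb_b <- model$mig[["belem_from_xingu"]]
  }
  mig0 <- mig_mat(list(c(1, 2, m_tx_t, m_tx_x), c(2, 3, m_xb_x, m_xb_b)),
                  ne_now)

  # epoch after t_recent: the ancestor of the recent pair occupies anc_deme
  # at size ne_anc_recent. As in an ms-style join, only the migration-matrix
  # entry between the two surviving demes persists: Tapajos-Xingu flow
  # continues when one of those demes survives as the ancestor (topologies
  # 2 and 3); under topology 1 the survivors are Tapajos and Belem, which
  # never exchange migrants.
  ne1 <- ne_now
  ne1[anc_deme] <- model$ne[["anc_recent"]]
  surv_pair <- sort(c(anc_deme, third))
  mig1 <- if (identical(surv_pair, c(1L, 2L)))
    mig_mat(list(c(1, 2, m_tx_t, m_tx_x)), ne1)
  else matrix(0, D, D)

  ne2 <- ne1
  ne2[anc_deme] <- model$ne[["anc_deep"]]
  mig2 <- matrix(0, D, D)

  ev_time <- c(model$t_recent, model$t_deep)
  ev_from <- c(pair_recent[2], third) - 1L
  ev_to <- c(anc_deme, anc_deme) - 1L
  ev_ne <- rbind(ne1, ne2)
  ev_mig <- rbind(as.vector(mig1), as.vector(mig2))
  if (use_out) {
    ev_time <- c(ev_time, model$t_outgroup)
    ev_from <- c(ev_from, 3L)
    ev_to <- c(ev_to, anc_deme - 1L)
    ev_ne <- rbind(ev_ne, ne2)
    ev_mig <- rbind(ev_mig, as.vector(mig2))
  }
  list(n_per_deme = unname(nv), ne0 = unname(ne_now), mig0 = as.vector(mig0),
       ev_time = ev_time, ev_from = as.integer(ev_from),
       ev_to = as.integer(ev_to), ev_ne = unname(ev_ne),
       ev_mig = unname(ev_mig),
       hap_pops = rep(pops[seq_len(D)], nv))
}

normalize_n_per_pop <- function(n_per_pop) {
  if (is.null(names(n_per_pop)))
    names(n_per_pop) <- c(POPS3, "outgroup")[seq_along(n_per_pop)]
  bad <- setdiff(names(n_per_pop), c(POPS3, "outgroup"))
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  n_per_pop
}

#' Simulate one genealogy under the structured coalescent
#'
#' Runs the structured coalescent (no recombination) for the given model and
#' sample configuration and returns the genealogy as an \pkg{ape}
#' \code{phylo} tree, ultrametric in time with branch lengths in
#' generations. Tips are labelled \code{population_index}.
#'
#' @param model a \code{\link{demographic_model}}.
#' @param n_per_pop named integer vector of haplotype sample sizes over
#'   \code{tapajos, xingu, belem, outgroup} (omitted = 0).
#' @return a \code{phylo} genealogy.
#' @export
simulate_genealogy <- function(model, n_per_pop) {
  n_per_pop <- normalize_n_per_pop(n_per_pop)
  ea <- build_engine_args(model, n_per_pop)
  res <- .cpp_simulate_arg(ea$n_per_deme, 1, 0, 0, ea$ne0,
                           ea$mig0, ea$ev_time, ea$ev_from, ea$ev_to,
                           ea$ev_ne, ea$ev_mig, TRUE)
  ntip <- sum(ea$n_per_deme)
  idx <- stats::ave(seq_along(ea$hap_pops), ea$hap_pops, FUN = seq_along)
  tips <- paste0(ea$hap_pops, "_", idx)
  edges_to_phylo(res$edge_child, res$edge_parent, res$node_time, ntip, tips)
}

# Assemble an ape phylo from child/parent node ids and node times.
edges_to_phylo <- function(child, parent, node_time, ntip, tip_labels) {
  par_of <- integer(length(node_time))
  par_of[child + 1L] <- parent + 1L
  root <- which(!(seq_along(node_time) %in% (child + 1L)) &
                  seq_along(node_time) > ntip)
  root <- root[length(root)]
  kids <- split(child + 1L, parent + 1L)
  nwk <- function(nd) {
    if (nd <= ntip) return(tip_labels[nd])
    ch <- kids[[as.character(nd)]]
    inner <- vapply(ch, function(c2) {
      bl <- node_time[nd] - node_time[c2]
      paste0(nwk(c2), ":", format(bl, digits = 12))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(nwk(root), ";"))
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Places Poisson(branch length x mu x L) mutations on every branch of a
#' genealogy and returns the resulting haplotypes. Each mutation gets a
#' unique position; carriers are the leaves below its branch.
#'
#' @param genealogy a \code{phylo} with branch lengths in generations and
#'   tips labelled \code{population_index} (as from
#'   \code{\link{simulate_genealogy}}).
#' @param mu per-bp per-generation mutation rate.
#' @param L locus length in bp (must be >= 1).
#' @return a \code{\link{genotype_matrix}}.
#' @export
drop_mutations <- function(genealogy, mu, L) {
  if (L < 1) stop("L must be >= 1")
  ntip <- length(genealogy$tip.label)
  pops <- sub("_[0-9]+$", "", genealogy$tip.label)
  nm <- rpois(nrow(genealogy$edge), genealogy$edge.length * mu * L)
  total <- sum(nm)
  if (total == 0L)
    return(genotype_matrix(matrix(integer(0), ntip, 0), integer(0), L, pops))
  below <- tips_below(genealogy)
  posf <- runif(total, 0, L)
  carrier <- rep(genealogy$edge[, 2], nm)
  ord <- order(posf)
  posf <- posf[ord]
  carrier <- carrier[ord]
  al <- matrix(0L, ntip, total)
  for (s in seq_len(total)) al[below[[carrier[s]]], s] <- 1L
  genotype_matrix(al, unique_int_positions(posf, L), L, pops)
}

tips_below <- function(tr) {
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  ord <- ape::reorder.phylo(tr, "postorder")$edge
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1]; c2 <- ord[e, 2]
    below[[p]] <- c(below[[p]], below[[c2]])
  }
  below
}

#' Simulate one locus of genotypes
#'
#' Simulates a single locus under the model; with
#' \code{with_recombination = TRUE} the model's recombination rate generates
#' piecewise genealogies along the locus (an ancestral recombination graph),
#' with \code{FALSE} (or \code{r = 0}) one genealogy covers all sites.
#'
#' @inheritParams simulate_genealogy
#' @param L locus length in bp.
#' @param with_recombination logical.
#' @return a \code{\link{genotype_matrix}}.
#' @export
simulate_locus <- function(model, n_per_pop, L, with_recombination = FALSE) {
  if (L < 1) stop("L must be >= 1")
  n_per_pop <- normalize_n_per_pop(n_per_pop)
  ea <- build_engine_args(model, n_per_pop)
  r <- if (with_recombination) model$r else 0
  res <- .cpp_simulate_arg(ea$n_per_deme, L, r, model$mu, ea$ne0, ea$mig0,
                           ea$ev_time, ea$ev_from, ea$ev_to, ea$ev_ne,
                           ea$ev_mig, FALSE)
  al <- res$genotypes
  rownames(al) <- paste0(ea$hap_pops, "_",
                         stats::ave(seq_along(ea$hap_pops), ea$hap_pops,
                                    FUN = seq_along))
  genotype_matrix(al, unique_int_positions(res$positions, L), L, ea$hap_pops)
}

#' Simulate a multi-locus dataset
#'
#' Independent loci under one model, with the generating parameters kept as
#' a one-row truth record for use as training labels.
#'
#' @inheritParams simulate_locus
#' @param n_loci number of independent loci.
#' @return list with \code{loci} (list of \code{genotype_matrix}) and
#'   \code{truth} (one-row data frame of generating parameters).
#' @export
simulate_dataset <- function(model, n_loci, L, n_per_pop,
                             with_recombination = FALSE) {
  loci <- lapply(seq_len(n_loci), function(i)
    simulate_locus(model, n_per_pop, L, with_recombination))
  draw <- attr(model, "draw")
  if (is.null(draw))
    draw <- c(topology = model$topology, model$ne, t_recent = model$t_recent,
              t_deep = model$t_deep, model$mig, recomb = model$r)
  list(loci = loci, truth = as.data.frame(as.list(draw)))
}

# Fast path: per-locus summary-statistic matrix straight from the engine
# (see features.R for the column layout). Ingroups only.
sim_dataset_stats <- function(model, n_loci, L, n_per_pop,
                              with_recombination = FALSE) {
  n_per_pop <- normalize_n_per_pop(n_per_pop)
  n_per_pop <- n_per_pop[setdiff(names(n_per_pop), "outgroup")]
  ea <- build_engine_args(model, n_per_pop)
  r <- if (with_recombination) model$r else 0
  st <- .cpp_sim_dataset_stats(as.integer(n_loci), ea$n_per_deme, L, r,
                               model$mu, ea$ne0, ea$mig0, ea$ev_time,
                               ea$ev_from, ea$ev_to, ea$ev_ne, ea$ev_mig)
  colnames(st) <- locus_stat_names()
  st
}

#' Generate a synthetic genomic landscape with truth labels
#'
#' Simulates one genotype window per landscape window under the base model,
#' with the window's recombination rate taken from the recombination map and
#' every effective size multiplied by the suppression factor of the
#' window's selection class. Returns the windows plus per-window tracks of
#' recombination rate and class probabilities (probability 1 on the true
#' class, optionally blurred by \code{class_noise}).
#'
#' @param cfg a \code{\link{landscape_config}}.
#' @param n_per_pop haplotype sample sizes as in
#'   \code{\link{simulate_locus}}.
#' @return list with \code{windows} (list of \code{genotype_matrix}),
#'   \code{recomb_track}, \code{class_track} (data frame with one
#'   probability column per class, \code{assigned_class} and \code{value} =
#'   true-class index), and \code{truth} (character vector of true classes).
#' @export
generate_landscape <- function(cfg, n_per_pop) {
  stopifnot(inherits(cfg, "landscape_config"))
  wl <- cfg$window_length
  windows <- vector("list", cfg$n_windows)
  for (i in seq_len(cfg$n_windows)) {
    m <- cfg$base_model
    mult <- cfg$suppression[[cfg$class_of_window[i]]]
    m$ne <- m$ne * mult
    m$r <- cfg$recomb_map[i]
    windows[[i]] <- simulate_locus(m, n_per_pop, wl,
                                   with_recombination = m$r > 0)
    windows[[i]]$chrom <- "sim1"
  }
  start <- (seq_len(cfg$n_windows) - 1L) * wl
  recomb_track <- window_track("sim1", start, start + wl,
                               value = cfg$recomb_map,
                               n_sites = vapply(windows, function(w)
                                 ncol(w$alleles), integer(1)))
  probs <- matrix(cfg$class_noise / 4, cfg$n_windows, 5,
                  dimnames = list(NULL, CLASSES5))
  truth_idx <- match(cfg$class_of_window, CLASSES5)
  probs[cbind(seq_len(cfg$n_windows), truth_idx)] <- 1 - cfg$class_noise
  class_track <- cbind(window_track("sim1", start, start + wl,
                                    value = truth_idx,
                                    n_sites = recomb_track$n_sites),
                       as.data.frame(probs))
  class_track$assigned_class <- cfg$class_of_window
  list(windows = windows, recomb_track = recomb_track,
       class_track = class_track, truth = cfg$class_of_window)
}

#' @exportS3Method stats::simulate
#' @rdname simulate_dataset
#' @param object a \code{\link{demographic_model}}.
#' @param nsim number of loci to simulate.
#' @param seed optional integer passed to \code{set.seed} first.
#' @param ... ignored.
simulate.demographic_model <- function(object, nsim = 1, seed = NULL,
                                       n_per_pop, L = 1e4,
                                       with_recombination = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_dataset(object, nsim, L, n_per_pop, with_recombination)
}
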