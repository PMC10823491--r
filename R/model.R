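POPS3 <- c("tapajos", "xingu", "belem")
CLASSES5 <- c("hard", "linked_hard", "soft", "linked_soft", "neutral")

#' Four-population isolation-with-migration model
#'
#' Describes one of three divergence histories for three ingroup populations
#' (Tapajos, Xingu, Belem areas of endemism) plus an outgroup, with constant
#' symmetric gene flow between the geographically adjacent pairs
#' Tapajos-Xingu and Xingu-Belem (never Tapajos-Belem, which are disjunct).
#' The three unrooted topologies are labelled as in the field:
#' topology 1 = (outgroup, Belem (Xingu, Tapajos)),
#' topology 2 = (outgroup, Tapajos (Xingu, Belem)),
#' topology 3 = (outgroup, Xingu (Belem, Tapajos)).
#'
#' After the first divergence the ancestor of the recent pair keeps
#' exchanging migrants with the remaining ingroup population at the rate of
#' the adjacent pair connecting them (both rates summed for topology 3,
#' where Xingu is adjacent to both members of the ancestor); all gene flow
#' stops at the deep divergence.
#'
#' @param topology integer 1, 2 or 3.
#' @param ne named vector of diploid effective sizes:
#'   \code{tapajos, xingu, belem, anc_recent, anc_deep, outgroup}.
#' @param t_recent,t_deep,t_outgroup divergence times in generations,
#'   ordered \code{t_recent < t_deep < t_outgroup}.
#' @param mig named vector \code{c(tapajos_xingu=, xingu_belem=)} of
#'   population migration rates in migrants per generation (2Nm); or, for
#'   directional flow, a length-4 vector named
#'   \code{tapajos_from_xingu, xingu_from_tapajos, xingu_from_belem,
#'   belem_from_xingu} (migrants per generation arriving in the first-named
#'   population).
#' @param mu per-bp per-generation mutation rate (default 2.42e-9, the
#'   passerine rate used throughout).
#' @param r per-bp per-generation recombination rate.
#' @param gen_time generation time in years (default 1).
#' @return object of class \code{demographic_model}.
#' @export
demographic_model <- function(topology, ne, t_recent, t_deep,
                              t_outgroup = 9.6e6, mig = c(tapajos_xingu = 0,
                                                          xingu_belem = 0),
                              mu = 2.42e-9, r = 0, gen_time = 1) {
  topology <- as.integer(topology)
  if (!topology %in% 1:3) stop("topology must be 1, 2 or 3")
  need <- c(POPS3, "anc_recent", "anc_deep", "outgroup")
  if (!all(need %in% names(ne))) stop("ne must name: ", paste(need, collapse = ", "))
  if (any(ne[need] <= 0)) stop("all effective sizes must be positive")
  if (!(t_recent < t_deep && t_deep < t_outgroup))
    stop("divergence times must satisfy t_recent < t_deep < t_outgroup")
  if (length(mig) == 2L) {
    if (!all(c("tapajos_xingu", "xingu_belem") %in% names(mig)))
      stop("symmetric mig must name tapajos_xingu and xingu_belem")
  } else if (length(mig) == 4L) {
    dn <- c("tapajos_from_xingu", "xingu_from_tapajos", "xingu_from_belem",
            "belem_from_xingu")
    if (!all(dn %in% names(mig))) stop("directional mig must name: ",
                                       paste(dn, collapse = ", "))
  } else stop("mig must have length 2 (symmetric) or 4 (directional)")
  if (any(mig < 0)) stop("migration rates must be non-negative")
  structure(list(topology = topology, ne = ne[need], t_recent = t_recent,
                 t_deep = t_deep, t_outgroup = t_outgroup, mig = mig,
                 mu = mu, r = r, gen_time = gen_time),
            class = "demographic_model")
}

#' @exportS3Method base::print
print.demographic_model <- function(x, ...) {
  lab <- c("(out, Belem (Xingu, Tapajos))", "(out, Tapajos (Xingu, Belem))",
           "(out, Xingu (Belem, Tapajos))")
  cat(sprintf("demographic_model: topology %d %s\n", x$topology,
              lab[x$topology]))
  cat(sprintf("  Ne: %s\n", paste(sprintf("%s=%.3g", names(x$ne), x$ne),
                                  collapse = " ")))
  cat(sprintf("  t_recent=%.4g  t_deep=%.4g  t_outgroup=%.4g generations\n",
              x$t_recent, x$t_deep, x$t_outgroup))
  cat(sprintf("  2Nm: %s\n", paste(sprintf("%s=%.3g", names(x$mig), x$mig),
                                   collapse = " ")))
  cat(sprintf("  mu=%.3g /bp/gen  r=%.3g /bp/gen  gen_time=%g yr\n",
              x$mu, x$r, x$gen_time))
  invisible(x)
}

#' Uniform prior bounds for model parameters
#'
#' Wide uniform priors with magnitudes consistent with passerine estimates.
#' \code{t_deep} is sampled conditionally on the drawn \code{t_recent}
#' (uniform between \code{max(lo, t_recent)} and its upper bound) to respect
#' the time ordering.
#'
#' @param ... named length-2 numeric vectors \code{c(lo, hi)} overriding the
#'   defaults: \code{ne_tapajos, ne_xingu, ne_belem, ne_anc_recent,
#'   ne_anc_deep, ne_outgroup, t_recent, t_deep, mig_tapajos_xingu,
#'   mig_xingu_belem, recomb}.
#' @return object of class \code{prior_set}.
#' @export
prior_set <- function(...) {
  defaults <- list(
    ne_tapajos = c(5e4, 2e6), ne_xingu = c(5e4, 2e6), ne_belem = c(5e4, 2e6),
    ne_anc_recent = c(5e4, 2e6), ne_anc_deep = c(5e4, 2e6),
    ne_outgroup = c(5e4, 2e6),
    t_recent = c(5e4, 5e5), t_deep = c(5e4, 2e6),
    mig_tapajos_xingu = c(0, 4), mig_xingu_belem = c(0, 4),
    recomb = c(0, 0))
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  for (nm in names(over)) {
    b <- over[[nm]]
    if (length(b) != 2L || !is.numeric(b) || any(!is.finite(b)))
      stop(sprintf("prior '%s' must be a finite numeric c(lo, hi)", nm))
    if (b[1] > b[2]) stop(sprintf("prior '%s' has lo > hi", nm))
    defaults[[nm]] <- b
  }
  structure(defaults, class = "prior_set")
}

#' Draw a demographic model from uniform priors
#'
#' @param priors a \code{\link{prior_set}}.
#' @param topology topology label 1, 2 or 3 of the drawn model.
#' @param t_outgroup outgroup divergence time in generations (fixed, not a
#'   prior: taken from fossil-calibrated split ages in practice).
#' @param mu,gen_time mutation rate and generation time passed through.
#' @return a \code{\link{demographic_model}}; the flat parameter draw is
#'   attached as attribute \code{"draw"} for training labels.
#' @export
sample_prior <- function(priors, topology = 1L, t_outgroup = 9.6e6,
                         mu = 2.42e-9, gen_time = 1) {
  stopifnot(inherits(priors, "prior_set"))
  u <- function(b) runif(1, b[1], b[2])
  ne <- c(tapajos = u(priors$ne_tapajos), xingu = u(priors$ne_xingu),
          belem = u(priors$ne_belem), anc_recent = u(priors$ne_anc_recent),
          anc_deep = u(priors$ne_anc_deep), outgroup = u(priors$ne_outgroup))
  t_recent <- u(priors$t_recent)
  t_deep <- runif(1, max(priors$t_deep[1], t_recent), priors$t_deep[2])
  if (t_deep <= t_recent) t_deep <- t_recent * (1 + 1e-9) + 1
  mig <- c(tapajos_xingu = u(priors$mig_tapajos_xingu),
           xingu_belem = u(priors$mig_xingu_belem))
  r <- u(priors$recomb)
  m <- demographic_model(topology, ne, t_recent, t_deep,
                         t_outgroup = max(t_outgroup, t_deep * (1 + 1e-9) + 1),
                         mig = mig, mu = mu, r = r, gen_time = gen_time)
  attr(m, "draw") <- c(topology = as.numeric(topology), ne,
                       t_recent = t_recent, t_deep = t_deep, mig, recomb = r)
  m
}

#' Configuration of a synthetic genomic landscape
#'
#' Describes a chromosome of equal-length windows with a per-window
#' recombination map and a per-window selection class. Sweep-affected
#' classes are emulated by multiplying every effective size of the base
#' model by a class-specific suppression factor in (0, 1], which reproduces
#' the local loss of diversity caused by selective sweeps and linked
#' selection without simulating selection trajectories.
#'
#' @param n_windows number of windows.
#' @param window_length window length in bp.
#' @param base_model a \code{\link{demographic_model}}.
#' @param recomb_map per-window recombination rate (recycled; defaults to
#'   the base model's rate).
#' @param class_of_window character vector over
#'   \code{hard, linked_hard, soft, linked_soft, neutral} (recycled).
#' @param suppression named per-class local-Ne multiplier in (0, 1];
#'   neutral must be 1.
#' @param class_noise probability mass moved off the true class in the
#'   emitted probability track (uniformly onto the other classes).
#' @return object of class \code{landscape_config}.
#' @export
landscape_config <- function(n_windows, window_length, base_model,
                             recomb_map = NULL, class_of_window = "neutral",
                             suppression = c(hard = 0.1, linked_hard = 0.3,
                                             soft = 0.3, linked_soft = 0.6,
                                             neutral = 1),
                             class_noise = 0) {
  stopifnot(inherits(base_model, "demographic_model"))
  if (is.null(recomb_map)) recomb_map <- base_model$r
  recomb_map <- rep_len(recomb_map, n_windows)
  class_of_window <- rep_len(class_of_window, n_windows)
  if (!all(class_of_window %in% CLASSES5))
    stop("classes must be among: ", paste(CLASSES5, collapse = ", "))
  if (!all(CLASSES5 %in% names(suppression)))
    stop("suppression must name all five classes")
  if (any(suppression <= 0 | suppression > 1))
    stop("suppression multipliers must lie in (0, 1]")
  if (suppression[["neutral"]] != 1) stop("neutral multiplier must be 1")
  structure(list(n_windows = as.integer(n_windows),
                 window_length = as.integer(window_length),
                 base_model = base_model, recomb_map = recomb_map,
                 class_of_window = class_of_window,
                 suppression = suppression[CLASSES5],
                 class_noise = class_noise),
            class = "landscape_config")
}
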