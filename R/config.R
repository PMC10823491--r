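#' Read and validate a pipeline configuration file
#'
#' YAML configuration with optional keys \code{priors} (named lo/hi pairs,
#' see \code{\link{prior_set}}), \code{window_size}, \code{min_sites},
#' \code{snps_per_window}, \code{prob_threshold}, \code{corner_fraction},
#' \code{r_max} (named per-species maximum recombination rate for the
#' single-window prior), \code{mu}, \code{gen_time}. Unknown keys raise an
#' error; the effective configuration (defaults merged with overrides) is
#' reported with \code{message()} when \code{verbose = TRUE}.
#'
#' @param path YAML file.
#' @param verbose log the effective configuration (default TRUE).
#' @return list with the validated effective configuration; element
#'   \code{priors} is a \code{\link{prior_set}}.
#' @export
read_config <- function(path, verbose = TRUE) {
  raw <- yaml::read_yaml(path)
  defaults <- list(window_size = 1e5, min_sites = 500,
                   snps_per_window = 1000, prob_threshold = 0.7,
                   corner_fraction = 0.1, r_max = NULL, mu = 2.42e-9,
                   gen_time = 1, priors = list())
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  num_keys <- c("window_size", "min_sites", "snps_per_window",
                "prob_threshold", "corner_fraction", "mu", "gen_time")
  for (k in num_keys)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L)
      stop(sprintf("configuration key '%s' must be a single number", k))
  if (cfg$prob_threshold <= 0 || cfg$prob_threshold >= 1)
    stop("prob_threshold must be in (0, 1)")
  cfg$priors <- do.call(prior_set, lapply(cfg$priors, as.numeric))
  if (verbose) {
    eff <- cfg[setdiff(names(cfg), "priors")]
    message("effective config: ",
            paste(sprintf("%s=%s", names(eff),
                          vapply(eff, function(v)
                            paste(format(v), collapse = ","), character(1))),
                  collapse = " "))
  }
  cfg
}
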