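#' Ground-truth parameters for a synthetic competition study
#'
#' Builds the per-genotype true expression levels and selection
#' coefficients that the simulator uses for one environment, together
#' with the noise model of the cytometry events. The shapes encode the
#' qualitative biology of the GAL network dosage study:
#'
#' * baseline reporter expression rises log-linearly with galactose;
#' * halving GAL80 (the inhibitor) raises expression, halving GAL4 (the
#'   activator) or GAL3 (the transducer) lowers it, GAL2 (the permease)
#'   barely moves it;
#' * in the mannose-dominated low-galactose environment the
#'   expression-fitness map is a hockey stick (mild benefit up to an
#'   optimum, steep cost beyond it);
#' * in galactose environments fitness is linear in expression with a
#'   slope that grows with log galactose concentration (negative at
#'   0.1%, ~zero at 0.3%, positive at 1%) and saturates above 1%;
#' * halving GAL2 costs fitness only at low galactose (<= 0.15%) and is
#'   marginally beneficial at >= 1%.
#'
#' @param environment A [gal_environment()] (or preset letter).
#' @param cv Coefficient of variation of each log-normal fluorescence
#'   channel (default 0.25).
#' @param contamination Fraction of debris-like background events in
#'   `[0, 0.3]` (default 0.10).
#' @param replicate_sd Standard deviation of the per-replicate jitter on
#'   the selection coefficient, per hour (default 5e-4); models day-to-day
#'   growth-rate variation between biological replicates.
#' @param bimodal_fraction Fraction of induced (high-YFP) query cells; the
#'   remainder sit at a low uninduced mode. Defaults to 0.6 in the
#'   mannose-dominated environment A (where single-cell distributions are
#'   bimodal) and 1 elsewhere.
#' @param null_effects If `TRUE`, zero every genotype effect: all
#'   genotypes share the baseline expression and a selection coefficient
#'   of exactly 0 (neutral competition null).
#' @return Object of class `gal_ground_truth`: list with
#'   `expression` and `fitness` (named over the 16 genotype codes; fitness
#'   is the true per-24 h odds fold-change relative to the reference),
#'   `selection` (per-hour log-ratio advantage, `log(fitness)/24`),
#'   `contamination_fraction`, `cv`, `replicate_sd`, `bimodal_fraction`,
#'   `environment`, and the fluorescence/scatter `channels` parameters.
#' @export
default_ground_truth <- function(environment, cv = 0.25, contamination = 0.10,
                                 replicate_sd = 5e-4, bimodal_fraction = NULL,
                                 null_effects = FALSE) {
  env <- as_gal_environment(environment)
  if (contamination < 0 || contamination > 0.3)
    stop("contamination must be in [0, 0.3]")
  g <- env$galactose
  mannose_dominated <- env$mannose > 0 && g <= 0.05

  if (is.null(bimodal_fraction))
    bimodal_fraction <- if (mannose_dominated && !null_effects) 0.6 else 1
  if (bimodal_fraction <= 0 || bimodal_fraction > 1)
    stop("bimodal_fraction must be in (0, 1]")

  # baseline reporter level (normalized to the reference channel mean)
  base <- 0.6 + 0.5 * log10(max(g, 1e-6) / 0.03)
  mult <- c(GAL2 = 0.95, GAL3 = 0.85, GAL4 = 0.75, GAL80 = 1.6)
  if (null_effects) mult[] <- 1

  codes <- genotype_codes()
  expr <- vapply(codes, function(code) {
    base * prod(mult[reduced_genes(code)])
  }, numeric(1))

  if (null_effects) {
    w <- stats::setNames(rep(1, length(codes)), codes)
  } else if (mannose_dominated) {
    # hockey stick: optimum E0, mild gain below, steep cost above
    E0 <- 0.7
    w <- 1 + 0.06 * (pmin(expr, E0) - pmin(base, E0)) -
      0.25 * pmax(expr - E0, 0)
  } else {
    slope <- 0.05 * log(min(max(g, 1e-6), 1) / 0.3)
    w <- 1 + slope * (expr - base)
  }
  if (!null_effects) {
    gal2_halved <- vapply(codes, function(code) "GAL2" %in% reduced_genes(code),
                          logical(1))
    if (g <= 0.15) w[gal2_halved] <- w[gal2_halved] * 0.93
    else if (g >= 1) w[gal2_halved] <- w[gal2_halved] * 1.01
  }
  names(w) <- codes
  if (any(!is.finite(w)) || any(w <= 0))
    stop("invalid ground truth: non-positive fitness")

  structure(list(
    environment = env,
    expression = expr,
    fitness = w,
    selection = log(w) / 24,
    contamination_fraction = contamination,
    cv = cv,
    replicate_sd = replicate_sd,
    bimodal_fraction = bimodal_fraction,
    channels = list(
      mcherry_reference_mean = 1000, mcherry_query_mean = 10,
      yfp_reference_mean = 5, yfp_scale = 1000, yfp_off_level = 0.05,
      fsc_meanlog = log(5e4), fsc_sdlog = 0.15,
      ssc_meanlog = log(3e4), ssc_sdlog = 0.20,
      debris_fsc_max = 1.2e5, debris_ssc_max = 8e4, debris_fluor_max = 30
    )
  ), class = "gal_ground_truth")
}

#' @export
print.gal_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground truth> environment %s: expression %.2f-%.2f, fitness %.3f-%.3f, %g%% debris\n",
    x$environment$name, min(x$expression), max(x$expression),
    min(x$fitness), max(x$fitness), 100 * x$contamination_fraction))
  invisible(x)
}
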