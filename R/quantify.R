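# Classify gated events into query vs reference, compute population ratios
# and reference-normalized expression.

#' Split gated events into query and reference populations
#'
#' The reference strain carries a constitutive mCherry reporter, so events
#' with mCherry above a threshold are reference and all others are query.
#' By default the threshold is found per sample at the minimum of the
#' smoothed log-mCherry density between its two largest modes; a fixed
#' threshold can be supplied instead.
#'
#' @param gated A gated [event_table()].
#' @param mcherry_threshold Optional fixed threshold (strictly positive);
#'   `NULL` (default) locates it automatically.
#' @return Object of class `sample_quant`: list with `n_query`,
#'   `n_reference`, `query_fraction`, `mean_yfp_query`,
#'   `mean_mcherry_reference`, `normalized_expression`, `threshold`, and
#'   the query/reference index partition.
#' @export
classify_events <- function(gated, mcherry_threshold = NULL) {
  if (!is.null(mcherry_threshold) && mcherry_threshold <= 0)
    stop("mcherry_threshold must be strictly positive")
  thr <- if (is.null(mcherry_threshold)) find_mcherry_threshold(gated$mCherry)
         else mcherry_threshold
  is_ref <- gated$mCherry > thr
  n_ref <- sum(is_ref)
  n_q <- sum(!is_ref)
  if (n_q == 0L || n_ref == 0L)
    stop("unquantifiable sample: empty ",
         if (n_q == 0L) "query" else "reference", " population")
  mean_yfp <- mean(gated$YFP[!is_ref])
  mean_mch <- mean(gated$mCherry[is_ref])
  structure(list(
    n_query = n_q, n_reference = n_ref,
    query_fraction = n_q / (n_q + n_ref),
    mean_yfp_query = mean_yfp, mean_mcherry_reference = mean_mch,
    normalized_expression = mean_yfp / mean_mch,
    threshold = thr,
    query = which(!is_ref), reference = which(is_ref)
  ), class = "sample_quant")
}

# valley between the two largest modes of the smoothed log-mCherry density
find_mcherry_threshold <- function(mcherry) {
  lx <- log10(mcherry + 1)
  d <- stats::density(lx, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2L)
    stop("cannot locate two mCherry modes; supply mcherry_threshold")
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  10^d$x[valley] - 1
}

#' @export
print.sample_quant <- function(x, ...) {
  cat(sprintf(
    "<sample quant> %d query / %d reference (fraction %.3f), expression %.3f\n",
    x$n_query, x$n_reference, x$query_fraction, x$normalized_expression))
  invisible(x)
}

#' Query:reference population odds
#'
#' @param quant A [classify_events()] result.
#' @return `n_query / n_reference` (strictly positive).
#' @export
population_ratio <- function(quant) {
  if (quant$n_reference < 1L) stop("cannot form a ratio: no reference events")
  quant$n_query / quant$n_reference
}

#' Reference-normalized expression of one sample
#'
#' Mean query YFP divided by the mean mCherry of the reference population
#' in the same sample, controlling for density and acquisition effects.
#'
#' @param quant A [classify_events()] result.
#' @return Unitless expression level (>= 0).
#' @export
normalized_expression <- function(quant) {
  if (!is.finite(quant$mean_mcherry_reference) ||
      quant$mean_mcherry_reference <= 0)
    stop("degenerate sample: reference mean is zero")
  quant$mean_yfp_query / quant$mean_mcherry_reference
}

#' Strain expression estimate over replicates
#'
#' Each replicate's value is the mean of its three timepoint measurements
#' (0, 24, 48 h); the strain estimate is the mean over replicates with
#' s.e.m. = sd / sqrt(N).
#'
#' @param values Either a numeric vector of per-replicate values, or a
#'   data.frame with columns `replicate`, `timepoint`, `value` holding the
#'   three timepoint measurements per replicate.
#' @return List of class `expression_estimate`: `estimate`, `sem`,
#'   `n_replicates`, `per_replicate`.
#' @export
expression_estimate <- function(values) {
  if (is.data.frame(values)) {
    sp <- split(values$value, values$replicate)
    n_tp <- length(unique(values$timepoint))
    if (n_tp != 3L || any(vapply(sp, length, integer(1)) != 3L))
      stop("incomplete experiment: each replicate needs all three timepoints")
    per_rep <- vapply(sp, mean, numeric(1))
  } else {
    per_rep <- as.numeric(values)
  }
  n <- length(per_rep)
  if (n < 2L) stop("need at least 2 replicates")
  structure(list(
    estimate = mean(per_rep),
    sem = stats::sd(per_rep) / sqrt(n),
    n_replicates = n,
    per_replicate = per_rep
  ), class = "expression_estimate")
}
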