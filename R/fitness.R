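# Relative fitness from the change in the query:reference population ratio
# over the competition period, normalized to the wild type.

#' Raw relative fitness from start/end population ratios
#'
#' Default (`type = "fold"`): the per-`interval` (24 h) fold-change of the
#' query:reference odds, `(ratio_end / ratio_start)^(interval/duration)`.
#' Equals 1 for neutral competition, is strictly positive, multiplicative
#' across loci, and — under exponential growth — independent of the
#' initial mixing ratio. `type = "selection"` returns the per-hour
#' log-ratio slope instead (the selection coefficient,
#' `log(ratio_end/ratio_start)/duration`).
#'
#' @param ratio_start,ratio_end Strictly positive query:reference odds at
#'   the beginning and end of the competition period (vectorized).
#' @param duration Competition duration in hours (default 48).
#' @param interval Reference interval for the fold-change (default 24 h).
#' @param type `"fold"` (default) or `"selection"`.
#' @return Numeric fitness value(s).
#' @examples
#' raw_fitness(1, 4, duration = 48)   # doubles every 24 h -> 2
#' @export
raw_fitness <- function(ratio_start, ratio_end, duration = 48, interval = 24,
                        type = c("fold", "selection")) {
  type <- match.arg(type)
  if (any(ratio_start <= 0) || any(ratio_end <= 0))
    stop("population ratios must be strictly positive")
  if (duration <= 0) stop("duration must be positive")
  if (type == "fold") (ratio_end / ratio_start)^(interval / duration)
  else log(ratio_end / ratio_start) / duration
}

#' Normalize raw fitness to the wild type
#'
#' Divides every raw fitness value by the mean wild-type raw fitness of
#' the same environment, so the wild-type normalized mean is exactly 1.
#'
#' @param fitness data.frame with columns `genotype` (codes),
#'   `environment`, `replicate` and the value column.
#' @param value Name of the column holding raw fitness
#'   (default `"raw_fitness"`).
#' @param wildtype Wild-type genotype code.
#' @return The input with a `fitness` column of normalized values added
#'   (replaced if present).
#' @export
normalize_fitness <- function(fitness, value = "raw_fitness",
                              wildtype = "2222") {
  stopifnot(value %in% names(fitness))
  out <- fitness
  out$fitness <- NA_real_
  for (env in unique(fitness$environment)) {
    in_env <- fitness$environment == env
    wt <- fitness[[value]][in_env & fitness$genotype == wildtype]
    if (length(wt) == 0L)
      stop("cannot normalize environment ", env, ": no wild-type estimates")
    out$fitness[in_env] <- fitness[[value]][in_env] / mean(wt)
  }
  out
}

#' Per-strain fitness summary
#'
#' Mean and s.e.m. of normalized fitness over replicates, per genotype and
#' environment. `sem` is the replicate scatter of the normalized values
#' (what the study's error bars show). Because every strain in an
#' environment is divided by the same noisy wild-type mean, `sem_norm`
#' additionally propagates the relative s.e.m. of the wild-type raw mean
#' in quadrature; use it when comparing a strain against an external
#' (e.g. ground-truth) value rather than against another strain of the
#' same environment.
#'
#' @param fitness Output of [normalize_fitness()]; a `raw_fitness` column
#'   (present in the standard pipeline) is needed for `sem_norm`.
#' @param wildtype Wild-type genotype code.
#' @return data.frame with `genotype`, `environment`, `w`, `sem`,
#'   `sem_norm`, `n`.
#' @export
fitness_summary <- function(fitness, wildtype = "2222") {
  sp <- split(fitness, list(fitness$genotype, fitness$environment), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(genotype = d$genotype[1], environment = d$environment[1],
               w = mean(d$fitness),
               sem = stats::sd(d$fitness) / sqrt(nrow(d)),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$sem_norm <- out$sem
  if ("raw_fitness" %in% names(fitness)) {
    for (env in unique(out$environment)) {
      wt <- fitness$raw_fitness[fitness$environment == env &
                                  fitness$genotype == wildtype]
      if (length(wt) < 2L) next
      rel_wt <- stats::sd(wt) / sqrt(length(wt)) / mean(wt)
      i <- out$environment == env & out$genotype != wildtype
      out$sem_norm[i] <- sqrt(out$sem[i]^2 + (out$w[i] * rel_wt)^2)
    }
  }
  out <- out[, c("genotype", "environment", "w", "sem", "sem_norm", "n")]
  out[order(out$environment, match(out$genotype, genotype_codes())), ]
}

#' Test invariance of fitness to the initial mixing ratio
#'
#' For every strain, compares fitness measured at different initial query
#' fractions with pairwise two-tailed two-sample Student's t-tests, then
#' controls the false discovery rate over the whole family with the
#' Benjamini-Hochberg procedure.
#'
#' @param fitness data.frame with columns `genotype`, `fraction` (initial
#'   query fraction condition) and `fitness` (one row per replicate).
#' @param alpha FDR level (default 0.05).
#' @param var_equal Pooled-variance t-test (default `TRUE`, Student).
#' @return data.frame with one row per strain x condition pair: `genotype`,
#'   `fraction1`, `fraction2`, `t`, `p`, `p_bh`, `discovery`.
#' @export
mixing_ratio_invariance_test <- function(fitness, alpha = 0.05,
                                         var_equal = TRUE) {
  fracs <- sort(unique(fitness$fraction))
  if (length(fracs) < 2L) stop("need at least 2 initial-fraction conditions")
  rows <- list()
  for (g in unique(fitness$genotype)) {
    for (i in seq_len(length(fracs) - 1L)) for (j in seq(i + 1L, length(fracs))) {
      x <- fitness$fitness[fitness$genotype == g & fitness$fraction == fracs[i]]
      y <- fitness$fitness[fitness$genotype == g & fitness$fraction == fracs[j]]
      if (length(x) < 3L || length(y) < 3L)
        stop("untestable design: need N >= 3 replicates per condition")
      tt <- safe_t_test(x, y, var_equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, fraction1 = fracs[i], fraction2 = fracs[j],
        t = tt$statistic, p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$discovery <- out$p_bh <= alpha
  rownames(out) <- NULL
  out
}

# t.test that reports t = 0, p = 1 instead of erroring on constant data
# with equal means (and p = 0 on constant data with different means)
safe_t_test <- function(x, y, var_equal = FALSE) {
  res <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, p.value = 1, parameter = NA_real_))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0,
                parameter = NA_real_))
  }
  list(statistic = unname(res$statistic), p.value = res$p.value,
       parameter = unname(res$parameter))
}
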