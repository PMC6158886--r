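# Strain-vs-wild-type comparisons with Bonferroni correction and the
# four-level star convention of the study's figures.

#' Compare one strain to the wild type
#'
#' Two-tailed two-sample t-test (Welch by default) of a strain's replicate
#' values against the wild type's, Bonferroni-corrected for the family of
#' strains compared (default 15, the non-wild-type strains of one
#' environment).
#'
#' @param values Replicate values for the strain (N >= 2).
#' @param wildtype Replicate values for the wild type (N >= 2).
#' @param family_size Number of comparisons in the Bonferroni family.
#' @param var_equal Pooled-variance Student's test instead of Welch.
#' @param alpha_levels Star thresholds, most to least stringent stars.
#' @return List of class `wt_comparison`: `t`, `df`, `p`, `p_bonferroni`
#'   (`min(1, p * family_size)`), `stars`.
#' @export
compare_to_wildtype <- function(values, wildtype, family_size = 15L,
                                var_equal = FALSE,
                                alpha_levels = c(0.05, 0.01, 0.001, 1e-4)) {
  if (length(values) < 2L || length(wildtype) < 2L)
    stop("need N >= 2 replicates per group")
  tt <- safe_t_test(values, wildtype, var_equal = var_equal)
  p_adj <- min(1, tt$p.value * family_size)
  structure(list(t = tt$statistic, df = tt$parameter, p = tt$p.value,
                 p_bonferroni = p_adj,
                 stars = star_level(p_adj, sort(alpha_levels,
                                                decreasing = TRUE))),
            class = "wt_comparison")
}

#' Strain-vs-wild-type comparison table
#'
#' Applies [compare_to_wildtype()] to every non-wild-type strain within
#' each environment for one metric, with the Bonferroni family equal to
#' the number of strains compared in that environment.
#'
#' @param data data.frame with `genotype`, `environment` and the
#'   per-replicate value column.
#' @param value Name of the value column (e.g. `"fitness"`).
#' @param wildtype Wild-type genotype code.
#' @param var_equal Passed to [compare_to_wildtype()].
#' @return data.frame with `genotype`, `environment`, `metric`, `t`, `df`,
#'   `p`, `p_bonferroni`, `stars`.
#' @export
compare_all_to_wildtype <- function(data, value, wildtype = "2222",
                                    var_equal = FALSE) {
  out <- list()
  for (env in unique(data$environment)) {
    d <- data[data$environment == env, ]
    wt <- d[[value]][d$genotype == wildtype]
    strains <- setdiff(unique(d$genotype), wildtype)
    for (g in strains) {
      cmp <- compare_to_wildtype(d[[value]][d$genotype == g], wt,
                                 family_size = length(strains),
                                 var_equal = var_equal)
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, environment = env, metric = value,
        t = cmp$t, df = cmp$df, p = cmp$p, p_bonferroni = cmp$p_bonferroni,
        stars = cmp$stars, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
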