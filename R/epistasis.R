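# Overall and net epistatic deviations on the 2^4 fitness lattice.
#
# The multiplicative null takes the expected fitness of a multi-reduced
# strain as the product of the single-reduction fitness values; the overall
# deviation is the departure from that product, and the net deviation
# removes everything already explained by lower-order interactions.

summary_lookup <- function(summary, codes) {
  idx <- match(codes, summary$genotype)
  if (anyNA(idx))
    stop("incomplete lattice: missing genotype(s) ",
         paste(codes[is.na(idx)], collapse = ", "))
  list(w = summary$w[idx], sem = summary$sem[idx])
}

#' Overall epistatic deviation of a gene set
#'
#' For a set M of at least two genes, `epsilon_M = w_M - prod(w_i, i in M)`
#' where `w_M` is the normalized fitness of the strain reduced in all of M
#' and `w_i` of the strain reduced only in gene i. The standard error is
#' first-order (delta-method) propagation of the strain s.e.m. values,
#' treated as independent:
#' `SE^2 = sem(w_M)^2 + sum_i (prod_{j != i} w_j)^2 sem(w_i)^2`.
#'
#' @param M Character vector of >= 2 genes from [gal_genes()].
#' @param summary A [fitness_summary()] for one environment with all
#'   required genotypes.
#' @return List of class `epistasis_deviation`: `set`, `epsilon`, `se`.
#' @export
overall_deviation <- function(M, summary) {
  M <- sort(match.arg(M, gal_genes(), several.ok = TRUE))
  if (length(M) < 2L) stop("epistatic deviation undefined for |M| < 2")
  full <- summary_lookup(summary, genotype_code(genotype_from_reduced(M)))
  singles <- summary_lookup(
    summary, vapply(M, function(g) genotype_code(genotype_from_reduced(g)),
                    character(1)))
  prod_others <- vapply(seq_along(M), function(i) prod(singles$w[-i]),
                        numeric(1))
  structure(list(
    set = M,
    epsilon = full$w - prod(singles$w),
    se = sqrt(full$sem^2 + sum(prod_others^2 * singles$sem^2))
  ), class = "epistasis_deviation")
}

#' Net epistatic deviation of a gene set
#'
#' Removes the net effects of all lower-order interactions by the
#' recursion `epsilon'_M = epsilon_M - sum(epsilon'_S)` over proper
#' subsets S of M with at least two genes; for pairs the net and overall
#' deviations coincide. Unrolling the recursion gives the signed
#' inclusion-exclusion expansion
#' `epsilon'_M = sum_{S subset of M, |S| >= 2} (-1)^(|M| - |S|) epsilon_S`,
#' and the standard error adds the overall-deviation standard errors of
#' that expansion in quadrature (their signs do not matter).
#'
#' @inheritParams overall_deviation
#' @return List of class `epistasis_deviation`: `set`, `epsilon` (the net
#'   deviation), `se`, plus `overall` (the set's overall deviation).
#' @export
net_deviation <- function(M, summary) {
  M <- sort(match.arg(M, gal_genes(), several.ok = TRUE))
  if (length(M) < 2L) stop("epistatic deviation undefined for |M| < 2")
  ov_memo <- new.env(parent = emptyenv())
  ov <- function(S) {
    key <- paste(S, collapse = "+")
    if (is.null(ov_memo[[key]])) ov_memo[[key]] <- overall_deviation(S, summary)
    ov_memo[[key]]
  }
  net_memo <- new.env(parent = emptyenv())
  net_rec <- function(S) {
    key <- paste(S, collapse = "+")
    if (!is.null(net_memo[[key]])) return(net_memo[[key]])
    e <- ov(S)$epsilon
    if (length(S) > 2L) {
      subs <- Filter(function(s) length(s) >= 2L && length(s) < length(S),
                     all_subsets(S))
      e <- e - sum(vapply(subs, net_rec, numeric(1)))
    }
    net_memo[[key]] <- e
    e
  }
  terms <- Filter(function(s) length(s) >= 2L, all_subsets(M))
  se2 <- sum(vapply(terms, function(S) ov(S)$se^2, numeric(1)))
  net <- net_rec(M)
  ov_M <- ov(M)
  structure(list(set = M, epsilon = net,
                 se = if (length(M) == 2L) ov_M$se else sqrt(se2),
                 overall = ov_M),
            class = "epistasis_deviation")
}

all_subsets <- function(S) {
  unlist(lapply(seq_along(S), function(k) utils::combn(S, k, simplify = FALSE)),
         recursive = FALSE)
}

#' @export
print.epistasis_deviation <- function(x, ...) {
  cat(sprintf("<deviation %s> epsilon = %.4f (SE %.4f)\n",
              paste(x$set, collapse = "+"), x$epsilon, x$se))
  invisible(x)
}

#' Z-test significance of epistatic deviations with Holm control
#'
#' Tests H0: epsilon = 0 for each deviation with a two-tailed Z-test and
#' controls the family-wise error rate over the supplied family with the
#' Holm-Bonferroni step-down procedure.
#'
#' @param epsilon,se Numeric vectors of deviations and their (strictly
#'   positive) standard errors.
#' @param alpha_levels Significance levels for the decision columns.
#' @return data.frame with `z`, `p`, `p_holm`, one logical column
#'   `sig_<alpha>` per level, and `stars`.
#' @export
epistasis_significance <- function(epsilon, se,
                                   alpha_levels = c(0.05, 0.01, 0.001, 1e-4)) {
  if (any(se <= 0)) stop("untestable result: zero standard error")
  z <- epsilon / se
  p <- 2 * stats::pnorm(-abs(z))
  p_holm <- stats::p.adjust(p, method = "holm")
  out <- data.frame(z = z, p = p, p_holm = p_holm)
  for (a in sort(alpha_levels, decreasing = TRUE))
    out[[paste0("sig_", format(a, scientific = FALSE))]] <- p_holm <= a
  out$stars <- star_level(p_holm, sort(alpha_levels, decreasing = TRUE))
  out
}

star_level <- function(p, levels = c(0.05, 0.01, 0.001, 1e-4)) {
  vapply(p, function(pp) strrep("*", sum(pp <= levels)), character(1))
}

#' Full epistasis table for one or more environments
#'
#' Computes, per environment, the 11 overall deviations (gene sets of
#' size >= 2) and the net deviations, and applies the Holm-corrected
#' Z-test within each environment separately for the overall panel (11
#' tests) and the higher-order net panel (the 4 triples and the
#' quadruple), mirroring the per-environment figure panels. With
#' `family = "study"` a single family per panel kind spans all
#' environments.
#'
#' @param summary A [fitness_summary()] covering complete 16-genotype
#'   lattices.
#' @param alpha_levels Significance levels for the decision columns.
#' @param family `"panel"` (default) or `"study"`.
#' @return data.frame with `environment`, `set`, `order`, `epsilon`,
#'   `se`, `epsilon_net`, `se_net`, Z/p/decision columns for both panels
#'   (`p_holm`/`stars` for the overall test, `p_holm_net`/`stars_net` for
#'   higher-order sets, NA elsewhere).
#' @export
epistasis_table <- function(summary, alpha_levels = c(0.05, 0.01, 0.001, 1e-4),
                            family = c("panel", "study")) {
  family <- match.arg(family)
  envs <- unique(summary$environment)
  sets <- gene_sets(min_size = 2L)
  base <- do.call(rbind, lapply(envs, function(env) {
    s <- summary[summary$environment == env, ]
    do.call(rbind, lapply(sets, function(M) {
      ov <- overall_deviation(M, s)
      nt <- net_deviation(M, s)
      data.frame(environment = env, set = paste(M, collapse = "+"),
                 order = length(M), epsilon = ov$epsilon, se = ov$se,
                 epsilon_net = nt$epsilon, se_net = nt$se,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(base) <- NULL
  group <- if (family == "panel") base$environment else rep("study", nrow(base))

  base$z <- base$epsilon / base$se
  base$p <- 2 * stats::pnorm(-abs(base$z))
  base$p_holm <- NA_real_
  for (gr in unique(group)) {
    i <- group == gr
    base$p_holm[i] <- stats::p.adjust(base$p[i], method = "holm")
  }
  for (a in sort(alpha_levels, decreasing = TRUE))
    base[[paste0("sig_", format(a, scientific = FALSE))]] <- base$p_holm <= a
  base$stars <- star_level(base$p_holm, sort(alpha_levels, decreasing = TRUE))

  hi <- base$order >= 3L
  base$z_net <- base$epsilon_net / base$se_net
  base$p_net <- ifelse(hi, 2 * stats::pnorm(-abs(base$z_net)), NA_real_)
  base$p_holm_net <- NA_real_
  for (gr in unique(group)) {
    i <- group == gr & hi
    base$p_holm_net[i] <- stats::p.adjust(base$p_net[i], method = "holm")
  }
  for (a in sort(alpha_levels, decreasing = TRUE))
    base[[paste0("sig_", format(a, scientific = FALSE), "_net")]] <-
      ifelse(hi, base$p_holm_net <= a, NA)
  base$stars_net <- ifelse(
    hi, star_level(base$p_holm_net, sort(alpha_levels, decreasing = TRUE)), "")
  base
}

#' Number of distinct fitness values entering a net deviation
#'
#' Every overall deviation in the expansion of `epsilon'_M` contributes
#' the multi-reduced strain's fitness `w_S`, and the singles contribute
#' `w_i`; a third-order net deviation therefore draws on 7 distinct
#' fitness measurements, the fourth-order one on 15.
#'
#' @param M Character vector of >= 2 genes.
#' @return Integer count of distinct strains involved.
#' @export
net_deviation_fitness_terms <- function(M) {
  if (length(M) < 2L) stop("epistatic deviation undefined for |M| < 2")
  sum(lengths(all_subsets(M)) >= 2L) + length(M)
}
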