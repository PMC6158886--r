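# Average effect of halving one gene's dosage on fitness, over the eight
# matched genetic backgrounds of the 2^4 design, with error propagation.

#' Matched genetic-background pairs for one gene
#'
#' The eight pairs of genotypes that are identical except for the named
#' gene's copy number (2 in the intact member, 1 in the halved member);
#' one pair per subset of the other three genes.
#'
#' @param gene One of [gal_genes()].
#' @return data.frame with columns `intact`, `halved` (genotype codes),
#'   8 rows in canonical background order.
#' @export
matched_backgrounds <- function(gene) {
  if (!gene %in% gal_genes()) stop("unknown gene: ", gene)
  others <- setdiff(gal_genes(), gene)
  backgrounds <- c(list(character(0)),
                   unlist(lapply(seq_along(others), function(k)
                     utils::combn(others, k, simplify = FALSE)),
                     recursive = FALSE))
  do.call(rbind, lapply(backgrounds, function(bg) {
    data.frame(intact = genotype_code(genotype_from_reduced(bg)),
               halved = genotype_code(genotype_from_reduced(c(bg, gene))),
               stringsAsFactors = FALSE)
  }))
}

#' Average dosage effect of one gene on fitness
#'
#' Mean over the 8 matched background pairs of
#' (fitness of the halved member - fitness of the intact member), using
#' the per-strain normalized fitness means. The uncertainty propagates the
#' strain s.e.m. values assuming independence:
#' `sqrt(sum(sem_halved^2 + sem_intact^2)) / 8`.
#'
#' @param gene One of [gal_genes()].
#' @param summary A [fitness_summary()] for one environment: data.frame
#'   with `genotype`, `w`, `sem` covering all 16 genotypes.
#' @return List of class `dosage_effect`: `gene`, `environment`, `effect`,
#'   `uncertainty`, `pairs`.
#' @export
average_dosage_effect <- function(gene, summary) {
  pairs <- matched_backgrounds(gene)
  idx <- match(c(pairs$intact, pairs$halved), summary$genotype)
  if (anyNA(idx))
    stop("incomplete design: missing genotype(s) in fitness summary")
  w <- stats::setNames(summary$w, summary$genotype)
  sem <- stats::setNames(summary$sem, summary$genotype)
  diffs <- w[pairs$halved] - w[pairs$intact]
  structure(list(
    gene = gene,
    environment = if ("environment" %in% names(summary))
      summary$environment[1] else NA,
    effect = mean(diffs),
    uncertainty = sqrt(sum(sem[pairs$halved]^2 + sem[pairs$intact]^2)) /
      nrow(pairs),
    pairs = pairs
  ), class = "dosage_effect")
}

#' Dosage-effect table over genes and environments
#'
#' @param summary A [fitness_summary()] covering one or more environments.
#' @return data.frame with `gene`, `environment`, `effect`, `uncertainty`
#'   (4 genes x environments rows).
#' @export
dosage_effects <- function(summary) {
  envs <- unique(summary$environment)
  out <- do.call(rbind, lapply(envs, function(env) {
    s <- summary[summary$environment == env, ]
    do.call(rbind, lapply(gal_genes(), function(gene) {
      d <- average_dosage_effect(gene, s)
      data.frame(gene = gene, environment = env, effect = d$effect,
                 uncertainty = d$uncertainty, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
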