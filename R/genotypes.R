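#' The four regulatory genes of the GAL network
#'
#' Returns the gene names in the fixed order used throughout the package
#' (also the digit order of genotype codes).
#'
#' @return Character vector `c("GAL2", "GAL3", "GAL4", "GAL80")`.
#' @export
gal_genes <- function() c("GAL2", "GAL3", "GAL4", "GAL80")

#' Construct a genotype from per-gene copy numbers
#'
#' A genotype is a copy-number assignment (1 or 2) for each of the four
#' regulatory genes GAL2, GAL3, GAL4 and GAL80 in a diploid background.
#'
#' @param copies Named integer vector with one entry per gene in
#'   [gal_genes()], each 1 or 2.
#' @return An object of class `gal_genotype`: a named integer vector.
#' @examples
#' genotype(c(GAL2 = 2, GAL3 = 2, GAL4 = 2, GAL80 = 1))
#' @export
genotype <- function(copies) {
  genes <- gal_genes()
  if (is.null(names(copies)) || !setequal(names(copies), genes))
    stop("`copies` must be named with exactly the genes ",
         paste(genes, collapse = ", "))
  copies <- as.integer(copies[genes])
  if (anyNA(copies) || !all(copies %in% c(1L, 2L)))
    stop("copy numbers must be 1 or 2")
  names(copies) <- genes
  structure(copies, class = "gal_genotype")
}

#' Coerce to a genotype
#'
#' Accepts a `gal_genotype`, a 4-character copy-number code such as
#' `"2122"` (digit order GAL2, GAL3, GAL4, GAL80), or a named copy vector.
#'
#' @param x Object to coerce.
#' @return A `gal_genotype`.
#' @export
as_genotype <- function(x) {
  if (inherits(x, "gal_genotype")) return(x)
  if (is.character(x) && length(x) == 1L && nchar(x) == 4L) {
    digits <- as.integer(strsplit(x, "")[[1]])
    return(genotype(stats::setNames(digits, gal_genes())))
  }
  if (is.numeric(x) && !is.null(names(x))) return(genotype(x))
  stop("cannot interpret ", deparse(substitute(x)), " as a genotype")
}

#' Genotype code string
#'
#' @param g A genotype (or code).
#' @return 4-character string of copy numbers in gene order, e.g. `"2222"`
#'   for the wild type.
#' @export
genotype_code <- function(g) paste0(unclass(as_genotype(g)), collapse = "")

#' Genes with reduced (halved) dosage
#'
#' The set M of the epistasis formulas: the genes carried at one copy.
#'
#' @param g A genotype (or code).
#' @return Character vector, possibly empty (wild type).
#' @export
reduced_genes <- function(g) {
  g <- as_genotype(g)
  gal_genes()[unclass(g) == 1L]
}

#' Genotype with a given set of genes halved
#'
#' @param genes Character vector of genes to carry at one copy (subset of
#'   [gal_genes()]); empty gives the wild type.
#' @return A `gal_genotype`.
#' @export
genotype_from_reduced <- function(genes) {
  if (length(genes) && !all(genes %in% gal_genes()))
    stop("unknown gene(s): ", paste(setdiff(genes, gal_genes()), collapse = ", "))
  copies <- stats::setNames(rep(2L, 4L), gal_genes())
  copies[genes] <- 1L
  genotype(copies)
}

#' @export
print.gal_genotype <- function(x, ...) {
  red <- reduced_genes(x)
  lab <- if (length(red) == 0L) "wild type" else paste(red, collapse = "+")
  cat("<genotype ", genotype_code(x), "> (", lab, " halved)\n", sep = "")
  invisible(x)
}

#' Enumerate the 16 genotypes of the combinatorial dosage design
#'
#' All 2^4 copy-number combinations over the four genes, wild type first,
#' then by the reduced set M in canonical subset order (singles in gene
#' order, then pairs, triples and the quadruple, each lexicographic in
#' gene order).
#'
#' @return List of 16 `gal_genotype` objects.
#' @export
enumerate_genotypes <- function() {
  sets <- c(list(character(0)), gene_sets(min_size = 1L))
  lapply(sets, genotype_from_reduced)
}

#' Codes of all genotypes in canonical order
#'
#' @return Character vector of 16 codes, `"2222"` first.
#' @export
genotype_codes <- function() {
  vapply(enumerate_genotypes(), genotype_code, character(1))
}

#' Canonical gene subsets
#'
#' Subsets of the four genes, ordered by size then lexicographically by
#' gene order; used to enumerate epistatic deviations (the 11 sets with
#' at least two genes) and genotypes.
#'
#' @param min_size,max_size Subset size bounds.
#' @return List of character vectors.
#' @export
gene_sets <- function(min_size = 2L, max_size = 4L) {
  genes <- gal_genes()
  out <- list()
  for (k in seq(min_size, max_size)) {
    cmb <- utils::combn(genes, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
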