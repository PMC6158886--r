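#' The six competition environments
#'
#' Carbon-source design of the study: two galactose + mannose mixtures and
#' four pure-galactose environments. Concentrations are percent w/v.
#'
#' @return data.frame with columns `name`, `galactose`, `mannose`.
#' @export
gal_environments <- function() {
  data.frame(
    name      = LETTERS[1:6],
    galactose = c(0.03, 0.1, 0.1, 1, 0.3, 2),
    mannose   = c(0.1, 0.03, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Construct a competition environment
#'
#' Either one of the six presets (by letter) or a custom sugar mix.
#'
#' @param name Preset letter `"A"`..`"F"`, or a label for a custom mix.
#' @param galactose,mannose Percent w/v; required for custom environments,
#'   must be non-negative.
#' @return Object of class `gal_environment`: list with `name`,
#'   `galactose`, `mannose`.
#' @examples
#' gal_environment("D")
#' gal_environment("lowgal", galactose = 0.05, mannose = 0)
#' @export
gal_environment <- function(name, galactose = NULL, mannose = NULL) {
  presets <- gal_environments()
  if (is.null(galactose) && is.null(mannose)) {
    i <- match(name, presets$name)
    if (is.na(i)) stop("unknown environment preset: ", name)
    galactose <- presets$galactose[i]
    mannose <- presets$mannose[i]
  } else {
    if (is.null(galactose)) galactose <- 0
    if (is.null(mannose)) mannose <- 0
  }
  if (galactose < 0 || mannose < 0)
    stop("sugar concentrations must be non-negative")
  structure(list(name = name, galactose = galactose, mannose = mannose),
            class = "gal_environment")
}

#' @rdname gal_environment
#' @param x Environment, preset letter, or list with the three fields.
#' @export
as_gal_environment <- function(x) {
  if (inherits(x, "gal_environment")) return(x)
  if (is.character(x) && length(x) == 1L) return(gal_environment(x))
  if (is.list(x) && all(c("galactose", "mannose") %in% names(x)))
    return(gal_environment(if (is.null(x$name)) "custom" else x$name,
                           x$galactose, x$mannose))
  stop("cannot interpret input as an environment")
}

#' @export
print.gal_environment <- function(x, ...) {
  cat(sprintf("<environment %s> %g%% galactose, %g%% mannose\n",
              x$name, x$galactose, x$mannose))
  invisible(x)
}
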