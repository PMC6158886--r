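# Synthetic competition experiments: deterministic exponential dynamics on the
# query:reference log-odds, observed through binomial event sampling and
# log-normal fluorescence, with a uniform debris background for the gate.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global random state so simulations are
#' reproducible without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-sample seed from a master seed
#'
#' Stable polynomial hash of the sample labels folded into the master
#' seed; gives every (genotype, environment, replicate, ...) its own
#' reproducible RNG stream below 2^31.
#'
#' @param master Integer master seed.
#' @param ... Labels (genotype code, environment name, replicate, ...).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "|")
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(max(h, 1))
}

#' Construct an event table
#'
#' Per-cell scatter and fluorescence measurements for one sample, with the
#' sample's metadata attached as attributes.
#'
#' @param FSC,SSC,YFP,mCherry Non-negative numeric channel vectors of one
#'   common length.
#' @param genotype,environment,replicate,timepoint Sample metadata
#'   (genotype code, environment name, replicate index, hours).
#' @return data.frame of class `event_table` with attribute `metadata`.
#' @export
event_table <- function(FSC, SSC, YFP, mCherry, genotype = NA, environment = NA,
                        replicate = NA, timepoint = NA) {
  df <- data.frame(FSC = FSC, SSC = SSC, YFP = YFP, mCherry = mCherry)
  if (nrow(df) < 1L) stop("an event table needs at least one event")
  if (any(as.matrix(df) < 0)) stop("channel values must be non-negative")
  attr(df, "metadata") <- list(genotype = genotype, environment = environment,
                               replicate = replicate, timepoint = timepoint)
  class(df) <- c("event_table", "data.frame")
  df
}

#' @export
print.event_table <- function(x, ...) {
  m <- attr(x, "metadata")
  cat(sprintf("<event table> %d events (genotype %s, env %s, rep %s, %s h)\n",
              nrow(x), m$genotype, m$environment, m$replicate, m$timepoint))
  invisible(x)
}

# one sample's worth of events at a given true query fraction
simulate_event_table <- function(n, query_fraction, expression, truth,
                                 metadata = list()) {
  ch <- truth$channels
  sdlog <- sqrt(log(1 + truth$cv^2))
  rln <- function(k, mean) stats::rlnorm(k, log(mean) - sdlog^2 / 2, sdlog)

  n_debris <- stats::rbinom(1, n, truth$contamination_fraction)
  n_cells <- n - n_debris
  n_q <- stats::rbinom(1, n_cells, query_fraction)
  n_r <- n_cells - n_q

  # query YFP: mixture of induced / uninduced modes whose weighted mean is
  # the genotype's true expression level (on the reference-normalized scale)
  bf <- truth$bimodal_fraction
  e_off <- ch$yfp_off_level
  yfp_q <- if (bf < 1) {
    e_on <- max((expression - (1 - bf) * e_off) / bf, e_off)
    n_on <- stats::rbinom(1, n_q, bf)
    c(rln(n_on, ch$yfp_scale * e_on), rln(n_q - n_on, ch$yfp_scale * e_off))
  } else {
    rln(n_q, ch$yfp_scale * expression)
  }

  cells_fsc <- stats::rlnorm(n_cells, ch$fsc_meanlog, ch$fsc_sdlog)
  cells_ssc <- stats::rlnorm(n_cells, ch$ssc_meanlog, ch$ssc_sdlog)

  FSC <- c(cells_fsc, stats::runif(n_debris, 0, ch$debris_fsc_max))
  SSC <- c(cells_ssc, stats::runif(n_debris, 0, ch$debris_ssc_max))
  YFP <- c(yfp_q, rln(n_r, ch$yfp_reference_mean),
           stats::runif(n_debris, 0, ch$debris_fluor_max))
  mCherry <- c(rln(n_q, ch$mcherry_query_mean),
               rln(n_r, ch$mcherry_reference_mean),
               stats::runif(n_debris, 0, ch$debris_fluor_max))

  ord <- sample.int(n)
  do.call(event_table, c(list(FSC = FSC[ord], SSC = SSC[ord], YFP = YFP[ord],
                              mCherry = mCherry[ord]), metadata))
}

#' Simulate one competition experiment
#'
#' One genotype x environment x replicate: the query strain is mixed with
#' the constitutive-mCherry reference at `init_fraction`, and the mixture
#' is observed at 0, 24 and 48 h. The true query:reference log-odds grows
#' linearly in time at the genotype's selection coefficient (plus a
#' per-replicate growth-rate jitter, see [default_ground_truth()]); each
#' observation draws `n_events` events binomially from the current true
#' fraction, with log-normal fluorescence and a `contamination_fraction`
#' of diffuse debris events.
#'
#' @param genotype Genotype (or code).
#' @param environment Environment (or preset letter).
#' @param truth A [default_ground_truth()] object for that environment.
#' @param init_fraction True initial query fraction in (0, 1); defaults to
#'   0.3 in environment A (the study's 3:7 mix) and 0.5 elsewhere.
#' @param n_events Events recorded per sample (>= 1000; default 25000).
#' @param seed RNG seed; the same seed reproduces the experiment exactly.
#' @param timepoints Observation times in hours.
#' @return Object of class `competition_experiment`: list with `events`
#'   (one [event_table()] per timepoint, named by hour), `init_fraction`,
#'   `true_selection` (the realized per-hour coefficient) and metadata.
#' @export
simulate_competition <- function(genotype, environment, truth,
                                 init_fraction = NULL, n_events = 25000,
                                 seed = 1L, timepoints = c(0, 24, 48)) {
  env <- as_gal_environment(environment)
  code <- genotype_code(genotype)
  if (is.null(init_fraction))
    init_fraction <- if (env$name == "A") 0.3 else 0.5
  if (init_fraction <= 0 || init_fraction >= 1)
    stop("init_fraction must be in (0, 1)")
  if (n_events < 1000) stop("n_events must be at least 1000")
  s0 <- truth$selection[[code]]
  if (!is.finite(s0)) stop("non-finite selection coefficient in ground truth")

  with_seed(seed, {
    s <- s0 + stats::rnorm(1, 0, truth$replicate_sd)
    lo0 <- stats::qlogis(init_fraction)
    events <- lapply(timepoints, function(t) {
      simulate_event_table(
        n_events, stats::plogis(lo0 + s * t), truth$expression[[code]], truth,
        metadata = list(genotype = code, environment = env$name,
                        replicate = NA, timepoint = t))
    })
    names(events) <- as.character(timepoints)
    structure(list(genotype = code, environment = env$name,
                   init_fraction = init_fraction, true_selection = s,
                   timepoints = timepoints, events = events),
              class = "competition_experiment")
  })
}

#' @export
print.competition_experiment <- function(x, ...) {
  cat(sprintf(
    "<competition experiment> genotype %s in env %s: %d timepoints x %d events, s = %.2e/h\n",
    x$genotype, x$environment, length(x$events), nrow(x$events[[1]]),
    x$true_selection))
  invisible(x)
}

#' Write / read an event table as CSV
#'
#' Plain-text round trip: metadata as leading `#key=value` comment lines,
#' then a header row `FSC,SSC,YFP,mCherry` and one row per event. Channel
#' values are written at full double precision so `read_events(write_events(x))`
#' reproduces `x` exactly.
#'
#' @param table An [event_table()].
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   the event table.
#' @export
write_events <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  m <- attr(table, "metadata")
  hdr <- vapply(names(m), function(k) sprintf("#%s=%s", k, m[[k]]), character(1))
  cols <- lapply(table[c("FSC", "SSC", "YFP", "mCherry")],
                 function(col) sprintf("%.17g", col))
  lines <- c(hdr, "FSC,SSC,YFP,mCherry", do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list(genotype = NA, environment = NA, replicate = NA, timepoint = NA)
  for (ln in lines[is_meta]) {
    kv <- sub("^#", "", ln)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    meta[[key]] <- if (key %in% c("replicate", "timepoint") && val != "NA")
      as.numeric(val) else if (val == "NA") NA else val
  }
  body <- lines[!is_meta]
  n_hdr <- sum(is_meta)
  if (length(body) < 2L || body[1] != "FSC,SSC,YFP,mCherry")
    stop("malformed event file (line ", n_hdr + 1L,
         "): expected header 'FSC,SSC,YFP,mCherry'")
  df <- utils::read.csv(textConnection(body), colClasses = "numeric")
  bad <- which(apply(as.matrix(df) < 0 | is.na(as.matrix(df)), 1, any))
  if (length(bad))
    stop("malformed event file (line ", n_hdr + 1L + bad[1],
         "): negative or missing channel value")
  do.call(event_table, c(as.list(df), meta))
}
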