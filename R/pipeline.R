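# End-to-end study pipeline: simulate -> gate -> classify -> quantify ->
# fitness -> dosage effects -> epistasis -> dose-response -> comparisons.

#' Study configuration
#'
#' Defaults reproduce the study design: 16 genotypes x 6 environments x
#' 9 replicates, 25,000 events per sample at 0/24/48 h, a 35% density
#' gate, the 3:7 initial mix in environment A and 1:1 elsewhere, and the
#' dose-response model trained on the 0.3% and 1% pure-galactose
#' environments.
#'
#' @param environments Environment preset letters.
#' @param genotypes Genotype codes.
#' @param replicates Biological replicates N (>= 2).
#' @param n_events Events per sample (>= 1000).
#' @param gate_fraction Density-gate target retention fraction.
#' @param timepoints Observation hours; fitness uses the first and last.
#' @param seed Master seed; every sample derives its own stream from it.
#' @param mcherry_threshold Fixed classification threshold, or `NULL` for
#'   the per-sample automatic threshold.
#' @param fitness_type `"fold"` (per-24 h odds fold-change, default) or
#'   `"selection"`.
#' @param init_fractions Optional named vector of initial query fractions
#'   per environment (defaults per [simulate_competition()]).
#' @param truth_args Extra arguments to [default_ground_truth()].
#' @param dose_response_training Environments used to fit the
#'   dose-response model.
#' @return List of class `study_config`.
#' @export
study_config <- function(environments = LETTERS[1:6],
                         genotypes = genotype_codes(),
                         replicates = 9L, n_events = 25000L,
                         gate_fraction = 0.35, timepoints = c(0, 24, 48),
                         seed = 1L, mcherry_threshold = NULL,
                         fitness_type = c("fold", "selection"),
                         init_fractions = NULL, truth_args = list(),
                         dose_response_training = c("E", "D")) {
  fitness_type <- match.arg(fitness_type)
  if (replicates < 2L) stop("need at least 2 replicates")
  if (n_events < 1000L) stop("n_events must be at least 1000")
  if (gate_fraction <= 0 || gate_fraction > 1)
    stop("gate_fraction must be in (0, 1]")
  if (length(timepoints) < 2L) stop("need at least 2 timepoints")
  structure(list(
    environments = environments, genotypes = genotypes,
    replicates = as.integer(replicates), n_events = as.integer(n_events),
    gate_fraction = gate_fraction, timepoints = timepoints,
    seed = as.integer(seed), mcherry_threshold = mcherry_threshold,
    fitness_type = fitness_type, init_fractions = init_fractions,
    truth_args = truth_args,
    dose_response_training = dose_response_training
  ), class = "study_config")
}

#' Run the full synthetic study and analysis
#'
#' Simulates every genotype x environment x replicate competition
#' experiment, gates and classifies each sample, and runs the complete
#' downstream analysis: per-replicate fitness (start vs end population
#' ratio), wild-type normalization, strain summaries, expression
#' estimates, average dosage effects, the epistatic-deviation table with
#' Holm-corrected Z-tests, the expression-fitness dose-response model
#' (with the 2%-galactose saturation diagnostic when environment F is
#' present), and Bonferroni-corrected strain-vs-wild-type comparisons.
#' Fully deterministic given the config (one derived seed per sample).
#'
#' @param config A [study_config()].
#' @param outdir Optional directory; when given, every result table is
#'   written there as TSV.
#' @param truths Optional precomputed ground truths (named by
#'   environment); by default built with [default_ground_truth()].
#' @return List of class `gal_study` with elements `samples`, `fitness`,
#'   `fitness_summary`, `expression`, `dosage_effects`, `epistasis`,
#'   `dose_response` (model, points, predictions, saturation), `comparisons`,
#'   `truths`, `config`.
#' @export
run_study <- function(config = study_config(), outdir = NULL, truths = NULL) {
  if (is.null(truths))
    truths <- stats::setNames(lapply(config$environments, function(env)
      do.call(default_ground_truth, c(list(environment = env),
                                      config$truth_args))),
      config$environments)

  t_end <- max(config$timepoints)
  t_start <- min(config$timepoints)
  samples <- list()
  fit_rows <- list()
  for (env in config$environments) {
    truth <- truths[[env]]
    init <- if (!is.null(config$init_fractions)) config$init_fractions[[env]]
            else NULL
    for (code in config$genotypes) {
      for (rep_i in seq_len(config$replicates)) {
        seed <- derive_seed(config$seed, env, code, rep_i)
        exp <- simulate_competition(code, env, truth, init_fraction = init,
                                    n_events = config$n_events, seed = seed,
                                    timepoints = config$timepoints)
        ratios <- numeric(0)
        for (tp in names(exp$events)) {
          gated <- apply_gate(exp$events[[tp]],
                              target_fraction = config$gate_fraction)
          q <- classify_events(gated, config$mcherry_threshold)
          ratios[tp] <- population_ratio(q)
          samples[[length(samples) + 1L]] <- data.frame(
            environment = env, genotype = code, replicate = rep_i,
            timepoint = as.numeric(tp), n_events = config$n_events,
            n_gated = nrow(gated), gate_fraction = nrow(gated) / config$n_events,
            n_query = q$n_query, n_reference = q$n_reference,
            query_fraction = q$query_fraction, ratio = ratios[[tp]],
            normalized_expression = q$normalized_expression,
            stringsAsFactors = FALSE)
        }
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          environment = env, genotype = code, replicate = rep_i,
          raw_fitness = raw_fitness(ratios[[as.character(t_start)]],
                                    ratios[[as.character(t_end)]],
                                    duration = t_end - t_start,
                                    type = config$fitness_type),
          true_selection = exp$true_selection, stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, samples)
  fitness <- do.call(rbind, fit_rows)
  fitness <- normalize_fitness(fitness)
  fsum <- fitness_summary(fitness)

  # per-replicate expression = mean over the three timepoints
  expr_rep <- stats::aggregate(
    normalized_expression ~ environment + genotype + replicate,
    data = samples, FUN = mean)
  names(expr_rep)[names(expr_rep) == "normalized_expression"] <- "expression"
  expression <- do.call(rbind, lapply(
    split(expr_rep, list(expr_rep$genotype, expr_rep$environment), drop = TRUE),
    function(d) {
      est <- expression_estimate(d$expression)
      data.frame(genotype = d$genotype[1], environment = d$environment[1],
                 expression = est$estimate, sem = est$sem,
                 n = est$n_replicates, stringsAsFactors = FALSE)
    }))
  rownames(expression) <- NULL
  expression <- expression[order(expression$environment,
                                 match(expression$genotype, genotype_codes())), ]

  full_lattice <- length(config$genotypes) == 16L
  dosage <- if (full_lattice) dosage_effects(fsum) else NULL
  epi <- if (full_lattice) epistasis_table(fsum) else NULL

  dr <- fit_study_dose_response(fsum, expression, config)

  comparisons <- NULL
  if ("2222" %in% config$genotypes) {
    comparisons <- rbind(
      compare_all_to_wildtype(fitness, "fitness"),
      compare_all_to_wildtype(expr_rep, "expression"))
  }

  study <- structure(list(
    samples = samples, fitness = fitness, fitness_summary = fsum,
    expression = expression, dosage_effects = dosage, epistasis = epi,
    dose_response = dr, comparisons = comparisons, truths = truths,
    config = config), class = "gal_study")
  if (!is.null(outdir)) write_study(study, outdir)
  study
}

# strain-mean (expression, fitness, galactose) points and model fit
fit_study_dose_response <- function(fsum, expression, config) {
  train_envs <- intersect(config$dose_response_training, config$environments)
  presets <- gal_environments()
  pts <- merge(fsum, expression[c("genotype", "environment", "expression")],
               by = c("genotype", "environment"))
  pts$galactose <- presets$galactose[match(pts$environment, presets$name)]
  pts <- pts[!is.na(pts$galactose) &
               presets$mannose[match(pts$environment, presets$name)] == 0, ]
  names(pts)[names(pts) == "w"] <- "fitness"
  train <- pts[pts$environment %in% train_envs, ]
  if (nrow(train) < 4L || length(unique(train$galactose)) < 2L) return(NULL)
  model <- fit_dose_response(train)
  pts$predicted <- predict(model, pts$expression, pts$galactose)
  sat <- if ("F" %in% pts$environment) {
    saturation_gap(model, pts[pts$environment == "F", ],
                   substitute_galactose = 1)
  } else NULL
  list(model = model, points = pts, saturation = sat,
       training_environments = train_envs)
}

write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(study$samples, "samples")
  wr(study$fitness, "fitness")
  wr(study$fitness_summary, "fitness_summary")
  wr(study$expression, "expression")
  wr(study$dosage_effects, "dosage_effects")
  wr(study$epistasis, "epistasis")
  wr(study$comparisons, "comparisons")
  if (!is.null(study$dose_response)) {
    wr(study$dose_response$points, "dose_response_points")
    wr(data.frame(term = names(study$dose_response$model$coefficients),
                  estimate = unname(study$dose_response$model$coefficients)),
       "dose_response_coefficients")
  }
  invisible(outdir)
}

#' @export
print.gal_study <- function(x, ...) {
  cat(sprintf(
    "<study> %d environments x %d genotypes x %d replicates (%d samples)\n",
    length(x$config$environments), length(x$config$genotypes),
    x$config$replicates, nrow(x$samples)))
  invisible(x)
}
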