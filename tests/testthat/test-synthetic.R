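# The simulator: deterministic exponential log-odds dynamics observed
# through binomial sampling, log-normal fluorescence, debris background.

test_that("qualitative ground-truth shapes match the network's biology", {
  trA <- default_ground_truth("A")
  codes <- genotype_codes()
  # halving GAL80 raises expression in every matched background
  for (p in seq_len(nrow(matched_backgrounds("GAL80")))) {
    pair <- matched_backgrounds("GAL80")[p, ]
    expect_gt(trA$expression[[pair$halved]], trA$expression[[pair$intact]])
  }
  # halving GAL2 costs fitness at low galactose, not at 1%
  trD <- default_ground_truth("D")
  expect_lt(trA$fitness[["1222"]], trA$fitness[["2222"]])
  expect_gte(trD$fitness[["1222"]], trD$fitness[["2222"]])
  # fitness rises with expression in the 1% galactose environment
  fit <- stats::lm(trD$fitness ~ trD$expression)
  expect_gt(coef(fit)[2], 0)
  # null configuration: identical selection coefficients
  tr0 <- default_ground_truth("D", null_effects = TRUE)
  expect_true(all(tr0$selection == 0))
})

test_that("the same seed reproduces an experiment exactly", {
  tr <- default_ground_truth("C")
  e1 <- simulate_competition("1212", "C", tr, n_events = 1000, seed = 11)
  e2 <- simulate_competition("1212", "C", tr, n_events = 1000, seed = 11)
  expect_identical(e1$events, e2$events)
  e3 <- simulate_competition("1212", "C", tr, n_events = 1000, seed = 12)
  expect_false(identical(e1$events[["0"]], e3$events[["0"]]))
})

test_that("neutral competition holds the query fraction at its start value", {
  tr <- default_ground_truth("D", null_effects = TRUE, contamination = 0,
                             replicate_sd = 0)
  exp <- simulate_competition("2222", "D", tr, init_fraction = 0.5,
                              n_events = 25000, seed = 3)
  q <- classify_events(exp$events[["48"]], mcherry_threshold = 100)
  expect_lt(abs(q$query_fraction - 0.5), 3 * sqrt(0.25 / 25000))
})

test_that("the odds ratio follows the closed-form exponential dynamics", {
  tr <- default_ground_truth("D", null_effects = TRUE, contamination = 0,
                             replicate_sd = 0)
  tr$selection["2222"] <- log(2) / 24  # doubles the odds every 24 h
  exp <- simulate_competition("2222", "D", tr, init_fraction = 0.5,
                              n_events = 25000, seed = 5)
  r <- vapply(exp$events, function(ev)
    population_ratio(classify_events(ev, mcherry_threshold = 100)), numeric(1))
  # binomial s.e. on the log odds at f ~ 0.5..0.8: ~ 3/sqrt(n) per timepoint
  expect_lt(abs(log(r[["48"]] / r[["0"]]) - log(4)), 6 * 3 / sqrt(25000))
})

test_that("the simulated log odds is linear in time with slope equal to the
           selection coefficient", {
  tr <- default_ground_truth("D", null_effects = TRUE, contamination = 0.05,
                             replicate_sd = 0)
  s_true <- 0.015
  tr$selection[] <- s_true
  slopes <- vapply(1:6, function(i) {
    exp <- simulate_competition("2222", "D", tr, n_events = 10000, seed = i)
    lo <- vapply(exp$events, function(ev) {
      q <- classify_events(apply_gate(ev), mcherry_threshold = 100)
      stats::qlogis(q$query_fraction)
    }, numeric(1))
    unname(coef(stats::lm(lo ~ c(0, 24, 48)))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - s_true),
            3 * stats::sd(slopes) / sqrt(length(slopes)))
})

test_that("event tables round-trip through CSV exactly", {
  tb <- event_table(FSC = c(1.25, 2^-20, 3e5), SSC = c(0.1, 0.2, 1/3),
                    YFP = c(10.123456789101112, 0, 5),
                    mCherry = c(1000.5, 2, pi),
                    genotype = "1122", environment = "B", replicate = 4,
                    timepoint = 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(tb, path)
  back <- read_events(path)
  expect_identical(as.data.frame(back), as.data.frame(tb))
  expect_identical(attr(back, "metadata"), attr(tb, "metadata"))
})

test_that("a bulk 25,000-event table survives the round trip with metadata", {
  tr <- default_ground_truth("E")
  exp <- simulate_competition("2211", "E", tr, n_events = 25000, seed = 8)
  tb <- exp$events[["24"]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(tb, path)
  back <- read_events(path)
  expect_identical(as.data.frame(back), as.data.frame(tb))
  expect_identical(attr(back, "metadata")$genotype, "2211")
  expect_identical(attr(back, "metadata")$timepoint, 24)
})

test_that("malformed event files are rejected with line context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#genotype=2222", "FSC,SSC,YFP,mCherry",
               "1,2,3,4", "1,-2,3,4"), path)
  expect_error(read_events(path), "line 4")
  writeLines(c("FSC,SSC,mCherry", "1,2,3"), path)
  expect_error(read_events(path), "header")
  expect_error(event_table(FSC = -1, SSC = 1, YFP = 1, mCherry = 1),
               "non-negative")
})

test_that("per-sample seeds derived from a master seed are stable and distinct", {
  s1 <- derive_seed(1, "A", "2222", 1)
  expect_identical(s1, derive_seed(1, "A", "2222", 1))
  expect_false(s1 == derive_seed(1, "A", "2222", 2))
  expect_false(s1 == derive_seed(2, "A", "2222", 1))
  seeds <- unlist(lapply(LETTERS[1:6], function(e)
    lapply(genotype_codes(), function(g)
      lapply(1:9, function(r) derive_seed(1, e, g, r)))))
  expect_length(unique(seeds), 16 * 6 * 9)
  expect_true(all(seeds >= 1 & seeds < 2^31))
})

test_that("the generated study has one sample per genotype, environment,
           replicate and timepoint", {
  cfg <- study_config(environments = "C", genotypes = genotype_codes(),
                      replicates = 2, n_events = 1000, seed = 21)
  st <- run_study(cfg)
  expect_equal(nrow(st$samples), 16 * 1 * 2 * 3)
  key <- with(st$samples, table(genotype, replicate, timepoint))
  expect_true(all(key == 1))
})
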