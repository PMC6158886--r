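# Query/reference classification, population ratios, normalized expression.

test_that("well-separated mCherry modes classify with the closed-form
           normal tail mass", {
  set.seed(501)
  n <- 20000
  sdlog <- 0.25
  sep <- 8 * sdlog  # 8 sigma between log-means; tail mass pnorm(-4) each
  mu_q <- log(10)
  mu_r <- mu_q + sep
  truth_ref <- rep(c(FALSE, TRUE), each = n / 2)
  mch <- exp(ifelse(truth_ref, rnorm(n, mu_r, sdlog), rnorm(n, mu_q, sdlog)))
  ev <- data.frame(FSC = rep(1, n), SSC = rep(1, n), YFP = rep(1, n),
                   mCherry = mch)
  thr <- exp((mu_q + mu_r) / 2)
  q <- classify_events(ev, mcherry_threshold = thr)
  called_ref <- seq_len(n) %in% q$reference
  miss <- mean(called_ref != truth_ref)
  expect_lt(miss, 0.001)
  expected <- pnorm(-(sep / 2) / sdlog)  # per-event misclassification mass
  expect_lt(abs(miss - expected), 3 * sqrt(expected / n) + 1e-4)
})

test_that("samples with an empty population are unquantifiable", {
  ev <- data.frame(FSC = 1:10, SSC = 1:10, YFP = 1:10, mCherry = rep(1, 10))
  expect_error(classify_events(ev, mcherry_threshold = 100),
               "unquantifiable sample: empty reference")
  expect_error(classify_events(ev, mcherry_threshold = 0.5),
               "unquantifiable sample: empty query")
  expect_error(classify_events(ev, mcherry_threshold = -1),
               "strictly positive")
})

test_that("a 50:50 truth mixture is recovered within the binomial bound", {
  tr <- default_ground_truth("D", contamination = 0)
  exp <- simulate_competition("2222", "D", tr, init_fraction = 0.5,
                              n_events = 25000, seed = 31)
  q <- classify_events(exp$events[["0"]], mcherry_threshold = 100)
  expect_lt(abs(q$query_fraction - 0.5), 3 * sqrt(0.25 / 25000))
})

test_that("population ratios equal the brute-force label tally", {
  set.seed(502)
  n <- 5000
  mch <- c(rlnorm(3000, log(10), 0.2), rlnorm(2000, log(1000), 0.2))[sample(n)]
  ev <- data.frame(FSC = rep(1, n), SSC = rep(1, n), YFP = rep(1, n),
                   mCherry = mch)
  q <- classify_events(ev, mcherry_threshold = 100)
  expect_equal(population_ratio(q), sum(mch <= 100) / sum(mch > 100))
  # equal counts give odds 1; the environment-A target mix gives 3:7
  expect_equal(population_ratio(list(n_query = 50, n_reference = 50)), 1)
  expect_equal(population_ratio(list(n_query = 30, n_reference = 70)), 3 / 7)
})

test_that("normalized expression is the query/reference channel-mean ratio", {
  ev <- data.frame(FSC = rep(1, 6), SSC = rep(1, 6),
                   YFP = c(4, 6, 8, 0, 0, 0),
                   mCherry = c(1, 1, 1, 500, 1000, 1500))
  q <- classify_events(ev, mcherry_threshold = 100)
  expect_equal(q$normalized_expression, mean(c(4, 6, 8)) / 1000)
  expect_equal(normalized_expression(q), q$normalized_expression)
  # ratio identity and homogeneity
  ev2 <- ev
  ev2$YFP <- ev2$YFP * 2
  q2 <- classify_events(ev2, mcherry_threshold = 100)
  expect_equal(q2$normalized_expression, 2 * q$normalized_expression)
  ev3 <- ev
  ev3$YFP[1:3] <- 1000
  expect_equal(classify_events(ev3, 100)$normalized_expression, 1)
})

test_that("channel rescaling leaves fractions and expression unchanged", {
  tr <- default_ground_truth("C")
  exp <- simulate_competition("2221", "C", tr, n_events = 5000, seed = 32)
  ev <- exp$events[["24"]]
  for (const in c(0.25, 40)) {
    ev2 <- ev
    ev2[c("FSC", "SSC", "YFP", "mCherry")] <-
      ev[c("FSC", "SSC", "YFP", "mCherry")] * const
    q1 <- classify_events(apply_gate(ev))
    q2 <- classify_events(apply_gate(ev2))
    expect_equal(q2$query_fraction, q1$query_fraction)
    expect_equal(q2$normalized_expression, q1$normalized_expression,
                 tolerance = 1e-6)
  }
})

test_that("strain expression estimates average three timepoints per replicate
           with s.e.m. over replicates", {
  expect_equal(expression_estimate(c(5, 5, 5))$sem, 0)
  est <- expression_estimate(c(1, 2, 3))
  expect_equal(est$estimate, 2)
  expect_equal(est$sem, 1 / sqrt(3))
  # N = 9 replicates: s.e.m. divides by sqrt(9)
  est9 <- expression_estimate(1:9)
  expect_equal(est9$sem, sd(1:9) / 3)
  # data.frame path: replicate means of the three timepoints
  df <- expand.grid(replicate = 1:3, timepoint = c(0, 24, 48))
  df$value <- df$replicate + df$timepoint / 100
  est_df <- expression_estimate(df)
  expect_equal(est_df$estimate, 2.24)
  expect_error(expression_estimate(df[df$timepoint != 48, ]), "incomplete")
  expect_error(expression_estimate(7), "at least 2 replicates")
})

test_that("recovered expression is monotone in the ground truth across
           genotypes", {
  tr <- default_ground_truth("D")
  expr_hat <- vapply(genotype_codes(), function(code) {
    exp <- simulate_competition(code, "D", tr, n_events = 4000,
                                seed = derive_seed(33, code))
    mean(vapply(exp$events, function(ev)
      classify_events(apply_gate(ev))$normalized_expression, numeric(1)))
  }, numeric(1))
  rho <- cor(expr_hat, tr$expression[genotype_codes()], method = "spearman")
  expect_gt(rho, 0.95)
})
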