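# Overall and net epistatic deviations with error propagation and
# Holm-controlled Z-tests.

test_that("overall deviation is the departure from the product of
           single-reduction fitness values", {
  s <- make_summary(1, sem = 0)
  s$w[s$genotype == "1122"] <- 0.9  # GAL2+GAL3 both halved
  d <- overall_deviation(c("GAL2", "GAL3"), s)
  expect_equal(d$epsilon, -0.1)
  # multiplicative lattice: every deviation vanishes
  m <- multiplicative_summary(c(GAL2 = 0.9, GAL3 = 1.1, GAL4 = 0.8,
                                GAL80 = 1.05), sem = 0)
  for (M in gene_sets()) {
    expect_equal(overall_deviation(M, m)$epsilon, 0, tolerance = 1e-12)
    expect_equal(net_deviation(M, m)$epsilon, 0, tolerance = 1e-12)
  }
  expect_error(overall_deviation("GAL2", s), "undefined")
})

test_that("the delta-method SE at unit fitness is s * sqrt(1 + |M|)", {
  for (sval in c(0.01, 0.05)) {
    s <- make_summary(1, sem = sval)
    for (M in gene_sets()) {
      d <- overall_deviation(M, s)
      expect_equal(d$se, sval * sqrt(1 + length(M)))
    }
  }
})

test_that("the net-deviation recursion equals the printed signed expansion
           on random lattices", {
  for (seed in 1:50) {
    s <- random_summary(900 + seed)
    for (M in gene_sets(min_size = 3)) {
      expect_equal(net_deviation(M, s)$epsilon, expansion_net(M, s),
                   tolerance = 1e-12)
    }
    # base case: pairs have net = overall
    for (M in gene_sets(2, 2))
      expect_equal(net_deviation(M, s)$epsilon,
                   overall_deviation(M, s)$epsilon)
  }
})

test_that("net deviations reconstruct every overall deviation exactly", {
  for (seed in 1:25) {
    s <- random_summary(950 + seed)
    for (M in gene_sets()) {
      subs <- Filter(function(x) length(x) >= 2,
                     unlist(lapply(seq_along(M), function(k)
                       utils::combn(M, k, simplify = FALSE)),
                       recursive = FALSE))
      total <- sum(vapply(subs, function(S) net_deviation(S, s)$epsilon,
                          numeric(1)))
      expect_equal(total, overall_deviation(M, s)$epsilon, tolerance = 1e-12)
    }
  }
})

test_that("per environment there are 11 overall and 5 higher-order net
           deviations", {
  s <- random_summary(980)
  tab <- epistasis_table(s)
  expect_equal(nrow(tab), 11)
  expect_equal(sum(tab$order >= 3), 5)
  expect_equal(sum(!is.na(tab$p_holm)), 11)
  expect_equal(sum(!is.na(tab$p_holm_net)), 5)
  expect_equal(sum(tab$order == 3), 4)
})

test_that("a third-order net deviation draws on 7 distinct fitness values", {
  expect_equal(net_deviation_fitness_terms(c("GAL2", "GAL3", "GAL4")), 7)
  expect_equal(net_deviation_fitness_terms(gal_genes()), 15)
  expect_equal(net_deviation_fitness_terms(c("GAL2", "GAL3")), 3)
})

test_that("Z-test and Holm step-down behave on the reference cases", {
  # exact null
  r0 <- epistasis_significance(0, 0.05)
  expect_equal(r0$p, 1)
  expect_false(r0$sig_0.05)
  # the two-tailed 5% quantile
  r <- epistasis_significance(1.959964 * 0.01, 0.01)
  expect_equal(r$p, 0.05, tolerance = 1e-5)
  # Holm: {0.001, 0.02, 0.03} all rejected at 0.05
  z <- -qnorm(c(0.001, 0.02, 0.03) / 2)
  r3 <- epistasis_significance(z * 0.1, rep(0.1, 3))
  expect_equal(r3$p, c(0.001, 0.02, 0.03), tolerance = 1e-10)
  expect_true(all(r3$sig_0.05))
  expect_error(epistasis_significance(0.1, 0), "untestable")
})

test_that("decisions are monotone in alpha and stars match the levels", {
  s <- random_summary(981)
  s$sem <- s$sem / 10
  tab <- epistasis_table(s)
  expect_true(all(tab$sig_0.0001 <= tab$sig_0.001))
  expect_true(all(tab$sig_0.001 <= tab$sig_0.01))
  expect_true(all(tab$sig_0.01 <= tab$sig_0.05))
  expect_equal(nchar(tab$stars),
               tab$sig_0.05 + tab$sig_0.01 + tab$sig_0.001 + tab$sig_0.0001)
})

test_that("injected interactions are detected with power increasing in
           effect size", {
  sem <- 0.02
  power_at <- function(eff) {
    hits <- vapply(1:60, function(i) {
      set.seed(2000 + i + round(1e4 * eff))
      s <- make_summary(1 + rnorm(16, 0, sem), sem = sem)
      s$w[s$genotype == "1122"] <- 1 + eff + rnorm(1, 0, sem)
      tab <- epistasis_table(s)
      tab$sig_0.05[tab$set == "GAL2+GAL3"]
    }, logical(1))
    mean(hits)
  }
  p <- vapply(c(0.05, 0.12, 0.25), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], p[1])
})
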