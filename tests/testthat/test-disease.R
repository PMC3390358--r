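test_that("risk assignment follows the GRR model with a probability cap", {
  s15 <- disease_scenario("c", 2, c(0.1, 0.3), grr = 1.5, baseline = 0.15)
  s3 <- disease_scenario("r", 2, c(0.005, 0.04), grr = 3, baseline = 0.15)
  g <- rbind(c(0, 0), c(1, 0), c(0, 2), c(1, 1))
  expect_equal(assign_risk(g, s15), c(0.15, 0.225, 0.15 * 1.5^2, 0.15 * 1.5^2))
  expect_equal(assign_risk(g, s3)[3], 1)            # min(1, 0.15 * 9)
  expect_equal(assign_risk(matrix(0, 3, 2), s3), rep(0.15, 3))
  expect_error(assign_risk(matrix(3, 1, 1), s3), "0, 1 or 2")
  # carrier rule: one factor regardless of copy number
  sc <- disease_scenario("c", 2, c(0.1, 0.3), 3, rule = "carrier")
  expect_equal(assign_risk(g, sc), c(0.15, 0.45, 0.45, 0.45))
})

test_that("risk is non-decreasing in the allele count, strictly below the cap", {
  s <- disease_scenario("r", 5, c(0.005, 0.04), 3)
  a <- 0:10
  p <- assign_risk(cbind(pmin(a, 2), pmin(pmax(a - 2, 0), 2),
                         pmin(pmax(a - 4, 0), 2), pmin(pmax(a - 6, 0), 2),
                         pmin(pmax(a - 8, 0), 2)), s)
  expect_true(all(diff(p) >= 0))
  below <- p < 1
  expect_true(all(diff(p[below]) > 0))
})

test_that("causal selection honours the frequency window, locus bounds and seed", {
  set.seed(31)
  freqs <- runif(300, 0.001, 0.45)
  p <- toy_panel(n_hap = 2000, freqs = freqs, spacing_bp = 500, seed = 31)
  scen <- disease_scenario("r", 5, c(0.005, 0.04), 3)
  bounds <- c(20000, 100000)
  cs <- select_causal(p, scen, bounds, seed = 7)
  expect_equal(nrow(cs), 5)
  expect_true(all(cs$freq >= 0.005 & cs$freq <= 0.04))
  expect_true(all(cs$bp >= bounds[1] & cs$bp <= bounds[2]))
  expect_identical(cs, select_causal(p, scen, bounds, seed = 7))
  # requesting more variants than are eligible errors with the count
  narrow <- disease_scenario("r", 200, c(0.005, 0.04), 3)
  expect_error(select_causal(p, narrow, bounds, seed = 1), "eligible")
})

test_that("singleton variants are never selected as causal", {
  n_hap <- 1000
  H <- cbind(matrix(rbinom(n_hap * 5, 1, 0.02), n_hap),
             c(1L, rep(0L, n_hap - 1)))           # singleton, freq 0.001
  p <- haplotype_panel(H, seq_len(6) * 100, seq_len(6) * 1e-3)
  scen <- disease_scenario("r", 2, c(0.0005, 0.04), 3)
  for (s in 1:100) {
    cs <- select_causal(p, scen, c(1, 1000), seed = s)
    expect_false(6 %in% cs$index)
  }
})

test_that("disease status counts match the exact binomial null", {
  n <- 10000
  ph <- sample_case_control(rep(0.15, n), 1000, 1000, seed = 4)
  aff <- sum(ph$status)
  expect_gte(aff, qbinom(5e-4, n, 0.15))
  expect_lte(aff, qbinom(1 - 5e-4, n, 0.15))
  expect_length(ph$cases, 1000)
  expect_length(ph$controls, 1000)
  expect_true(all(ph$status[ph$cases] == 1))
  expect_true(all(ph$status[ph$controls] == 0))
  expect_identical(ph, sample_case_control(rep(0.15, n), 1000, 1000, seed = 4))
})

test_that("degenerate risks and short pools raise informative errors", {
  expect_error(sample_case_control(rep(1, 100), 10, 10, seed = 1),
               "unaffected")
  expect_error(sample_case_control(rep(0.5, 10), 9, 9, seed = 1),
               "population smaller")
})

test_that("cases are enriched for risk alleles at causal variants", {
  scen <- disease_scenario("r", 3, c(0.005, 0.04), grr = 3)
  set.seed(88)
  n <- 4000
  G <- cbind(rbinom(n, 2, 0.02), rbinom(n, 2, 0.03), rbinom(n, 2, 0.01))
  risk <- assign_risk(G, scen)
  wins <- 0; total <- 0
  for (r in 1:20) {
    ph <- sample_case_control(risk, 400, 400, seed = 200 + r)
    fc <- colMeans(G[ph$cases, , drop = FALSE])
    fk <- colMeans(G[ph$controls, , drop = FALSE])
    wins <- wins + sum(fc > fk); total <- total + 3
  }
  expect_lt(binom.test(wins, total, 0.5, alternative = "greater")$p.value,
            0.01)
})

test_that("with GRR 1 the affected fraction matches the baseline risk", {
  scen <- disease_scenario("n", 2, c(0.1, 0.3), grr = 1, baseline = 0.15)
  set.seed(5)
  G <- cbind(rbinom(5000, 2, 0.2), rbinom(5000, 2, 0.2))
  risk <- assign_risk(G, scen)
  expect_true(all(risk == 0.15))
  ph <- sample_case_control(risk, 500, 500, seed = 6)
  expect_gt(binom.test(sum(ph$status), 5000, 0.15)$p.value, 0.001)
})

test_that("null assignment is label-only and seed-sensitive", {
  a <- null_assignment(5000, 1000, 1000, seed = 1)
  b <- null_assignment(5000, 1000, 1000, seed = 2)
  expect_length(a$cases, 1000)
  expect_length(a$controls, 1000)
  expect_length(intersect(a$cases, a$controls), 0)
  expect_false(identical(a$cases, b$cases))
  # labels uncorrelated with arbitrary genotype columns
  set.seed(3)
  G <- matrix(rbinom(5000 * 50, 2, 0.3), 5000)
  idx <- c(a$cases, a$controls)
  y <- rep(1:0, each = 1000)
  cors <- suppressWarnings(cor(G[idx, ], y))
  expect_lt(abs(mean(cors)), 0.05)
  expect_error(null_assignment(10, 9, 9, seed = 1), "population smaller")
})
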