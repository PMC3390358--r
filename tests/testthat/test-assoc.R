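test_that("logistic beta on a binary predictor equals the 2x2 log odds ratio", {
  g <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  y <- rep(1:0, each = 100)
  r <- logistic_assoc(g, y)
  expect_equal(r$beta, log(30 * 90 / (70 * 10)), tolerance = 1e-6)
  expect_equal(r$flag, "ok")
})

test_that("the scan's MLE matches glm() on 0/1/2 dosages", {
  set.seed(17)
  for (f in c(0.05, 0.2, 0.4)) {
    g <- rbinom(600, 2, f)
    y <- rbinom(600, 1, plogis(-0.5 + 0.4 * g))
    r <- logistic_assoc(g, y)
    fit <- glm(y ~ g, family = binomial)
    expect_equal(r$beta, unname(coef(fit)[2]), tolerance = 1e-5)
    expect_equal(r$se, unname(summary(fit)$coefficients[2, 2]),
                 tolerance = 1e-5)
    expect_equal(r$p, unname(summary(fit)$coefficients[2, 4]),
                 tolerance = 1e-4)
  }
})

test_that("a constant dosage is flagged monomorphic with NA results", {
  r <- logistic_assoc(rep(1, 100), rep(0:1, 50))
  expect_identical(r$flag, "monomorphic")
  expect_true(is.na(r$beta) && is.na(r$p))
  expect_error(logistic_assoc(rbinom(10, 2, 0.5), rep(1, 10)), "both")
})

test_that("separated markers fall back to a finite Firth estimate", {
  # all 16 carriers are cases: plain MLE diverges
  g <- c(rep(1, 16), rep(0, 184), rep(0, 200))
  y <- rep(1:0, each = 200)
  r <- logistic_assoc(g, y)
  expect_identical(r$flag, "firth")
  expect_true(is.finite(r$beta) && is.finite(r$se) && r$beta > 0)
  expect_lt(r$p, 0.05)
})

test_that("null p-values are uniform across a marker panel", {
  set.seed(23)
  n_hap <- 1000; m <- 2000
  H <- vapply(runif(m, 0.05, 0.5), function(f) rbinom(n_hap, 1, f),
              integer(n_hap))
  p <- haplotype_panel(H, seq_len(m) * 100, seq_len(m) * 1e-4)
  map <- recomb_map(c(1, m * 100), c(0, m * 100 * 1e-4))
  ph <- null_assignment(n_hap / 2, 250, 250, seed = 3)
  res <- region_scan(p, seq_len(m), ph, NULL, c(1, m * 100), map,
                     flank_cm = 0, alpha = 0.05)
  # identical 2x3 dosage tables give tied p-values; ties only make the KS
  # test conservative here
  ks <- suppressWarnings(ks.test(res$p[!res$monomorphic], "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Bonferroni threshold and window boundary follow the stated rules", {
  # dyadic map: 1/128 cM per bp; locus [129, 257] spans cM [1, 2]
  map <- dyadic_map()
  bp <- c(130, 150, 200, 641, 649)   # cm: ~1, ~1.16, ~1.55, 5 (edge), 5.0625
  set.seed(9)
  H <- vapply(seq_along(bp), function(j) rbinom(400, 1, 0.3), integer(400))
  p <- haplotype_panel(H, bp, genetic_position(bp, map))
  ph <- null_assignment(200, 80, 80, seed = 2)
  res <- region_scan(p, seq_along(bp), ph, NULL, c(129, 257), map,
                     flank_cm = 3, alpha = 0.05)
  # marker exactly at locus end + 3 cM is included; beyond is excluded
  expect_true(641 %in% res$bp)
  expect_false(649 %in% res$bp)
  expect_equal(attr(res, "threshold"), 0.05 / attr(res, "n_tested"))
  expect_equal(attr(res, "n_tested"), 4)
})

test_that("causal variants on the array are excluded from the scan", {
  p <- toy_panel(n_hap = 400, freqs = rep(0.3, 10), spacing_bp = 1000,
                 seed = 4)
  map <- recomb_map(c(1, 11000), c(0, 0.11))
  causal <- data.frame(index = 4L, id = p$variants$id[4],
                       bp = p$variants$bp[4], cm = p$variants$cm[4],
                       freq = p$variants$freq[4])
  ph <- null_assignment(200, 80, 80, seed = 5)
  res <- region_scan(p, 1:10, ph, causal, c(1, 11000), map, flank_cm = 1)
  expect_false(causal$bp %in% res$bp)
  expect_equal(nrow(res), 9)
  expect_error(region_scan(p, integer(0), ph, NULL, c(1, 11000), map, 1),
               "no testable markers")
})

test_that("scan power at a common causal variant is well calibrated", {
  # single common causal placed on the array: median estimated OR across
  # replicates within 15% of the per-allele odds ratio implied by the model
  sim <- simulate_panel(demography("constant"), 1e5, 0.3, 120, seed = 8)
  mk <- ascertain_array(sim$panel, seed = 2)
  locus <- which(sim$panel$variants$bp >= sim$locus_bounds[1] &
                 sim$panel$variants$bp <= sim$locus_bounds[2])
  sub <- subset_panel(sim$panel, sort(unique(c(mk, locus))))
  ex <- resample_mosaic(sub, 2 * 4000, map = sim$map, seed = 5)
  G <- .hap_dosage(ex$haplotypes)
  scen <- disease_scenario("c1", 1, c(0.1, 0.3), grr = 1.5)
  cand <- which(ex$variants$freq > 0.15 & ex$variants$freq < 0.25 &
                ex$variants$bp >= sim$locus_bounds[1] &
                ex$variants$bp <= sim$locus_bounds[2])
  set.seed(1)
  cv <- sample(cand, 1)
  risk <- assign_risk(G[, cv, drop = FALSE], scen)
  ors <- vapply(1:30, function(r) {
    ph <- sample_case_control(risk, 400, 400, seed = 100 + r)
    fit <- logistic_assoc(G[c(ph$cases, ph$controls), cv],
                          rep(1:0, c(400, 400)))
    exp(fit$beta)
  }, numeric(1))
  or_true <- (0.225 / 0.775) / (0.15 / 0.85)
  expect_lt(abs(median(ors) / or_true - 1), 0.15)
})
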