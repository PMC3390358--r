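test_that("zero mutation rate yields a panel with zero variants", {
  sim <- simulate_panel(demography("constant", mu = 0), 1e4, 0, 10, seed = 1)
  expect_equal(ncol(sim$panel$haplotypes), 0)
})

test_that("segregating-site count matches the Watterson expectation", {
  n <- 100
  theta <- 4 * 1e4 * 1.2e-8 * 1e5          # theta for the whole 100-kb locus
  a <- sum(1 / seq_len(n - 1))
  b <- sum(1 / seq_len(n - 1)^2)
  sd_S <- sqrt(theta * a + theta^2 * b)     # no-recombination (conservative)
  sim <- simulate_panel(demography("constant"), 1e5, 0, n, seed = 42)
  S <- ncol(sim$panel$haplotypes)
  expect_gt(S, theta * a - 3 * sd_S)
  expect_lt(S, theta * a + 3 * sd_S)
})

test_that("growth demography enriches rare variants relative to constant size", {
  for (s in 1:5) {
    pc <- simulate_panel(demography("constant"), 5e4, 0, 100, seed = s)$panel
    pg <- simulate_panel(demography("bottleneck_growth"), 5e4, 0, 100,
                         seed = s)$panel
    expect_gt(mean(pg$variants$maf < 0.04), mean(pc$variants$maf < 0.04))
  }
})

test_that("panel simulation is deterministic given the seed and validates input", {
  a <- simulate_panel(demography("constant"), 2e4, 0, 20, seed = 9)
  b <- simulate_panel(demography("constant"), 2e4, 0, 20, seed = 9)
  expect_identical(a$panel$haplotypes, b$panel$haplotypes)
  expect_identical(a$panel$variants, b$panel$variants)
  expect_error(simulate_panel(demography("constant"), -1, 0, 20, seed = 1),
               "locus_length")
  expect_error(simulate_panel(demography("constant"), 1e4, 0, 2, seed = 1),
               "n_hap")
})

test_that("panel container enforces its invariants and recomputes MAF", {
  expect_error(haplotype_panel(matrix(2L, 2, 1), 1, 0), "0 or 1")
  expect_error(haplotype_panel(matrix(0L, 3, 1), 1, 0), "even")
  expect_error(haplotype_panel(matrix(0L, 2, 2), c(5, 5), c(0, 0)), "sorted")
  p <- haplotype_panel(matrix(c(1L, 1L, 1L, 0L), 2), c(1, 2), c(0, 0))
  expect_equal(p$variants$maf, c(0, 0.5))   # 1-allele freq 1 has MAF 0
})

test_that("mosaic resampling with lambda = 0 copies panel haplotypes exactly", {
  p <- toy_panel(n_hap = 20, freqs = rep(0.4, 30), seed = 2)
  out <- resample_mosaic(p, 50, params = mosaic_params(lambda = 1e-12, eps = 0),
                         seed = 3)
  key <- apply(p$haplotypes, 1, paste, collapse = "")
  expect_true(all(apply(out$haplotypes, 1, paste, collapse = "") %in% key))
})

test_that("a panel of identical haplotypes resamples to identical outputs", {
  H <- matrix(rep(c(0L, 1L, 1L, 0L, 1L), each = 10), nrow = 10)
  p <- haplotype_panel(H, seq_len(5) * 100, seq_len(5) * 1e-3)
  out <- resample_mosaic(p, 20, params = mosaic_params(lambda = 5, eps = 0),
                         seed = 1)
  expect_true(all(apply(out$haplotypes, 1, identical, H[1, ])))
})

test_that("mosaic output frequencies stay inside exact binomial bounds", {
  freqs <- c(0.05, 0.1, 0.25, 0.5, 0.4, 0.15, 0.3, 0.2)
  p <- toy_panel(n_hap = 400, freqs = freqs, seed = 5)
  f_panel <- p$variants$freq
  n_out <- 4000
  out <- resample_mosaic(p, n_out, params = mosaic_params(lambda = 2, eps = 0),
                         seed = 6)
  cnt <- colSums(out$haplotypes)
  lo <- qbinom(5e-4, n_out, f_panel)
  hi <- qbinom(1 - 5e-4, n_out, f_panel)
  expect_true(all(cnt >= lo & cnt <= hi))
})

test_that("binned LD of the panel is preserved through mosaic expansion", {
  sim <- simulate_panel(demography("bottleneck_growth"), 1e5, 0.75, 80,
                        seed = 3)
  common <- which(sim$panel$variants$maf > 0.1)
  common <- common[round(seq(1, length(common), length.out = 120))]
  sub <- subset_panel(sim$panel, common)
  ex <- resample_mosaic(sub, 2000, seed = 9)
  r2p <- suppressWarnings(cor(sub$haplotypes)^2)
  r2e <- suppressWarnings(cor(ex$haplotypes)^2)
  d <- abs(outer(sub$variants$cm, sub$variants$cm, "-"))
  ut <- upper.tri(d)
  bins <- cut(d[ut], breaks = seq(0, 0.2, by = 0.01))
  mp <- tapply(r2p[ut], bins, mean, na.rm = TRUE)
  me <- tapply(r2e[ut], bins, mean, na.rm = TRUE)
  keep <- !is.na(mp) & !is.na(me)
  expect_true(any(keep))
  expect_lt(max(abs(me[keep] - mp[keep])), 0.05)
})

test_that("very fast switching decouples sites (r2 ~ 0 at >= 1 cM)", {
  sim <- simulate_panel(demography("constant"), 1e5, 0.8, 60, seed = 3)
  common <- which(sim$panel$variants$maf > 0.1)
  common <- common[round(seq(1, length(common), length.out = 120))]
  sub <- subset_panel(sim$panel, common)
  ex <- resample_mosaic(sub, 1000,
                        params = mosaic_params(lambda = 1e5, eps = 0),
                        seed = 4)
  r2u <- suppressWarnings(cor(ex$haplotypes)^2)
  d <- abs(outer(sub$variants$cm, sub$variants$cm, "-"))
  far <- d >= 1 & upper.tri(d)
  expect_gt(sum(far), 100)
  expect_lt(mean(r2u[far], na.rm = TRUE), 0.02)
})

test_that("array ascertainment respects the MAF floor and the spacing rules", {
  sim <- simulate_panel(demography("constant"), 5e4, 0, 100, seed = 12)
  p <- sim$panel
  expect_warning(mk <- ascertain_array(p, maf_floor = 0.5, seed = 1),
                 "empty")
  expect_length(mk, 0)
  mk <- ascertain_array(p, maf_floor = 0.05, target_spacing = 2000, seed = 1)
  expect_true(all(p$variants$maf[mk] >= 0.05))
  expect_identical(mk, ascertain_array(p, 0.05, 2000, seed = 1))
  # spacing <= min gap keeps every eligible variant
  gap <- min(diff(p$variants$bp))
  mk0 <- ascertain_array(p, maf_floor = 0, target_spacing = max(1, gap),
                         seed = 1)
  expect_length(mk0, ncol(p$haplotypes))
  # mean spacing is near the target
  sp <- mean(diff(p$variants$bp[mk]))
  expect_gt(sp, 1000); expect_lt(sp, 4000)
})

test_that("panels and maps round-trip through VCF + map files bit-exact", {
  sim <- simulate_panel(demography("constant"), 2e4, 0.02, 10, seed = 5)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  mp <- withr::local_tempfile(fileext = ".map")
  write_panel(sim$panel, sim$map, vcf, mp)
  rt <- read_panel(vcf, mp)
  expect_identical(rt$panel$haplotypes, sim$panel$haplotypes)
  expect_identical(rt$panel$variants$bp, sim$panel$variants$bp)
  expect_identical(rt$panel$variants$cm, sim$panel$variants$cm)
  expect_identical(rt$map$bp, sim$map$bp)
  expect_identical(rt$map$cm, sim$map$cm)
})

test_that("unphased or missing genotypes are rejected with the record coordinate", {
  sim <- simulate_panel(demography("constant"), 2e4, 0, 10, seed = 5)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  mp <- withr::local_tempfile(fileext = ".map")
  write_panel(sim$panel, sim$map, vcf, mp)
  l <- readLines(vcf)
  i <- grep("^[^#]", l)[3]
  pos <- strsplit(l[i], "\t")[[1]][2]
  f <- strsplit(l[i], "\t")[[1]]
  f[10] <- sub("|", "/", f[10], fixed = TRUE)
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(replace(l, i, paste(f, collapse = "\t")), bad)
  expect_error(read_panel(bad, mp), paste0("unphased.*", pos))
  f[10] <- ".|."
  writeLines(replace(l, i, paste(f, collapse = "\t")), bad)
  expect_error(read_panel(bad, mp), paste0("missing.*", pos))
})

test_that("a genetic map with decreasing cumulative cM is rejected", {
  f <- withr::local_tempfile()
  writeLines(c("position rate map", "100 1 1.0", "200 1 0.5"), f)
  expect_error(read_genetic_map(f), "non-decreasing")
  expect_error(recomb_map(c(10, 5), c(0, 1)), "increasing")
})
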