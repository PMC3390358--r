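test_that("r2 matches hand-computed haplotype values", {
  H <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0))
  p <- haplotype_panel(H[rep(1:4, 25), ], c(10, 20, 30), c(1, 2, 3) * 1e-3)
  expect_equal(r2(p, 1, 1), 1)          # a variant with itself
  expect_equal(r2(p, 1, 2), 1)          # AB=2, ab=2: D = 0.25, r2 = 1
  expect_equal(r2(p, 1, 3), 0)          # all four gametes equally frequent
  mono <- haplotype_panel(cbind(rep(0L, 4), c(1L, 0L, 1L, 0L)), c(1, 2),
                          c(0, 0))
  expect_error(r2(mono, 1, 2), "monomorphic")
})

test_that("r2 is symmetric, relabel-invariant and equals squared correlation", {
  set.seed(42)
  for (i in 1:10) {
    x <- rbinom(200, 1, runif(1, 0.1, 0.9))
    y <- as.integer(xor(x, rbinom(200, 1, 0.3)))
    if (var(x) == 0 || var(y) == 0) next
    p <- haplotype_panel(cbind(x, y, 1L - x), c(1, 2, 3), c(1, 2, 3) * 1e-5)
    expect_equal(r2(p, 1, 2), r2(p, 2, 1))
    expect_equal(r2(p, 1, 2), r2(p, 3, 2))       # 0 <-> 1 relabeling
    expect_equal(r2(p, 1, 2), cor(x, y)^2)       # independent route
  }
})

test_that("genetic positions interpolate and extrapolate as specified", {
  m <- recomb_map(c(100, 200), c(1, 2))
  expect_equal(genetic_position(150, m), 1.5)
  expect_equal(genetic_position(c(100, 200), m), c(1, 2))
  expect_equal(genetic_position(250, m), 2.5)    # terminal-rate extrapolation
  expect_equal(genetic_position(50, m), 0.5)
  set.seed(11)
  bp <- sort(sample(1e6, 20))
  mm <- recomb_map(bp, cumsum(runif(20, 0, 0.5)))
  q <- sort(sample(1.2e6, 500))
  expect_true(all(diff(genetic_position(q, mm)) >= 0))  # monotone
})

test_that("association distance picks the highest-r2 causal with stated tie-breaks", {
  set.seed(7)
  x <- rbinom(600, 1, 0.4)
  mk_flip <- function(fp) as.integer(xor(x, rbinom(600, 1, fp)))
  # causal columns with increasing LD to the marker x at column 1
  H <- cbind(x, mk_flip(0.45), mk_flip(0.02), mk_flip(0.25), x, x)
  bp <- c(500, 100, 300, 700, 900, 1100)
  ord <- order(bp)
  p <- haplotype_panel(H[, ord], bp[ord], bp[ord] * 1e-5)
  mcol <- which(bp[ord] == 500)
  assoc <- data.frame(marker = "m", index = mcol, bp = 500, cm = 500e-5,
                      maf = 0.4, p = 1e-12, significant = TRUE)
  # three imperfect causals: argmax r2 must match brute force
  causal3 <- data.frame(index = match(c(100, 300, 700), bp[ord]),
                        id = c("a", "b", "c"), bp = c(100, 300, 700),
                        cm = c(100, 300, 700) * 1e-5)
  causal3$freq <- colMeans(p$haplotypes[, causal3$index])
  d <- assoc_distance(assoc, causal3, p)
  brute <- vapply(causal3$index, function(j) r2(p, mcol, j), numeric(1))
  expect_equal(d$causal_id, causal3$id[which.max(brute)])
  expect_equal(d$r2, max(brute))
  expect_equal(d$dist_cm, abs(500 - causal3$bp[which.max(brute)]) * 1e-5)
  # closest causal never further than the highest-r2 causal
  expect_lte(d$dist_closest_cm, d$dist_cm)
  # r2 tie between two perfect copies: the genetically nearer one wins
  causal2 <- data.frame(index = match(c(900, 1100), bp[ord]),
                        id = c("near", "far"), bp = c(900, 1100),
                        cm = c(900, 1100) * 1e-5, freq = mean(x))
  d2 <- assoc_distance(assoc, causal2, p)
  expect_equal(d2$causal_id, "near")
  # perfect LD at the same genetic position: distance 0
  causal0 <- data.frame(index = mcol, id = "self", bp = 500, cm = 500e-5,
                        freq = mean(x))
  expect_equal(assoc_distance(assoc, causal0, p)$dist_cm, 0)
})

test_that("capture curves are exact on a hand-counted fixture and monotone", {
  d <- data.frame(test = c("t1", "t1", "t2", "t3"),
                  dist_cm = c(0.5, 0.01, 0.2, 3))
  cc <- capture_curve(d, windows = c(0, 0.1, 1, 5))
  expect_equal(cc$fraction, c(0, 1 / 3, 2 / 3, 1))
  expect_true(all(diff(cc$fraction) >= 0))
  expect_equal(capture_curve(d, windows = max(d$dist_cm))$fraction, 1)
  expect_error(capture_curve(d[0, ]), "no distance records")
})

test_that("D' confidence intervals separate perfect LD from equilibrium", {
  set.seed(19)
  x <- rbinom(2000, 1, 0.4)
  p <- haplotype_panel(cbind(x, x, rbinom(2000, 1, 0.4)),
                       c(100, 200, 300), c(1, 2, 3) * 1e-3)
  ci <- dprime_ci(p, 1, 2)
  expect_equal(unname(ci["dprime"]), 1)
  expect_gte(unname(ci["low"]), 0.7)
  expect_gte(unname(ci["high"]), 0.98)
  ci0 <- dprime_ci(p, 1, 3)
  expect_lt(unname(ci0["high"]), 0.9)
})

test_that("Gabriel blocks: strong-LD pairs form a block, equilibrium does not", {
  set.seed(20)
  x <- rbinom(2000, 1, 0.4)
  flip <- function(fp) as.integer(xor(x, rbinom(2000, 1, fp)))
  H <- cbind(x, flip(0.01), rbinom(2000, 1, 0.3), rbinom(2000, 1, 0.3))
  p <- haplotype_panel(H, c(1000, 2000, 50000, 80000),
                       c(0.001, 0.002, 0.05, 0.08))
  bl <- ld_blocks(p, 1:4)
  expect_equal(nrow(bl), 1)
  expect_equal(c(bl$first, bl$last), c(1, 2))
  # flank arithmetic: every block spans >= 0.001 cM after flanking
  expect_true(all(bl$cm_end - bl$cm_start >= 0.001))
  expect_equal(bl$cm_start, 0.001 - 0.0005)
  expect_equal(bl$cm_end, 0.002 + 0.0005)
  # independent markers: no blocks
  He <- vapply(1:6, function(j) rbinom(2000, 1, 0.3), integer(2000))
  pe <- haplotype_panel(He, (1:6) * 1000, (1:6) * 0.01)
  expect_equal(nrow(ld_blocks(pe, 1:6)), 0)
})

test_that("block capture counts associations by hand on a small fixture", {
  blocks <- data.frame(first = c(1L, 3L), last = c(2L, 4L),
                       bp_start = c(100, 500), bp_end = c(200, 600),
                       cm_start = c(0.0995, 0.4995), cm_end = c(0.2005, 0.6005),
                       n_markers = c(2L, 2L))
  assoc <- data.frame(marker = letters[1:5], bp = 1:5,
                      cm = c(0.10, 0.15, 0.50, 0.60, 0.90),
                      maf = 0.2, p = 1e-9, significant = TRUE)
  causal <- data.frame(index = 1L, id = "c", bp = 150, cm = 0.12, freq = 0.02)
  bc <- block_capture(assoc, blocks, causal)
  # a, b sit in block 1 which holds the causal; c, d in block 2 (no causal);
  # e is outside every block
  expect_equal(bc$captured, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(bc$fraction, 2 / 5)
  causal2 <- rbind(causal, data.frame(index = 2L, id = "c2", bp = 550,
                                      cm = 0.55, freq = 0.02))
  expect_equal(block_capture(assoc, blocks, causal2)$fraction, 4 / 5)
})
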