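#' Haplotype-based r-squared between two variants
#'
#' `r2 = (p_ab - p_a p_b)^2 / (p_a (1 - p_a) p_b (1 - p_b))` from phased
#' haplotype counts. Symmetric in its arguments and invariant under allele
#' relabeling at either site.
#'
#' @param panel a [haplotype_panel()].
#' @param a,b variant column indices.
#' @return r-squared in `[0, 1]`.
#' @export
r2 <- function(panel, a, b) {
  x <- panel$haplotypes[, a]
  y <- panel$haplotypes[, b]
  pa <- mean(x); pb <- mean(y)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    stop("r2 undefined for a monomorphic variant")
  pab <- mean(x & y)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# r2 between two sets of columns; NA for monomorphic columns
r2_matrix <- function(H, ia, ib) {
  A <- H[, ia, drop = FALSE]
  B <- H[, ib, drop = FALSE]
  suppressWarnings(stats::cor(A, B)^2)
}

#' D' point estimate and confidence interval for a variant pair
#'
#' Normalised disequilibrium coefficient with a Gabriel-style confidence
#' interval: the multinomial likelihood of the phased two-locus haplotype
#' counts is evaluated on a grid of |D'| values in `[0, 1]` and 5% of the
#' normalised mass is cut from each end.
#'
#' @param panel a [haplotype_panel()].
#' @param a,b variant column indices.
#' @param step grid step for the likelihood.
#' @param tail tail mass removed at each end.
#' @return named vector `dprime`, `low`, `high`.
#' @export
dprime_ci <- function(panel, a, b, step = 0.005, tail = 0.05) {
  x <- panel$haplotypes[, a]
  y <- panel$haplotypes[, b]
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  .dprime_ci(n11, n10, n01, n00, step, tail)
}

#' Distance from significant associations to their highest-r2 causal variant
#'
#' For each significant association, identifies the causal variant with which
#' it is in highest LD (r2, computed on the phased expanded haplotypes); ties
#' are broken by smaller genetic distance, then smaller bp. Records the
#' genetic distance to that variant and to the closest causal variant.
#'
#' @param assoc an `association_result` (see [region_scan()]); only
#'   significant rows are used.
#' @param causal a non-empty `causal_set`.
#' @param panel the expanded [haplotype_panel()] (for r2).
#' @param map unused placeholder for a custom map (distances use the cM
#'   stored on markers and causal variants).
#' @return data frame with one row per significant association: `marker`,
#'   `bp`, `cm`, `maf`, `p`, `causal_id`, `r2`, `dist_cm` (to the highest-r2
#'   causal) and `dist_closest_cm`.
#' @export
assoc_distance <- function(assoc, causal, panel, map = NULL) {
  stopifnot(nrow(causal) >= 1)
  sig <- assoc[which(assoc$significant), , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(marker = character(0), bp = numeric(0), cm = numeric(0),
                      maf = numeric(0), p = numeric(0),
                      causal_id = character(0), r2 = numeric(0),
                      dist_cm = numeric(0), dist_closest_cm = numeric(0)))
  }
  R <- r2_matrix(panel$haplotypes, sig$index, causal$index)
  pick <- integer(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    ri <- R[i, ]
    ri[is.na(ri)] <- -Inf
    best <- which(ri == max(ri))
    if (length(best) > 1) {                      # tie-break: genetic proximity
      d <- abs(causal$cm[best] - sig$cm[i])
      best <- best[d == min(d)]
      if (length(best) > 1) best <- best[which.min(causal$bp[best])]
    }
    pick[i] <- best[1]
  }
  data.frame(marker = sig$marker, bp = sig$bp, cm = sig$cm, maf = sig$maf,
             p = sig$p, causal_id = causal$id[pick],
             r2 = R[cbind(seq_len(nrow(sig)), pick)],
             dist_cm = abs(sig$cm - causal$cm[pick]),
             dist_closest_cm = vapply(sig$cm, function(cmi)
               min(abs(causal$cm - cmi)), numeric(1)))
}

#' Capture curve over resequencing window sizes
#'
#' For each window size w, the fraction of tests (among tests contributing at
#' least one significant association) that have at least one association
#' whose highest-r2 causal variant lies within w cM.
#'
#' @param distances data frame with columns `test` (test identifier) and
#'   `dist_cm`, one row per significant association.
#' @param windows window-size grid in cM.
#' @return data frame with `window_cm` and `fraction`; non-decreasing in the
#'   window size.
#' @export
capture_curve <- function(distances, windows = seq(0, 10, by = 0.005)) {
  if (!nrow(distances)) stop("no distance records")
  # group by observed test ids only (a factor may carry empty levels)
  dmin <- tapply(distances$dist_cm, as.character(distances$test), min)
  data.frame(window_cm = windows,
             fraction = vapply(windows, function(w) mean(dmin <= w),
                               numeric(1)))
}

#' Gabriel-style LD blocks on array markers
#'
#' D'-confidence-interval block estimation on the phased array-marker data:
#' a pair is in "strong LD" if its CI lower bound is >= 0.70 and upper bound
#' >= 0.98, and shows "strong evidence of recombination" if the upper bound
#' is < 0.90; a candidate block has a strong outermost pair and at least 95%
#' of its informative pairs strong; candidates are accepted greedily by
#' decreasing genetic span. Each reported block is expanded by `flank_cm`
#' (default 0.0005 cM) on each side to compensate for boundary uncertainty.
#'
#' @param panel a [haplotype_panel()] (typically a sampled subset of the
#'   expanded data).
#' @param markers array-marker column indices (>= 2).
#' @param map unused placeholder; block coordinates use the marker cM.
#' @param flank_cm flank added to each side of a block, in cM.
#' @param maf_min minimum sample MAF for a marker to enter block estimation.
#' @param max_span_bp maximum physical block span considered.
#' @return data frame of class `ld_blocks` with columns `first`, `last`
#'   (marker indices into `markers`), `bp_start`, `bp_end` (marker bp),
#'   `cm_start`, `cm_end` (flanked), `n_markers`.
#' @export
ld_blocks <- function(panel, markers, map = NULL, flank_cm = 0.0005,
                      maf_min = 0.05, max_span_bp = 2e5) {
  stopifnot(length(markers) >= 2)
  v <- panel$variants
  H <- panel$haplotypes[, markers, drop = FALSE]
  res <- .gabriel_blocks(H, v$bp[markers], v$cm[markers],
                         maf_min, max_span_bp)
  i <- res$first; j <- res$last
  ord <- order(i)
  i <- i[ord]; j <- j[ord]
  out <- data.frame(first = i, last = j,
                    bp_start = v$bp[markers[i]], bp_end = v$bp[markers[j]],
                    cm_start = v$cm[markers[i]] - flank_cm,
                    cm_end = v$cm[markers[j]] + flank_cm,
                    n_markers = j - i + 1L)
  class(out) <- c("ld_blocks", "data.frame")
  out
}

#' Fraction of associations whose LD block captures a causal variant
#'
#' An association lying inside a flanked block is "captured" if any causal
#' variant's genetic position falls in that flanked interval; associations
#' outside every block count as not captured.
#'
#' @param assoc an `association_result`; only significant rows are used.
#' @param blocks an [ld_blocks()] result.
#' @param causal a `causal_set`.
#' @param map unused placeholder.
#' @return list with `fraction` and the per-association logical `captured`.
#' @export
block_capture <- function(assoc, blocks, causal, map = NULL) {
  sig <- assoc[which(assoc$significant), , drop = FALSE]
  if (!nrow(sig)) return(list(fraction = NA_real_, captured = logical(0)))
  captured <- vapply(sig$cm, function(cmi) {
    inb <- which(blocks$cm_start <= cmi & cmi <= blocks$cm_end)
    if (!length(inb)) return(FALSE)
    any(causal$cm >= blocks$cm_start[inb[1]] &
        causal$cm <= blocks$cm_end[inb[1]])
  }, logical(1))
  list(fraction = mean(captured), captured = captured)
}
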