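#' MAF summary over pooled associations
#'
#' Statistics over all significant associations pooled across causal-variant
#' sets and phenotype replicates: median MAF, fraction below a threshold, and
#' the sample standard deviation (n - 1 denominator) of associated MAF.
#'
#' @param maf minor-allele frequencies of pooled significant associations.
#' @param below threshold for the low-frequency fraction (default 0.1).
#' @return data frame with `n`, `median_maf`, `frac_below`, `sd_maf`, `iqr`.
#' @export
maf_summary <- function(maf, below = 0.1) {
  if (!length(maf)) stop("no associations to summarise")
  data.frame(n = length(maf), median_maf = stats::median(maf),
             frac_below = mean(maf < below),
             sd_maf = if (length(maf) > 1) stats::sd(maf) else 0,
             iqr = stats::IQR(maf))
}

#' MAF of the most significant association of a test
#'
#' Ties on the p-value are broken by larger absolute effect, then smaller bp.
#'
#' @param assoc an `association_result` for one test; must contain at least
#'   one significant association.
#' @return the sample MAF of the top association (one number).
#' @export
top_assoc_maf <- function(assoc) {
  sig <- assoc[which(assoc$significant), , drop = FALSE]
  if (!nrow(sig)) stop("test has no significant association")
  ord <- order(sig$p, -abs(sig$beta), sig$bp)
  sig$maf[ord[1]]
}

#' Age-of-mutation classification of rare variants
#'
#' A rare variant is classified as relatively `more_recent` if its minor
#' allele is absent from every out-panel (matched by physical position), and
#' `older` otherwise. Candidates must lie in the narrowed risk-allele
#' frequency window (default `[0.005, 0.02]`).
#'
#' @param panel focal [haplotype_panel()].
#' @param candidates variant column indices of the rare candidates.
#' @param out_panels list of one or more [haplotype_panel()] objects from
#'   other samples/populations.
#' @param freqs risk-allele frequencies used to enforce the window; defaults
#'   to the focal-panel 1-allele frequencies of the candidates.
#' @param freq_window narrowed frequency window.
#' @return factor with levels `more_recent`, `older`, one per candidate.
#' @export
classify_age <- function(panel, candidates, out_panels,
                         freqs = NULL, freq_window = c(0.005, 0.02)) {
  if (!length(out_panels)) stop("at least one out-panel is required")
  if (inherits(out_panels, "haplotype_panel")) out_panels <- list(out_panels)
  if (is.null(freqs)) freqs <- panel$variants$freq[candidates]
  bad <- freqs < freq_window[1] | freqs > freq_window[2]
  if (any(bad))
    stop(sprintf("%d candidate(s) outside the frequency window [%g, %g]",
                 sum(bad), freq_window[1], freq_window[2]))
  bp <- panel$variants$bp[candidates]
  seen <- rep(FALSE, length(candidates))
  for (op in out_panels) {
    m <- match(bp, op$variants$bp)
    has <- !is.na(m) & colSums(op$haplotypes)[replace(m, is.na(m), 1L)] > 0
    seen <- seen | has
  }
  factor(ifelse(seen, "older", "more_recent"),
         levels = c("more_recent", "older"))
}

#' Contrast signature statistics between scenarios
#'
#' For each pair of scenarios and each signature (median association
#' distance, median associated MAF, SD of associated MAF), reports the two
#' pooled statistics, their difference, and a bootstrap confidence interval
#' obtained by resampling tests (not individual associations), respecting the
#' replicate structure.
#'
#' @param records named list (one element per scenario) of data frames with
#'   columns `test`, `dist_cm`, `maf` — one row per significant association.
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return data frame with one row per scenario pair x signature:
#'   `signature`, `scenario_a`, `scenario_b`, `stat_a`, `stat_b`, `diff`
#'   (a - b), `ci_lo`, `ci_hi`.
#' @export
compare_scenarios <- function(records, n_boot = 1000, seed = 1,
                              conf = 0.95) {
  stopifnot(length(records) >= 2, !is.null(names(records)))
  stats_of <- function(d) c(median_dist = stats::median(d$dist_cm),
                            median_maf = stats::median(d$maf),
                            sd_maf = if (nrow(d) > 1) stats::sd(d$maf) else 0)
  boot_stats <- function(d, seed_i) {
    tests <- unique(d$test)
    set.seed(seed_i)
    t(vapply(seq_len(n_boot), function(b) {
      pick <- sample(tests, length(tests), replace = TRUE)
      rows <- unlist(lapply(pick, function(tt) which(d$test == tt)),
                     use.names = FALSE)
      stats_of(d[rows, , drop = FALSE])
    }, numeric(3)))
  }
  nm <- names(records)
  point <- lapply(records, stats_of)
  boots <- lapply(seq_along(records),
                  function(i) boot_stats(records[[i]], seed + i))
  alpha2 <- (1 - conf) / 2
  out <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    for (s in names(point[[i]])) {
      dboot <- boots[[i]][, s] - boots[[j]][, s]
      out[[length(out) + 1]] <- data.frame(
        signature = s, scenario_a = nm[i], scenario_b = nm[j],
        stat_a = unname(point[[i]][s]), stat_b = unname(point[[j]][s]),
        diff = unname(point[[i]][s] - point[[j]][s]),
        ci_lo = unname(stats::quantile(dboot, alpha2)),
        ci_hi = unname(stats::quantile(dboot, 1 - alpha2)))
    }
  }
  do.call(rbind, out)
}
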