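#' Disease scenario under a genotypic-relative-risk model
#'
#' @param label scenario label.
#' @param n_causal number of causal variants to draw (0 for the null).
#' @param freq_window risk-allele frequency window `c(low, high)` in the
#'   expanded sample, `0 < low < high < 0.5`.
#' @param grr genotypic relative risk per risk-allele copy (>= 1).
#' @param baseline baseline disease risk pi0 (probability, default 0.15).
#' @param rule risk combination rule: `"percopy"` multiplies the baseline by
#'   `grr` for every risk-allele copy across the causal set (capped at 1);
#'   `"carrier"` applies a single factor `grr` to carriers of any risk
#'   allele.
#' @param age_class optional `"more_recent"` or `"older"`: restricts causal
#'   selection to variants of that age class when the pipeline has an
#'   out-panel available (see [classify_age()]).
#' @return a `disease_scenario` object.
#' @export
disease_scenario <- function(label, n_causal, freq_window, grr,
                             baseline = 0.15,
                             rule = c("percopy", "carrier"),
                             age_class = NULL) {
  rule <- match.arg(rule)
  if (!is.null(age_class))
    age_class <- match.arg(age_class, c("more_recent", "older"))
  stopifnot(n_causal >= 0, grr >= 1, baseline > 0, baseline < 1)
  if (n_causal > 0) {
    stopifnot(length(freq_window) == 2, freq_window[1] > 0,
              freq_window[1] < freq_window[2], freq_window[2] < 0.5)
  }
  structure(list(label = label, n_causal = as.integer(n_causal),
                 freq_window = freq_window, grr = grr, baseline = baseline,
                 rule = rule, age_class = age_class),
            class = "disease_scenario")
}

#' The study's causal-variant scenarios
#'
#' Common causal variants have risk-allele frequencies 0.1-0.3 and GRR 1.5
#' (with a GRR-3 variant as an effect-size control and a 5-variant control
#' for the number of causal variants); rare causal variants have frequencies
#' 0.005-0.04 and GRR 3; the null scenario has no causal variants.
#'
#' @param baseline baseline risk passed to every scenario.
#' @return named list of [disease_scenario()] objects.
#' @export
scenario_presets <- function(baseline = 0.15) {
  common <- c(0.1, 0.3)
  rare <- c(0.005, 0.04)
  list(
    common2_grr1.5 = disease_scenario("common(2) GRR1.5", 2, common, 1.5, baseline),
    common2_grr3   = disease_scenario("common(2) GRR3",   2, common, 3,   baseline),
    common5_grr1.5 = disease_scenario("common(5) GRR1.5", 5, common, 1.5, baseline),
    rare5_grr3     = disease_scenario("rare(5) GRR3",     5, rare,   3,   baseline),
    rare9_grr3     = disease_scenario("rare(9) GRR3",     9, rare,   3,   baseline),
    null           = disease_scenario("null", 0, c(0.1, 0.3), 1, baseline)
  )
}

#' Select a causal-variant set from the disease locus
#'
#' Draws `n_causal` distinct variants uniformly at random among eligible
#' ones. Eligibility: physical position inside `locus_bounds` (inclusive),
#' risk-allele (1-allele) frequency within the scenario window as computed on
#' `panel` (normally the expanded sample), and a minor-allele count of at
#' least 2 (no singletons) in the pre-expansion panel.
#'
#' @param panel [haplotype_panel()] whose frequencies define eligibility
#'   (the expanded sample).
#' @param scenario a [disease_scenario()].
#' @param locus_bounds bp interval `c(start, end)` of the disease locus.
#' @param seed integer seed.
#' @param panel_counts optional minor-allele counts in the original panel,
#'   one per variant column of `panel`, used for the no-singleton rule;
#'   defaults to counts recomputed from `panel` itself.
#' @return a `causal_set` data frame with columns `index`, `id`, `bp`, `cm`,
#'   `freq`.
#' @export
select_causal <- function(panel, scenario, locus_bounds, seed,
                          panel_counts = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(scenario, "disease_scenario"))
  if (scenario$n_causal == 0L) {
    out <- data.frame(index = integer(0), id = character(0), bp = numeric(0),
                      cm = numeric(0), freq = numeric(0))
    class(out) <- c("causal_set", "data.frame")
    return(out)
  }
  v <- panel$variants
  if (is.null(panel_counts)) {
    cnt <- colSums(panel$haplotypes)
    panel_counts <- pmin(cnt, nrow(panel$haplotypes) - cnt)
  }
  eligible <- which(v$bp >= locus_bounds[1] & v$bp <= locus_bounds[2] &
                    v$freq >= scenario$freq_window[1] &
                    v$freq <= scenario$freq_window[2] &
                    panel_counts >= 2)
  if (length(eligible) < scenario$n_causal)
    stop(sprintf("only %d eligible causal variants in window [%g, %g] (need %d)",
                 length(eligible), scenario$freq_window[1],
                 scenario$freq_window[2], scenario$n_causal))
  set.seed(seed)
  idx <- sort(eligible[sample.int(length(eligible), scenario$n_causal)])
  out <- data.frame(index = idx, id = v$id[idx], bp = v$bp[idx],
                    cm = v$cm[idx], freq = v$freq[idx])
  class(out) <- c("causal_set", "data.frame")
  out
}

#' Assign per-individual disease risk
#'
#' Under the per-copy rule, `p_i = min(1, pi0 * grr^a_i)` where `a_i` is the
#' individual's total risk-allele count over the causal set; `p_i = pi0` when
#' `a_i = 0`. Under the carrier rule, `p_i = min(1, pi0 * grr)` for carriers
#' of at least one risk allele.
#'
#' @param genotypes matrix (individuals x causal variants) of risk-allele
#'   dosages in `{0, 1, 2}`, or a vector for a single causal variant.
#' @param scenario a [disease_scenario()].
#' @return numeric vector of probabilities in `[pi0, 1]`.
#' @export
assign_risk <- function(genotypes, scenario) {
  stopifnot(inherits(scenario, "disease_scenario"))
  g <- as.matrix(genotypes)
  if (length(g) && !all(g %in% c(0, 1, 2)))
    stop("genotype dosages must be 0, 1 or 2")
  a <- if (ncol(g)) rowSums(g) else rep(0, nrow(g))
  if (scenario$rule == "carrier") a <- as.numeric(a > 0)
  pmin(1, scenario$baseline * scenario$grr^a)
}

#' Sample cases and controls according to individual risk
#'
#' Disease status is drawn independently as Bernoulli(p_i); `n_cases`
#' individuals are then sampled uniformly without replacement from the
#' affected pool and `n_controls` from the unaffected pool. If either pool is
#' too small, all statuses are redrawn, up to `max_retries` times.
#'
#' @param risks per-individual disease probabilities.
#' @param n_cases,n_controls sample sizes.
#' @param seed integer seed.
#' @param max_retries redraw attempts before giving up.
#' @return a `phenotype_assignment`: list with `cases` and `controls`
#'   (individual indices), `status` (0/1 disease status for the whole
#'   population) and `retries`.
#' @export
sample_case_control <- function(risks, n_cases, n_controls, seed,
                                max_retries = 10) {
  n <- length(risks)
  if (n < n_cases + n_controls)
    stop("population smaller than n_cases + n_controls")
  set.seed(seed)
  for (try in 0:max_retries) {
    status <- stats::rbinom(n, 1, risks)
    aff <- which(status == 1L)
    una <- which(status == 0L)
    if (length(aff) >= n_cases && length(una) >= n_controls) {
      cases <- sort(aff[sample.int(length(aff), n_cases)])
      controls <- sort(una[sample.int(length(una), n_controls)])
      return(structure(list(cases = cases, controls = controls,
                            status = status, retries = try),
                       class = "phenotype_assignment"))
    }
  }
  stop(sprintf(
    "affected/unaffected pools too small after %d retries (%d affected, %d unaffected; need %d + %d)",
    max_retries, length(aff), length(una), n_cases, n_controls))
}

#' Random case/control labels (null assignment)
#'
#' Uniform random labels with no genotype dependence; provides the null
#' distribution in the absence of any risk alleles.
#'
#' @param n population size.
#' @param n_cases,n_controls sample sizes.
#' @param seed integer seed.
#' @return a `phenotype_assignment` (with `status = NULL`).
#' @export
null_assignment <- function(n, n_cases, n_controls, seed) {
  if (n < n_cases + n_controls)
    stop("population smaller than n_cases + n_controls")
  set.seed(seed)
  idx <- sample.int(n, n_cases + n_controls)
  structure(list(cases = sort(idx[seq_len(n_cases)]),
                 controls = sort(idx[n_cases + seq_len(n_controls)]),
                 status = NULL, retries = 0L),
            class = "phenotype_assignment")
}
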