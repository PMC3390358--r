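#' Phased haplotype panel
#'
#' Container for a phased 0/1 haplotype matrix with per-variant coordinates.
#' Rows are haplotypes (consecutive pairs form a diploid individual), columns
#' are variants sorted by physical position; 0 codes the major/reference
#' allele of the panel and 1 the minor/alternate allele. The per-variant MAF
#' is always recomputed from the matrix.
#'
#' @param haplotypes integer matrix of 0/1 entries, haplotypes x variants.
#' @param bp physical positions (1-based bp), strictly increasing.
#' @param cm genetic positions (cumulative cM from region start).
#' @param id variant identifiers; defaults to `s<bp>`.
#' @param population population label.
#' @return an object of class `haplotype_panel`: a list with elements
#'   `haplotypes` (matrix) and `variants` (data frame with `id`, `bp`, `cm`,
#'   `freq` of the 1-allele, and `maf`), plus `population`.
#' @export
haplotype_panel <- function(haplotypes, bp, cm, id = NULL,
                            population = "panel") {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (length(haplotypes) && !all(haplotypes %in% c(0L, 1L)))
    stop("haplotype entries must be 0 or 1")
  if (nrow(haplotypes) %% 2L != 0L)
    stop("number of haplotypes must be even (diploid pairing)")
  if (ncol(haplotypes) != length(bp) || length(bp) != length(cm))
    stop("positions must match the number of variant columns")
  if (length(bp) > 1 && any(diff(bp) <= 0))
    stop("variant columns must be sorted by strictly increasing bp")
  if (is.null(id)) id <- sprintf("s%d", as.integer(round(bp)))
  freq <- if (ncol(haplotypes)) unname(colMeans(haplotypes)) else numeric(0)
  structure(list(
    haplotypes = haplotypes,
    variants = data.frame(id = as.character(id), bp = as.numeric(bp),
                          cm = as.numeric(cm), freq = freq,
                          maf = pmin(freq, 1 - freq)),
    population = population
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel '%s': %d haplotypes x %d variants\n",
              x$population, nrow(x$haplotypes), ncol(x$haplotypes)))
  if (ncol(x$haplotypes)) {
    cat(sprintf("  span: %.0f-%.0f bp (%.4f-%.4f cM); median MAF %.3f\n",
                min(x$variants$bp), max(x$variants$bp),
                min(x$variants$cm), max(x$variants$cm),
                stats::median(x$variants$maf)))
  }
  invisible(x)
}

#' Subset a panel to a set of variant columns
#'
#' Restricting the panel to a variant subset is exact with respect to the
#' mosaic resampler: because template switches target a uniformly chosen
#' haplotype, the copying process observed at any subset of sites has the
#' same law as the full process restricted to those sites.
#'
#' @param panel a [haplotype_panel()].
#' @param idx variant column indices (will be sorted).
#' @return a [haplotype_panel()].
#' @export
subset_panel <- function(panel, idx) {
  stopifnot(inherits(panel, "haplotype_panel"))
  idx <- sort(unique(as.integer(idx)))
  haplotype_panel(panel$haplotypes[, idx, drop = FALSE],
                  panel$variants$bp[idx], panel$variants$cm[idx],
                  panel$variants$id[idx], panel$population)
}

#' Demography presets for the coalescent simulator
#'
#' Two presets, in backward time:
#' \describe{
#'   \item{`constant`}{diploid effective size 10,000 at all times
#'     ("YRI-like").}
#'   \item{`bottleneck_growth`}{exponential growth from Ne = 1,000 at 2,000
#'     generations ago to Ne = 1,000,000 at present, with an ancestral size of
#'     10,000 before the bottleneck ("CEU-like"; emulates the >1000-fold
#'     recent growth of European populations that inflates the proportion of
#'     rare variants).}
#' }
#'
#' @param preset `"constant"` or `"bottleneck_growth"`.
#' @param mu mutation rate per bp per generation.
#' @param rec_rate_cm_mb recombination backdrop in cM/Mb.
#' @return a `demography` object (list with segment vectors `start`, `N0`,
#'   `alpha`, plus `mu`, `rec_rate_cm_mb`, `label`).
#' @export
demography <- function(preset = c("constant", "bottleneck_growth"),
                       mu = 1.2e-8, rec_rate_cm_mb = 1.3) {
  preset <- match.arg(preset)
  stopifnot(mu >= 0, rec_rate_cm_mb > 0)
  if (preset == "constant") {
    d <- list(start = 0, N0 = 1e4, alpha = 0)
  } else {
    t_bot <- 2000
    d <- list(start = c(0, t_bot),
              N0 = c(1e6, 1e4),
              alpha = c(log(1e6 / 1e3) / t_bot, 0))
  }
  stopifnot(all(d$N0 > 0), all(d$start >= 0))
  structure(c(d, list(mu = mu, rec_rate_cm_mb = rec_rate_cm_mb,
                      label = preset)),
            class = "demography")
}

#' Simulate a resequenced disease locus with flanking regions
#'
#' Simulates a phased haplotype panel under the sequentially Markov
#' coalescent (SMC') for a region consisting of a central "disease locus" of
#' `locus_length` bp plus `flank_cm` cM of sequence on each side, under a
#' constant-rate recombination backdrop. The panel plays the role of deeply
#' resequenced data: every segregating site is observed, so rare variants are
#' abundant, especially under the `bottleneck_growth` demography.
#'
#' @param demog a [demography()] (or preset name).
#' @param locus_length length of the central disease locus in bp.
#' @param flank_cm flanking genetic length on each side, in cM.
#' @param n_hap number of haplotypes to simulate (>= 4, even).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param population label stored in the panel.
#' @return a list with elements `panel` (a [haplotype_panel()]), `map` (a
#'   [recomb_map()] spanning the region) and `locus_bounds` (bp interval of
#'   the central locus, inclusive).
#' @export
simulate_panel <- function(demog = demography("constant"),
                           locus_length = 1e5, flank_cm = 3,
                           n_hap = 220, seed = 1,
                           population = NULL) {
  if (is.character(demog)) demog <- demography(demog)
  stopifnot(inherits(demog, "demography"))
  if (n_hap < 4) stop("n_hap must be >= 4")
  if (n_hap %% 2L != 0L) stop("n_hap must be even")
  if (locus_length <= 0) stop("locus_length must be positive")
  if (flank_cm < 0) stop("flank_cm must be >= 0")

  morgans_per_bp <- demog$rec_rate_cm_mb / 1e6 / 100
  flank_bp <- round(flank_cm / 100 / morgans_per_bp)
  phys_len <- locus_length + 2 * flank_bp

  set.seed(seed)
  sim <- .smc_simulate(as.integer(n_hap), phys_len, morgans_per_bp,
                       demog$mu, demog$start, demog$N0, demog$alpha)
  map <- recomb_map(c(1, phys_len),
                    c(0, (phys_len - 1) * morgans_per_bp * 100))
  bp <- sim$position
  cm <- genetic_position(bp, map)
  if (is.null(population)) population <- demog$label
  panel <- haplotype_panel(sim$haplotypes, bp, cm, population = population)
  list(panel = panel, map = map,
       locus_bounds = c(flank_bp + 1, flank_bp + locus_length))
}

#' Mosaic resampling parameters
#'
#' @param lambda expected template switches per cM (> 0). The default,
#'   `NULL`, uses the Li-Stephens rate rho/k per cM with rho = 4 * Ne * 0.01
#'   at a fixed scaling size Ne = `ne_scale` and k the panel haplotype count.
#' @param eps per-site copying-error rate in `[0, 0.01]`; near zero by
#'   default so resampling adds essentially no new mutations.
#' @param ne_scale effective size used for the default switch rate.
#' @return a `mosaic_params` list.
#' @export
mosaic_params <- function(lambda = NULL, eps = 1e-4, ne_scale = 1e4) {
  if (!is.null(lambda) && lambda <= 0) stop("lambda must be > 0")
  if (eps < 0 || eps > 0.01) stop("eps must be in [0, 0.01]")
  structure(list(lambda = lambda, eps = eps, ne_scale = ne_scale),
            class = "mosaic_params")
}

#' Expand a haplotype panel by Li-Stephens mosaic resampling
#'
#' Each new haplotype is a mosaic of the panel haplotypes: a template is
#' chosen uniformly, and between adjacent variants separated by d cM the
#' template switches to a uniformly chosen panel haplotype with probability
#' 1 - exp(-lambda * d); each copied allele flips with probability `eps`.
#' Allele frequencies and local LD of the panel are approximately preserved.
#'
#' @param panel a non-empty [haplotype_panel()].
#' @param n_out number of haplotypes to generate (>= 2, even for diploids).
#' @param map optional [recomb_map()]; if supplied, genetic positions are
#'   re-interpolated from it instead of using the panel's stored cM.
#' @param params a [mosaic_params()].
#' @param seed integer seed.
#' @return a [haplotype_panel()] with `n_out` haplotypes.
#' @export
resample_mosaic <- function(panel, n_out, map = NULL,
                            params = mosaic_params(), seed = 1) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel$haplotypes) == 0 || ncol(panel$haplotypes) == 0)
    stop("empty panel")
  if (n_out < 2) stop("n_out must be >= 2")
  cm <- if (is.null(map)) panel$variants$cm
        else genetic_position(panel$variants$bp, map)
  k <- nrow(panel$haplotypes)
  lambda <- params$lambda
  if (is.null(lambda)) lambda <- 4 * params$ne_scale * 0.01 / k
  set.seed(seed)
  H <- .mosaic_resample(panel$haplotypes, cm, as.integer(n_out),
                        lambda, params$eps)
  haplotype_panel(H, panel$variants$bp, cm, panel$variants$id,
                  paste0(panel$population, "_expanded"))
}

#' Ascertain array markers from a panel
#'
#' Emulates a common-biased genotyping array: only variants with panel MAF at
#' or above `maf_floor` are eligible, and eligible variants are thinned to a
#' mean spacing of about `target_spacing` bp by picking one eligible variant
#' within each consecutive `target_spacing`-wide bin. With the default
#' `weight = "maf"`, the within-bin pick is made with probability
#' proportional to MAF: sequencing-derived site-frequency spectra are
#' strongly skewed towards rare alleles (density roughly proportional to
#' 1/f), so MAF-proportional sampling yields the approximately flat marker
#' MAF spectrum characteristic of double-hit-ascertained commercial arrays.
#' `weight = "uniform"` keeps the raw spectrum above the floor.
#'
#' @param panel a [haplotype_panel()].
#' @param maf_floor minimum panel MAF (`0 <= maf_floor < 0.5`).
#' @param target_spacing target mean marker spacing in bp.
#' @param seed integer seed; selection is deterministic given the seed.
#' @param weight within-bin selection weight, `"maf"` or `"uniform"`.
#' @return sorted integer vector of selected variant column indices (empty,
#'   with a warning, if nothing passes the floor).
#' @export
ascertain_array <- function(panel, maf_floor = 0.05, target_spacing = 2000,
                            seed = 1, weight = c("maf", "uniform")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  weight <- match.arg(weight)
  if (maf_floor < 0) stop("maf_floor must be >= 0")
  eligible <- which(panel$variants$maf >= maf_floor & maf_floor < 0.5)
  if (!length(eligible)) {
    warning("no variant passes the MAF floor; returning an empty marker set")
    return(integer(0))
  }
  bin <- floor((panel$variants$bp[eligible] - 1) / target_spacing)
  maf <- panel$variants$maf
  set.seed(seed)
  picks <- vapply(split(eligible, bin), function(ix) {
    if (length(ix) == 1L) return(ix)
    w <- if (weight == "maf") maf[ix] else rep(1, length(ix))
    ix[sample.int(length(ix), 1L, prob = w)]
  }, integer(1))
  sort(unname(picks))
}
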