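#' Experiment configuration
#'
#' Bundles every knob of the replication design: demographies, loci, the
#' expanded population, the causal-variant scenarios, and the test design
#' (sets x replicates, case/control counts, significance level). Defaults
#' follow the full study design: 100-kb disease locus with 3-cM flanks, two
#' demographies, 10,000 diploid individuals after mosaic expansion, six
#' scenarios, 50 causal sets x 10 phenotype replicates (500 tests per
#' scenario per locus), 1000 cases + 1000 controls, region-wide Bonferroni at
#' 0.05.
#'
#' @param demographies character vector of demography preset names.
#' @param n_loci independent simulated disease loci per demography.
#' @param locus_length disease-locus length in bp.
#' @param flank_cm flank on each side, in cM (both for simulation span and
#'   the association window).
#' @param n_hap_panel resequencing-panel haplotypes per locus.
#' @param n_hap_out extra haplotypes held out as the out-panel for the
#'   age-of-mutation classification (0 disables the classification).
#' @param n_pop expanded population size (diploid individuals).
#' @param scenarios named list of [disease_scenario()] objects.
#' @param n_sets causal-variant sets per scenario per locus.
#' @param n_replicates phenotype replicates per set.
#' @param n_cases,n_controls case/control sample sizes.
#' @param alpha region-wide significance level.
#' @param maf_floor,target_spacing array-ascertainment parameters.
#' @param mosaic a [mosaic_params()].
#' @param block_sample_n diploids subsampled for LD-block estimation.
#' @param max_retries phenotype redraws when an affected/unaffected pool is
#'   short.
#' @param seed master seed; all stage seeds are derived from it.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(demographies = c("bottleneck_growth", "constant"),
                              n_loci = 5, locus_length = 1e5, flank_cm = 3,
                              n_hap_panel = 220, n_hap_out = 0,
                              n_pop = 10000,
                              scenarios = scenario_presets(),
                              n_sets = 50, n_replicates = 10,
                              n_cases = 1000, n_controls = 1000,
                              alpha = 0.05,
                              maf_floor = 0.05, target_spacing = 2000,
                              mosaic = mosaic_params(),
                              block_sample_n = 2000,
                              max_retries = 10, seed = 1) {
  stopifnot(n_loci >= 1, n_sets >= 1, n_replicates >= 1,
            n_cases >= 1, n_controls >= 1, n_pop >= 1,
            n_hap_panel >= 4, n_hap_panel %% 2 == 0, n_hap_out %% 2 == 0)
  structure(as.list(environment()), class = "experiment_config")
}

#' Scale an experiment configuration for desk-size runs
#'
#' Multiplies the number of causal-variant sets by `factor` (minimum 1),
#' leaving replicate counts, sample sizes and all schemas unchanged, so a
#' scaled run produces the same outputs at reduced Monte-Carlo precision.
#'
#' @param config an [experiment_config()].
#' @param factor scaling factor in (0, 1].
#' @return the scaled configuration.
#' @examples
#' cfg <- scale_config(experiment_config(), 0.1)  # 5 sets x 10 replicates
#' @export
scale_config <- function(config, factor) {
  stopifnot(inherits(config, "experiment_config"), factor > 0)
  config$n_sets <- max(1L, as.integer(round(config$n_sets * factor)))
  config
}

# panel restricted to a subset of haplotype rows (same variants)
panel_rows <- function(panel, rows) {
  haplotype_panel(panel$haplotypes[rows, , drop = FALSE],
                  panel$variants$bp, panel$variants$cm,
                  panel$variants$id, panel$population)
}

# simulate one locus setting and precompute everything phenotype-independent
prepare_locus <- function(config, demog_name, locus, verbose = FALSE) {
  di <- match(demog_name, config$demographies)
  dem <- demography(demog_name)
  sim <- simulate_panel(dem, config$locus_length, config$flank_cm,
                        config$n_hap_panel + config$n_hap_out,
                        seed = derive_seed(config$seed, di, locus, 1),
                        population = demog_name)
  focal <- if (config$n_hap_out > 0)
    panel_rows(sim$panel, seq_len(config$n_hap_panel)) else sim$panel
  markers_full <- ascertain_array(focal, config$maf_floor,
                                  config$target_spacing,
                                  seed = derive_seed(config$seed, di, locus, 2))
  locus_idx <- which(focal$variants$bp >= sim$locus_bounds[1] &
                     focal$variants$bp <= sim$locus_bounds[2])
  keep <- sort(unique(c(locus_idx, markers_full)))
  sub <- subset_panel(focal, keep)
  markers <- match(markers_full, keep)
  cnt <- colSums(sub$haplotypes)
  panel_counts <- pmin(cnt, nrow(sub$haplotypes) - cnt)

  expanded <- resample_mosaic(sub, 2 * config$n_pop, map = sim$map,
                              params = config$mosaic,
                              seed = derive_seed(config$seed, di, locus, 3))
  G_all <- .hap_dosage(expanded$haplotypes)

  set.seed(derive_seed(config$seed, di, locus, 4))
  bs <- sort(sample.int(config$n_pop, min(config$block_sample_n, config$n_pop)))
  block_panel <- panel_rows(expanded, sort(c(2 * bs - 1, 2 * bs)))
  blocks <- ld_blocks(block_panel, markers)

  age <- NULL
  if (config$n_hap_out > 0) {
    outp <- panel_rows(sim$panel, config$n_hap_panel + seq_len(config$n_hap_out))
    outp <- subset_panel(outp, keep)
    in_locus <- expanded$variants$bp >= sim$locus_bounds[1] &
                expanded$variants$bp <= sim$locus_bounds[2]
    cand <- which(in_locus & expanded$variants$freq >= 0.005 &
                  expanded$variants$freq <= 0.02 & panel_counts >= 2)
    if (length(cand)) {
      lab <- classify_age(expanded, cand, list(outp))
      age <- data.frame(index = cand, class = as.character(lab))
    }
  }
  if (verbose)
    message(sprintf("[%s locus %d] %d panel variants, %d kept, %d markers, %d blocks",
                    demog_name, locus, ncol(focal$haplotypes), length(keep),
                    length(markers), nrow(blocks)))
  list(demography = demog_name, locus = locus, map = sim$map,
       locus_bounds = sim$locus_bounds, panel = sub, expanded = expanded,
       markers = markers, panel_counts = panel_counts, G_all = G_all,
       blocks = blocks, age = age)
}

# run one scenario on a prepared locus; returns per-test and per-association
# records
run_scenario <- function(config, prep, scen_name, verbose = FALSE) {
  scen <- config$scenarios[[scen_name]]
  di <- match(prep$demography, config$demographies)
  si <- match(scen_name, names(config$scenarios))
  eligible_subset <- NULL
  if (!is.null(scen$age_class)) {
    if (is.null(prep$age))
      stop("scenario requires age classes; set n_hap_out > 0 in the config")
    eligible_subset <- prep$age$index[prep$age$class == scen$age_class]
  }
  tests <- list(); assocs <- list(); dists <- list(); errors <- 0L
  for (set in seq_len(config$n_sets)) {
    causal <- NULL
    risks <- NULL
    sel_err <- NULL
    if (scen$n_causal > 0) {
      causal <- tryCatch(
        select_causal_subset(prep, scen, config,
                             derive_seed(config$seed, di, prep$locus, si, set),
                             eligible_subset),
        error = function(e) { sel_err <<- conditionMessage(e); NULL })
      if (is.null(causal)) { errors <- errors + config$n_replicates; next }
      risks <- assign_risk(prep$G_all[, causal$index, drop = FALSE], scen)
    }
    for (rep in seq_len(config$n_replicates)) {
      seed_rep <- derive_seed(config$seed, di, prep$locus, si, set, rep)
      rec <- tryCatch(
        run_single_test(config, prep, scen, causal, risks, set, rep, seed_rep),
        error = function(e) { errors <<- errors + 1L; NULL })
      if (is.null(rec)) next
      tests[[length(tests) + 1]] <- rec$test
      if (!is.null(rec$assoc)) assocs[[length(assocs) + 1]] <- rec$assoc
      if (!is.null(rec$dist)) dists[[length(dists) + 1]] <- rec$dist
    }
  }
  n_total <- config$n_sets * config$n_replicates
  if (errors > 0.5 * n_total)
    stop(sprintf("scenario '%s' failed in %d of %d tests", scen_name,
                 errors, n_total))
  if (verbose)
    message(sprintf("  [%s] %d/%d tests ok", scen_name, n_total - errors,
                    n_total))
  list(tests = do.call(rbind, tests),
       assoc = if (length(assocs)) do.call(rbind, assocs) else NULL,
       dist = if (length(dists)) do.call(rbind, dists) else NULL)
}

select_causal_subset <- function(prep, scen, config, seed, eligible_subset) {
  causal <- select_causal(prep$expanded, scen, prep$locus_bounds, seed,
                          panel_counts = local({
                            pc <- prep$panel_counts
                            if (!is.null(eligible_subset)) {
                              mask <- rep(0L, length(pc))
                              mask[eligible_subset] <- pc[eligible_subset]
                              mask
                            } else pc
                          }))
  causal
}

run_single_test <- function(config, prep, scen, causal, risks, set, rep,
                            seed_rep) {
  ph <- if (is.null(risks))
    null_assignment(config$n_pop, config$n_cases, config$n_controls, seed_rep)
  else
    sample_case_control(risks, config$n_cases, config$n_controls, seed_rep,
                        config$max_retries)
  res <- region_scan(prep$expanded, prep$markers, ph, causal,
                     prep$locus_bounds, prep$map, config$flank_cm,
                     config$alpha, dosage_cache = prep$G_all)
  sig <- res[which(res$significant), , drop = FALSE]
  key <- data.frame(demography = prep$demography, locus = prep$locus,
                    scenario = scen$label, set = set, replicate = rep)
  bc <- if (!is.null(causal) && nrow(causal))
    block_capture(res, prep$blocks, causal) else NULL
  test <- cbind(key, data.frame(
    n_tested = attr(res, "n_tested"), n_sig = nrow(sig),
    top_maf = if (nrow(sig)) top_assoc_maf(res) else NA_real_,
    block_captured = if (nrow(sig) && !is.null(bc)) sum(bc$captured)
                     else NA_integer_,
    min_dist_cm = NA_real_, retries = ph$retries, seed = seed_rep))
  assoc <- NULL; dist <- NULL
  if (nrow(sig)) {
    assoc <- cbind(key[rep(1, nrow(sig)), , drop = FALSE],
                   sig[, c("marker", "bp", "cm", "maf", "beta", "se", "p",
                           "fallback")],
                   row.names = NULL)
    if (!is.null(causal) && nrow(causal)) {
      d <- assoc_distance(res, causal, prep$expanded)
      test$min_dist_cm <- min(d$dist_cm)
      dist <- cbind(key[rep(1, nrow(d)), , drop = FALSE], d,
                    row.names = NULL)
    }
  }
  list(test = test, assoc = assoc, dist = dist)
}

#' Run the full replication experiment
#'
#' For every demography x locus: simulate a resequencing panel, ascertain
#' array markers, expand to the study population, estimate LD blocks; then
#' for every scenario draw `n_sets` causal-variant sets and `n_replicates`
#' phenotype replicates each, scan the region, and pool the signature
#' statistics. Fully reproducible from the master seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for TSV outputs (`tests.tsv`,
#'   `associations.tsv`, `distances.tsv`, `summary.tsv`, `blocks.tsv`).
#' @param verbose print progress.
#' @return an `experiment_result` list: `tests`, `associations`, `distances`
#'   (data frames), `summary` (per scenario x demography x locus), `blocks`,
#'   `age_classes`, `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  tests <- list(); assocs <- list(); dists <- list()
  blocks <- list(); ages <- list()
  for (dname in config$demographies) {
    for (l in seq_len(config$n_loci)) {
      prep <- prepare_locus(config, dname, l, verbose)
      blocks[[paste(dname, l, sep = "_")]] <- prep$blocks
      if (!is.null(prep$age))
        ages[[paste(dname, l, sep = "_")]] <- prep$age
      for (scen_name in names(config$scenarios)) {
        r <- tryCatch(run_scenario(config, prep, scen_name, verbose),
                      error = function(e) {
                        warning(sprintf("[%s locus %d] scenario '%s' skipped: %s",
                                        dname, l, scen_name,
                                        conditionMessage(e)), call. = FALSE)
                        NULL
                      })
        if (is.null(r)) next
        tests[[length(tests) + 1]] <- r$tests
        if (!is.null(r$assoc)) assocs[[length(assocs) + 1]] <- r$assoc
        if (!is.null(r$dist)) dists[[length(dists) + 1]] <- r$dist
      }
      rm(prep); gc(FALSE)
    }
  }
  res <- structure(list(
    tests = do.call(rbind, tests),
    associations = if (length(assocs)) do.call(rbind, assocs) else NULL,
    distances = if (length(dists)) do.call(rbind, dists) else NULL,
    blocks = blocks, age_classes = ages, config = config
  ), class = "experiment_result")
  res$summary <- summarize_experiment(res)
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

#' Pool per-test results into signature summaries
#'
#' One row per scenario x demography x locus: test counts, median and IQR of
#' the association distance (pooled over associations), capture fractions of
#' tests at 0.01 / 0.1 / 1 cM windows, LD-block capture rate (pooled over
#' associations), and the associated-MAF statistics (median, fraction below
#' 0.1, sample SD, median top-association MAF).
#'
#' @param res an `experiment_result`.
#' @return a data frame.
#' @export
summarize_experiment <- function(res) {
  tests <- res$tests
  keyf <- function(d) interaction(d$scenario, d$demography, d$locus, drop = TRUE)
  out <- list()
  for (k in levels(keyf(tests))) {
    tt <- tests[keyf(tests) == k, , drop = FALSE]
    sigt <- tt[tt$n_sig > 0, , drop = FALSE]
    a <- res$associations
    a <- if (!is.null(a)) a[keyf(a) == k, , drop = FALSE] else NULL
    d <- res$distances
    d <- if (!is.null(d)) d[keyf(d) == k, , drop = FALSE] else NULL
    row <- data.frame(
      scenario = tt$scenario[1], demography = tt$demography[1],
      locus = tt$locus[1], n_tests = nrow(tt), n_tests_sig = nrow(sigt),
      frac_tests_sig = nrow(sigt) / nrow(tt),
      median_dist_cm = if (!is.null(d) && nrow(d)) median(d$dist_cm) else NA,
      iqr_dist_cm = if (!is.null(d) && nrow(d)) stats::IQR(d$dist_cm) else NA,
      capture_0.01cm = if (nrow(sigt) && any(!is.na(sigt$min_dist_cm)))
        mean(sigt$min_dist_cm <= 0.01) else NA,
      capture_0.1cm = if (nrow(sigt) && any(!is.na(sigt$min_dist_cm)))
        mean(sigt$min_dist_cm <= 0.1) else NA,
      capture_1cm = if (nrow(sigt) && any(!is.na(sigt$min_dist_cm)))
        mean(sigt$min_dist_cm <= 1) else NA,
      block_capture = if (nrow(sigt) && any(!is.na(sigt$block_captured)))
        sum(sigt$block_captured, na.rm = TRUE) / sum(sigt$n_sig) else NA,
      median_maf = if (!is.null(a) && nrow(a)) median(a$maf) else NA,
      frac_maf_below_0.1 = if (!is.null(a) && nrow(a)) mean(a$maf < 0.1) else NA,
      sd_maf = if (!is.null(a) && nrow(a) > 1) sd(a$maf) else NA,
      median_top_maf = if (nrow(sigt)) median(sigt$top_maf) else NA)
    out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) {
    if (!is.null(d))
      utils::write.table(d, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wr(res$tests, "tests.tsv")
  wr(res$associations, "associations.tsv")
  wr(res$distances, "distances.tsv")
  wr(res$summary, "summary.tsv")
  bl <- lapply(names(res$blocks), function(k)
    if (nrow(res$blocks[[k]])) cbind(setting = k, res$blocks[[k]]))
  bl <- bl[!vapply(bl, is.null, logical(1))]
  if (length(bl)) wr(do.call(rbind, bl), "blocks.tsv")
  invisible(out_dir)
}

#' Write LD blocks as a BED file
#'
#' Physical coordinates, 0-based half-open as BED requires.
#'
#' @param blocks an [ld_blocks()] result.
#' @param path output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path, chrom = "1") {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(blocks))
    writeLines(sprintf("%s\t%d\t%d\tblock%d", chrom,
                       as.integer(blocks$bp_start) - 1L,
                       as.integer(blocks$bp_end), seq_len(nrow(blocks))), con)
  invisible(path)
}
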