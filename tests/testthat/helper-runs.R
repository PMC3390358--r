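# Shared desk-scale experiment runs, computed once per test session.
# Sizes follow the package's desk profile: the full study design (100-kb
# locus, 3-cM flanks, 10,000 diploids, 1000 + 1000 sampling) with the number
# of causal sets and replicates reduced.

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

# CEU-like loci, all five causal scenarios
desk_run <- function() cached("desk", {
  cfg <- experiment_config(
    demographies = "bottleneck_growth", n_loci = 2, n_pop = 10000,
    scenarios = scenario_presets()[c("common2_grr1.5", "common2_grr3",
                                     "common5_grr1.5", "rare5_grr3",
                                     "rare9_grr3")],
    n_sets = 8, n_replicates = 2, seed = 20260919)
  run_experiment(cfg)
})

# YRI-like locus, natural and synthetic scenario only
const_run <- function() cached("const", {
  cfg <- experiment_config(
    demographies = "constant", n_loci = 1, n_pop = 10000,
    scenarios = scenario_presets()[c("common2_grr1.5", "rare5_grr3")],
    n_sets = 8, n_replicates = 2, seed = 20260920)
  run_experiment(cfg)
})

# random case/control labels, 200 scans
null_run <- function() cached("null", {
  cfg <- experiment_config(
    demographies = "bottleneck_growth", n_loci = 1, n_pop = 2000,
    scenarios = scenario_presets()["null"],
    n_sets = 20, n_replicates = 10, seed = 20260921)
  run_experiment(cfg)
})

# age-of-mutation partition: narrowed frequency window, causal sets drawn
# entirely from the more-recent or entirely from the older class
age_run <- function() cached("age", {
  narrowed <- c(0.005, 0.02)
  cfg <- experiment_config(
    demographies = "bottleneck_growth", n_loci = 2, n_pop = 10000,
    n_hap_out = 230,
    scenarios = list(
      recent = disease_scenario("rare(5) more_recent", 5, narrowed, 3,
                                age_class = "more_recent"),
      older = disease_scenario("rare(5) older", 5, narrowed, 3,
                               age_class = "older")),
    n_sets = 8, n_replicates = 2, seed = 20260922)
  suppressWarnings(run_experiment(cfg))
})
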