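#!/usr/bin/env Rscript
# Distance signatures from a finished experiment (02): per-scenario distance
# medians by locus (box-plot analogue), capture curves over resequencing
# window sizes, and the scenario contrasts with bootstrap CIs.
#
# Usage: Rscript analysis/03_distance_signatures.R [--in DIR] [--out DIR]
#          [--seed S]

suppressPackageStartupMessages(library(synthassoc))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
}
indir <- get_arg("--in", "results/experiment")
out <- get_arg("--out", "results/signatures")
seed <- as.integer(get_arg("--seed", "1"))
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d <- read.table(file.path(indir, "distances.tsv"), header = TRUE, sep = "\t")
d$test <- interaction(d$demography, d$locus, d$scenario, d$set, d$replicate,
                      drop = TRUE)

# per scenario x setting distance summary (highest-r2 and closest causal)
key <- interaction(d$scenario, d$demography, d$locus, drop = TRUE)
tab <- do.call(rbind, lapply(levels(key), function(k) {
  dk <- d[key == k, ]
  data.frame(scenario = dk$scenario[1], demography = dk$demography[1],
             locus = dk$locus[1], n_assoc = nrow(dk),
             median_dist_cm = median(dk$dist_cm),
             iqr_dist_cm = IQR(dk$dist_cm),
             median_closest_cm = median(dk$dist_closest_cm))
}))
write.table(tab, file.path(out, "distance_by_setting.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# capture curves per scenario, pooled over settings
curves <- do.call(rbind, lapply(split(d, d$scenario), function(ds) {
  cc <- capture_curve(ds[, c("test", "dist_cm")],
                      windows = seq(0, 1, by = 0.005))
  cbind(scenario = ds$scenario[1], cc)
}))
write.table(curves, file.path(out, "capture_curves.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (s in unique(curves$scenario)) {
  cs <- curves[curves$scenario == s, ]
  w90 <- cs$window_cm[which(cs$fraction >= 0.9)[1]]
  message(sprintf("%-18s window for 90%% capture: %s cM", s,
                  ifelse(is.na(w90), ">1", format(w90))))
}

# synthetic vs natural contrast with bootstrap CIs over tests
rare <- c("rare(5) GRR3", "rare(9) GRR3")
if (any(d$scenario %in% rare) && any(d$scenario == "common(2) GRR1.5")) {
  recs <- list(
    synthetic = d[d$scenario %in% rare, c("test", "dist_cm", "maf")],
    natural = d[d$scenario == "common(2) GRR1.5",
                c("test", "dist_cm", "maf")])
  cc <- compare_scenarios(recs, n_boot = 1000, seed = seed)
  write.table(cc, file.path(out, "contrasts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dr <- cc[cc$signature == "median_dist", ]
  message(sprintf(
    "median distance synthetic - natural: %+.4f cM (95%% CI %.4f..%.4f)",
    dr$diff, dr$ci_lo, dr$ci_hi))
}
message("wrote ", out)
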