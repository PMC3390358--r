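#!/usr/bin/env Rscript
# MAF signatures from a finished experiment (02): per-setting associated-MAF
# summaries (median, fraction below 0.1, SD — the Table-2 analogue) and the
# MAF of the most significant association per test.
#
# Usage: Rscript analysis/04_maf_signatures.R [--in DIR] [--out DIR]

suppressPackageStartupMessages(library(synthassoc))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
}
indir <- get_arg("--in", "results/experiment")
out <- get_arg("--out", "results/signatures")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

a <- read.table(file.path(indir, "associations.tsv"), header = TRUE,
                sep = "\t")
tests <- read.table(file.path(indir, "tests.tsv"), header = TRUE, sep = "\t")

key <- interaction(a$scenario, a$demography, a$locus, drop = TRUE)
tab <- do.call(rbind, lapply(levels(key), function(k) {
  ak <- a[key == k, ]
  cbind(data.frame(scenario = ak$scenario[1], demography = ak$demography[1],
                   locus = ak$locus[1]),
        maf_summary(ak$maf))
}))
write.table(tab, file.path(out, "maf_by_setting.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# Table-2 layout: SD of associated MAF, loci as rows, scenarios as columns
sd_wide <- reshape(tab[, c("scenario", "demography", "locus", "sd_maf")],
                   direction = "wide", idvar = c("demography", "locus"),
                   timevar = "scenario")
write.table(sd_wide, file.path(out, "sd_maf_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# top-association MAF per test (most significant association only)
tt <- tests[tests$n_sig > 0, ]
top <- aggregate(top_maf ~ scenario, data = tt, FUN = median)
names(top)[2] <- "median_top_maf"
all_m <- aggregate(maf ~ scenario, data = a, FUN = median)
names(all_m)[2] <- "median_all_maf"
cmp <- merge(top, all_m)
write.table(cmp, file.path(out, "top_assoc_maf.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pool <- function(labs) a$maf[a$scenario %in% labs]
nat <- pool("common(2) GRR1.5")
syn <- pool(c("rare(5) GRR3", "rare(9) GRR3"))
if (length(nat) && length(syn)) {
  message(sprintf(
    "pooled MAF < 0.1: natural %.2f%%, synthetic %.1f%%; median MAF %.3f vs %.3f; SD %.3f vs %.3f",
    100 * mean(nat < 0.1), 100 * mean(syn < 0.1),
    median(nat), median(syn), sd(nat), sd(syn)))
}
message("wrote ", out)
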