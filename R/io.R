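#' Write a haplotype panel as a phased VCF plus a genetic map
#'
#' The VCF (v4.2) stores consecutive haplotype pairs as one diploid sample
#' with a phased GT field; the map is written in HapMap format (see
#' [write_genetic_map()]).
#'
#' @param panel a [haplotype_panel()].
#' @param map a [recomb_map()].
#' @param vcf_path,map_path output paths.
#' @param chrom chromosome name to write.
#' @return `vcf_path`, invisibly.
#' @export
write_panel <- function(panel, map, vcf_path, map_path, chrom = "1") {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(map, "recomb_map"))
  H <- panel$haplotypes
  n_ind <- nrow(H) / 2
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=synthassoc",
               sprintf("##population=%s", panel$population),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- sprintf("IND%04d", seq_len(n_ind))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (ncol(H)) {
    gt <- matrix(paste(H[seq(1, nrow(H), 2), , drop = FALSE],
                       H[seq(2, nrow(H), 2), , drop = FALSE], sep = "|"),
                 nrow = n_ind)
    lines <- vapply(seq_len(ncol(H)), function(j) {
      paste(c(chrom, format(panel$variants$bp[j], scientific = FALSE),
              panel$variants$id[j], "A", "T", ".", "PASS", ".", "GT",
              gt[, j]), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  write_genetic_map(map, map_path)
  invisible(vcf_path)
}

#' Read a phased VCF and genetic map into a haplotype panel
#'
#' Genotypes must be fully phased ("|" separator) and complete; an unphased
#' or missing genotype aborts with an error naming the first offending
#' record. Genetic positions are interpolated from the map.
#'
#' @param vcf_path phased VCF file.
#' @param map_path HapMap-format genetic map file.
#' @param population population label for the panel.
#' @return a list with `panel` and `map`, as in [simulate_panel()].
#' @export
read_panel <- function(vcf_path, map_path, population = "panel") {
  map <- read_genetic_map(map_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  pos <- as.numeric(fix[, "POS"])
  ids <- fix[, "ID"]
  bad <- function(test, what) {
    hit <- which(matrix(test, nrow = nrow(gt)), arr.ind = TRUE)
    if (nrow(hit)) {
      i <- hit[1, 1]; j <- hit[1, 2]
      stop(sprintf("%s genotype at %s:%s (sample %s)", what,
                   fix[i, "CHROM"], fix[i, "POS"], colnames(gt)[j]))
    }
  }
  bad(is.na(gt) | gt %in% c(".", "./.", ".|."), "missing")
  bad(grepl("/", gt, fixed = TRUE), "unphased")
  bad(!grepl("^[01]\\|[01]$", gt), "malformed")
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  n_ind <- ncol(gt)
  H <- matrix(0L, nrow = 2 * n_ind, ncol = nrow(gt))
  H[seq(1, 2 * n_ind, 2), ] <- t(h1)
  H[seq(2, 2 * n_ind, 2), ] <- t(h2)
  panel <- haplotype_panel(H, pos, genetic_position(pos, map), ids,
                           population = population)
  list(panel = panel, map = map)
}
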