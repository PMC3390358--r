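# Small in-code fixtures shared across test files.

# iid-column toy panel with prescribed 1-allele frequencies
toy_panel <- function(n_hap = 200, freqs = c(0.5, 0.3, 0.1, 0.05),
                      spacing_bp = 1000, cm_per_bp = 1e-5, seed = 1,
                      population = "toy") {
  set.seed(seed)
  m <- length(freqs)
  H <- vapply(freqs, function(f) rbinom(n_hap, 1, f), integer(n_hap))
  bp <- seq(spacing_bp, by = spacing_bp, length.out = m)
  haplotype_panel(H, bp, bp * cm_per_bp, population = population)
}

# panel whose columns have controlled LD with the first column: column j
# equals column 1 with per-haplotype flip probability flip[j]
ld_panel <- function(n_hap = 400, flip = c(0, 0.4, 0.05, 0.2),
                     spacing_bp = 1000, cm_per_bp = 1e-5, seed = 1) {
  set.seed(seed)
  x <- rbinom(n_hap, 1, 0.5)
  H <- vapply(flip, function(fp) {
    fl <- rbinom(n_hap, 1, fp)
    as.integer(xor(x, fl))
  }, integer(n_hap))
  bp <- seq(spacing_bp, by = spacing_bp, length.out = length(flip))
  haplotype_panel(H, bp, bp * cm_per_bp)
}

# dyadic-rate map so interpolated cM values are exact in floating point
dyadic_map <- function() recomb_map(c(1, 1025), c(0, 8))  # 1/128 cM per bp
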