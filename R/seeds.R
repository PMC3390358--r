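#' Derive a child seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; every stage
#' derives its own seed by hashing the master seed together with a fixed-order
#' path of integer indices (demography, locus, scenario, set, replicate, ...),
#' so any stage can be reproduced in isolation.
#'
#' @param master integer master seed.
#' @param ... integer path components, in fixed order.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, 2, 3) == derive_seed(1, 2, 3)
#' derive_seed(1, 2, 3) != derive_seed(1, 3, 2)
#' @export
derive_seed <- function(master, ...) {
  ks <- c(...)
  s <- as.double(master) %% 2147483647
  # affine steps stay below 2^53 so double arithmetic is exact
  s <- (s * 48271 + 11) %% 2147483647
  for (k in ks) {
    s <- (s * 48271 + (as.double(k) %% 65521) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}
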