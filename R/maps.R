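#' Recombination map
#'
#' A piecewise-linear physical-to-genetic mapping given by ordered anchor
#' points. Physical positions must be strictly increasing and genetic
#' positions non-decreasing.
#'
#' @param bp integer-valued physical positions (1-based bp).
#' @param cm cumulative genetic positions (cM) at those anchors.
#' @return an object of class `recomb_map` (a data frame with columns `bp`
#'   and `cm`).
#' @examples
#' m <- recomb_map(c(100, 200), c(1, 2))
#' genetic_position(150, m)
#' @export
recomb_map <- function(bp, cm) {
  stopifnot(length(bp) == length(cm), length(bp) >= 1)
  if (any(diff(bp) <= 0)) stop("physical positions must be strictly increasing")
  if (any(diff(cm) < 0)) stop("genetic positions must be non-decreasing")
  structure(data.frame(bp = as.numeric(bp), cm = as.numeric(cm)),
            class = c("recomb_map", "data.frame"))
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation between the two flanking anchors; at an anchor the
#' anchor's value is returned exactly; queries beyond the map ends are
#' extrapolated at the terminal interval's rate (constant rate if the map has
#' a single anchor, where rate 0 is used).
#'
#' @param bp physical positions to query.
#' @param map a [recomb_map()].
#' @return genetic positions in cM, same length as `bp`.
#' @export
genetic_position <- function(bp, map) {
  stopifnot(inherits(map, "recomb_map"), nrow(map) >= 1)
  n <- nrow(map)
  if (n == 1L) return(rep(map$cm[1], length(bp)))
  out <- stats::approx(map$bp, map$cm, xout = bp, rule = 2, ties = "ordered")$y
  rate_lo <- (map$cm[2] - map$cm[1]) / (map$bp[2] - map$bp[1])
  rate_hi <- (map$cm[n] - map$cm[n - 1]) / (map$bp[n] - map$bp[n - 1])
  lo <- bp < map$bp[1]
  hi <- bp > map$bp[n]
  out[lo] <- map$cm[1] - (map$bp[1] - bp[lo]) * rate_lo
  out[hi] <- map$cm[n] + (bp[hi] - map$bp[n]) * rate_hi
  out
}

#' Read a HapMap-format genetic map
#'
#' Whitespace-delimited text with a header and three columns: physical
#' position (bp), local rate (cM/Mb) and cumulative map position (cM).
#'
#' @param path file path.
#' @return a [recomb_map()]; the per-interval rates are kept in attribute
#'   `rate_cm_mb`.
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  if (ncol(d) < 3) stop("genetic map must have 3 columns: position, rate, map")
  if (any(diff(d[[1]]) <= 0)) stop("genetic map positions must be strictly increasing")
  if (any(diff(d[[3]]) < 0)) stop("genetic map cumulative cM must be non-decreasing")
  m <- recomb_map(d[[1]], d[[3]])
  attr(m, "rate_cm_mb") <- d[[2]]
  m
}

#' Write a recombination map in HapMap format
#'
#' @param map a [recomb_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "recomb_map"))
  n <- nrow(map)
  rate <- attr(map, "rate_cm_mb")
  if (is.null(rate)) {
    rate <- if (n > 1) c(diff(map$cm) / diff(map$bp) * 1e6, 0) else 0
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("position rate.cM.Mb. map.cM.", con)
  # %.17g so coordinates survive a write/read round trip bit-exact
  writeLines(sprintf("%.17g %.17g %.17g", map$bp, rate, map$cm), con)
  invisible(path)
}
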