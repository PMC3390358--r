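#' Firth-penalised logistic regression for a single marker
#'
#' Jeffreys-prior penalised fit of `logit P(case) = b0 + b1 g`, used as a
#' fallback when the plain maximum-likelihood fit separates or fails to
#' converge. Scores are adjusted by the hat values, which keeps estimates
#' finite under separation.
#'
#' @param g dosage vector.
#' @param y 0/1 phenotype vector.
#' @param maxit,tol iteration controls.
#' @return list with `beta` (slope), `se` and `converged`.
#' @export
firth_logistic <- function(g, y, maxit = 100, tol = 1e-7) {
  X <- cbind(1, g)
  b <- c(log(mean(y) / (1 - mean(y))), 0)
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XtWX <- crossprod(X * sqrt(w))
    Vi <- solve(XtWX)
    h <- rowSums((X %*% Vi) * X) * w
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(Vi %*% U)
    b <- b + step
    if (sum(abs(step)) < tol) { converged <- TRUE; break }
  }
  se <- sqrt(diag(solve(XtWX)))
  list(beta = b[2], se = se[2], converged = converged)
}

#' Single-marker logistic association test
#'
#' Maximum-likelihood logistic regression of case status on allele dosage
#' (additive coding) by iteratively reweighted least squares, with a Wald
#' p-value for the dosage effect. On detected separation or non-convergence
#' the fit falls back to [firth_logistic()] and is flagged.
#'
#' @param dosage per-individual dosage in `{0, 1, 2}` (any numeric coding is
#'   accepted, e.g. 0/1 carrier coding).
#' @param phenotype 0/1 vector (1 = case).
#' @param firth use the Firth fallback on unstable fits (default TRUE).
#' @return list with `beta`, `se`, `p` and `flag` (one of `"ok"`,
#'   `"monomorphic"`, `"firth"`).
#' @export
logistic_assoc <- function(dosage, phenotype, firth = TRUE) {
  y <- as.integer(phenotype)
  if (all(y == y[1])) stop("phenotype must contain both cases and controls")
  r <- .logistic_scan(matrix(as.numeric(dosage), ncol = 1), y)
  beta <- r[1, 1]; se <- r[1, 2]; flag <- r[1, 3]
  if (flag == 1)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                flag = "monomorphic"))
  out_flag <- "ok"
  if (flag == 2 && firth) {
    f <- firth_logistic(as.numeric(dosage), y)
    beta <- f$beta; se <- f$se
    out_flag <- "firth"
  } else if (flag == 2) {
    out_flag <- "firth"
  }
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)),
       flag = out_flag)
}

#' Region-wide single-marker association scan
#'
#' Tests every ascertained array marker whose genetic position lies within
#' `flank_cm` of the disease locus (closed interval), excluding markers that
#' are themselves causal variants, and applies a region-wide Bonferroni
#' threshold `alpha / M` with `M` the number of markers actually tested
#' (polymorphic in the sample).
#'
#' @param panel expanded [haplotype_panel()] (consecutive haplotype pairs =
#'   individuals).
#' @param markers variant column indices of the array markers.
#' @param phenotype a `phenotype_assignment` (see [sample_case_control()]).
#' @param causal a `causal_set` (see [select_causal()]); may be empty.
#' @param locus_bounds bp interval of the disease locus.
#' @param map a [recomb_map()] used to place the locus bounds in cM.
#' @param flank_cm genetic flank tested on each side of the locus.
#' @param alpha region-wide significance level.
#' @param firth use the Firth fallback for separated markers.
#' @param dosage_cache optional precomputed dosage matrix (individuals x all
#'   panel variants) to avoid rebuilding dosages from haplotypes on every
#'   call.
#' @return data frame of class `association_result` with one row per tested
#'   marker: `marker`, `index`, `bp`, `cm`, `maf` (sample MAF), `beta`, `se`,
#'   `p`, `significant`, `fallback`, `monomorphic`; attributes `n_tested` and
#'   `threshold`.
#' @export
region_scan <- function(panel, markers, phenotype, causal, locus_bounds,
                        map, flank_cm = 3, alpha = 0.05, firth = TRUE,
                        dosage_cache = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), flank_cm >= 0)
  v <- panel$variants
  locus_cm <- genetic_position(locus_bounds, map)
  win <- c(locus_cm[1] - flank_cm, locus_cm[2] + flank_cm)
  mk <- markers[v$cm[markers] >= win[1] & v$cm[markers] <= win[2]]
  if (length(causal) && nrow(causal))
    mk <- mk[!(v$bp[mk] %in% causal$bp)]
  if (!length(mk)) stop("no testable markers in the region")

  ind <- c(phenotype$cases, phenotype$controls)
  y <- rep(c(1L, 0L), c(length(phenotype$cases), length(phenotype$controls)))
  if (is.null(dosage_cache)) {
    H <- panel$haplotypes
    G <- H[2 * ind - 1, mk, drop = FALSE] + H[2 * ind, mk, drop = FALSE]
  } else {
    G <- dosage_cache[ind, mk, drop = FALSE]
  }
  storage.mode(G) <- "double"

  r <- .logistic_scan(G, y)
  beta <- r[, 1]; se <- r[, 2]; flag <- r[, 3]
  fallback <- flag == 2
  if (any(fallback) && firth) {
    for (j in which(fallback)) {
      f <- firth_logistic(G[, j], y)
      beta[j] <- f$beta; se[j] <- f$se
    }
  }
  mono <- flag == 1
  p <- ifelse(mono, NA_real_, 2 * stats::pnorm(-abs(beta / se)))
  n_tested <- sum(!mono)
  thr <- alpha / n_tested
  f1 <- colMeans(G) / 2
  out <- data.frame(marker = v$id[mk], index = mk, bp = v$bp[mk],
                    cm = v$cm[mk], maf = pmin(f1, 1 - f1),
                    beta = beta, se = se, p = p,
                    significant = !mono & p < thr,
                    fallback = fallback, monomorphic = mono)
  attr(out, "n_tested") <- n_tested
  attr(out, "threshold") <- thr
  class(out) <- c("association_result", "data.frame")
  out
}
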