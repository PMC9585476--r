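# Per-site Weir-Cockerham F_ST, branch-length transform, PBS, derived-allele
# frequency and the percentile rule.  Everything here is a pure function of
# allele counts; vectorised over sites so the genome-wide scan stays cheap.

# Weir-Cockerham variance components for two populations at a bi-allelic site,
# from allele counts (each called chromosome is one haploid observation).
# Vectorised over sites: d1, n1, d2, n2 are parallel vectors of derived-allele
# counts and called-chromosome totals.
#
# With r = 2 groups, weighted mean frequency p_bar, between-group mean square
# MSP = sum n_i (p_i - p_bar)^2 / (r - 1) and within-group mean square
# MSG = sum n_i p_i q_i / sum (n_i - 1), the estimator is
# theta = (MSP - MSG) / (MSP + (n_c - 1) MSG) with
# n_c = (sum n_i - sum n_i^2 / sum n_i) / (r - 1).
# We return a = (MSP - MSG)/n_c and b_plus_c = MSG so that multi-site
# ratio-of-sums aggregation is a plain sum of components.
wc_components <- function(d1, n1, d2, n2) {
  stopifnot(length(d1) == length(n1), length(d2) == length(n2),
            length(d1) == length(d2))
  bad <- n1 < 2 | n2 < 2
  p1 <- d1 / n1
  p2 <- d2 / n2
  ntot <- n1 + n2
  pbar <- (d1 + d2) / ntot
  nc <- ntot - (n1^2 + n2^2) / ntot
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2     # df = r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (ntot - 2)
  a <- (msp - msg) / nc
  b <- msg
  denom <- a + b
  undefined <- bad | (denom == 0)
  fst <- ifelse(undefined, NA_real_, a / denom)
  a[bad] <- NA_real_
  b[bad] <- NA_real_
  list(a = a, b_plus_c = b, fst = fst, undefined = undefined)
}

#' Per-site Weir-Cockerham F_ST from allele counts of two populations
#'
#' Computes the two-population, two-allele Weir-Cockerham (1984) moment
#' estimator with its sample-size correction, treating every called
#' chromosome as one haploid observation.  The among-population variance
#' component `a` and the residual component `b_plus_c` are returned alongside
#' the per-site ratio so that multi-site F_ST can be aggregated as a ratio of
#' summed components (see [fst_region()]).
#'
#' The estimate is undefined (flagged, `fst = NA`) exactly when both
#' populations are monomorphic for the same allele, which zeroes the
#' denominator.  Negative estimates (expected when the two sample frequencies
#' are equal) are returned as-is; clamping happens later, in
#' [branch_length()].
#'
#' @param counts_pop1,counts_pop2 numeric vectors of length 2:
#'   `c(derived_count, called_chromosomes)` for each population.  Each
#'   population needs at least 2 called chromosomes.
#' @return A list of class `fst_components` with elements `a`, `b_plus_c`,
#'   `fst` and logical `undefined`.
#' @examples
#' fst_site(c(50, 50), c(0, 50))$fst   # fixed difference: 1
#' fst_site(c(25, 50), c(25, 50))$fst  # identical frequencies: <= 0
#' @export
fst_site <- function(counts_pop1, counts_pop2) {
  stopifnot(length(counts_pop1) == 2L, length(counts_pop2) == 2L)
  if (counts_pop1[2] < 2 || counts_pop2[2] < 2) {
    stop_config("fst_site: each population needs >= 2 called chromosomes (got %s and %s)",
                counts_pop1[2], counts_pop2[2])
  }
  if (counts_pop1[1] > counts_pop1[2] || counts_pop2[1] > counts_pop2[2]) {
    stop_config("fst_site: derived count exceeds called chromosomes")
  }
  out <- wc_components(counts_pop1[1], counts_pop1[2],
                       counts_pop2[1], counts_pop2[2])
  res <- lapply(out, `[[`, 1L)
  class(res) <- "fst_components"
  res
}

#' Multi-site F_ST as a ratio of summed variance components
#'
#' Aggregates per-site Weir-Cockerham components over a region (or the whole
#' genome) as `sum(a) / sum(a + b_plus_c)`, the standard "ratio of averages"
#' estimator.  Sites flagged undefined are excluded.
#'
#' @param components a list of `fst_components` (from [fst_site()]) or a list
#'   with vector elements `a`, `b_plus_c`, `undefined` (from the internal
#'   vectorised path).
#' @return A list with `fst` and logical `undefined` (true when no site
#'   contributes a non-zero denominator).
#' @export
fst_region <- function(components) {
  if (!is.null(components$a)) {
    a <- components$a
    b <- components$b_plus_c
    undef <- components$undefined
  } else {
    a <- vapply(components, `[[`, numeric(1), "a")
    b <- vapply(components, `[[`, numeric(1), "b_plus_c")
    undef <- vapply(components, `[[`, logical(1), "undefined")
  }
  keep <- !undef & !is.na(a)
  if (!any(keep)) {
    return(list(fst = NA_real_, undefined = TRUE))
  }
  denom <- sum(a[keep] + b[keep])
  if (denom == 0) {
    return(list(fst = NA_real_, undefined = TRUE))
  }
  list(fst = sum(a[keep]) / denom, undefined = FALSE)
}

#' Branch length transform T = -log(1 - F_ST)
#'
#' Log-transforms F_ST into an additive divergence measure on the population
#' tree (natural logarithm).  Estimates are clamped to `[0, 1 - 1e-8]` first:
#' negative moment estimates become a zero-length branch, and F_ST = 1 stays
#' finite.  `NA` (undefined F_ST) propagates.
#'
#' @param fst numeric vector of per-site F_ST estimates.
#' @return numeric vector of branch lengths.
#' @examples
#' branch_length(0.5)    # log(2)
#' branch_length(-0.02)  # 0 after clamping
#' @export
branch_length <- function(fst) {
  clamped <- pmin(pmax(fst, 0), 1 - 1e-8)
  -log(1 - clamped)
}

#' Population branch statistic
#'
#' `PBS_A = (T_AB + T_AC - T_BC) / 2` for a target population A scored
#' against an ingroup B and outgroup C.  Values may be negative; no
#' truncation is applied.  `NA` branch lengths propagate.
#'
#' @param t_ab,t_ac,t_bc numeric vectors of branch lengths from
#'   [branch_length()].
#' @return numeric vector of PBS values.
#' @examples
#' pbs(branch_length(0.1), branch_length(0.2), branch_length(0.05))
#' @export
pbs <- function(t_ab, t_ac, t_bc) {
  (t_ab + t_ac - t_bc) / 2
}

#' Derived allele frequency
#'
#' @param derived_count,called_chromosomes numeric vectors of per-population
#'   derived-allele counts and called chromosome totals
#'   (`called_chromosomes >= 1`).
#' @param polarizable logical vector; sites whose ancestral state could not
#'   be resolved have no derived allele and raise an error.
#' @return numeric vector of frequencies in `[0, 1]`.
#' @export
derived_allele_frequency <- function(derived_count, called_chromosomes,
                                     polarizable = TRUE) {
  polarizable <- rep_len(polarizable, length(derived_count))
  if (any(!polarizable)) {
    stop_config("derived_allele_frequency: unpolarizable site(s) at index %s",
                paste(which(!polarizable), collapse = ", "))
  }
  if (any(called_chromosomes < 1)) {
    stop_config("derived_allele_frequency: called_chromosomes must be >= 1")
  }
  derived_count / called_chromosomes
}

#' Linear-interpolation percentile
#'
#' The percentile rule used by every threshold in the scan: linear
#' interpolation between order statistics (the common "type 7" definition,
#' `h = 1 + (n - 1) q/100`).
#'
#' @param values non-empty numeric vector (NAs dropped).
#' @param q percent in `[0, 100]`; may be a vector.
#' @return numeric vector of thresholds, one per `q`.
#' @examples
#' percentile(1:100, 90)  # 90.1
#' @export
percentile <- function(values, q) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop_config("percentile: no non-missing values")
  }
  if (any(q < 0 | q > 100)) {
    stop_config("percentile: q must lie in [0, 100]")
  }
  unname(stats::quantile(values, probs = q / 100, type = 7, names = FALSE))
}

#' @export
print.fst_components <- function(x, ...) {
  cat("Weir-Cockerham site components\n")
  cat(sprintf("  a = %.6g, b+c = %.6g\n", x$a, x$b_plus_c))
  if (x$undefined) {
    cat("  F_ST undefined (degenerate denominator)\n")
  } else {
    cat(sprintf("  F_ST = %.6f\n", x$fst))
  }
  invisible(x)
}
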