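# Independent oracles and tiny fixture builders shared across the suite.

# Weir-Cockerham two-population F_ST by brute force: expand the allele
# counts into 0/1 indicator vectors (one per called chromosome), run a
# one-way ANOVA, and assemble the estimator from its mean squares:
#   theta = (MSB - MSW) / (MSB + (n_c - 1) MSW).
# Entirely independent of the package's component-sum implementation.
oracle_wc_fst <- function(d1, n1, d2, n2) {
  y <- c(rep(1, d1), rep(0, n1 - d1), rep(1, d2), rep(0, n2 - d2))
  g <- factor(rep(c("p1", "p2"), c(n1, n2)))
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))  # perfect fits warn
  msb <- tab$`Mean Sq`[1]
  msw <- tab$`Mean Sq`[2]
  ntot <- n1 + n2
  nc <- ntot - (n1^2 + n2^2) / ntot
  denom <- msb + (nc - 1) * msw
  if (denom == 0) return(NA_real_)
  (msb - msw) / denom
}

# Hudson-style ratio-of-averages F_ST from true (noise-free) population
# frequencies: sum (p1 - p2)^2 / sum (p1 q2 + p2 q1).
oracle_hudson_fst <- function(p1, p2) {
  sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))
}

# Random allele-count pairs for property tests.
rand_count_pairs <- function(n, seed = 1) {
  withr::with_seed(seed, {
    n1 <- sample(4:100, n, replace = TRUE)
    n2 <- sample(4:100, n, replace = TRUE)
    data.frame(
      d1 = vapply(n1, function(k) sample(0:k, 1), integer(1)),
      n1 = n1,
      d2 = vapply(n2, function(k) sample(0:k, 1), integer(1)),
      n2 = n2
    )
  })
}

# Hand-built site_counts table for toy scan fixtures.  `...` are
# per-population lists: POP = list(derived =, called =).
make_site_counts <- function(chrom, pos, depth, missing, ...) {
  pops <- list(...)
  out <- data.frame(
    chrom = chrom, pos = as.integer(pos),
    site_id = paste0(chrom, ":", pos),
    ref = "A", alt = "G", ancestral = "A", polarizable = TRUE,
    site_mean_depth = depth, missing_fraction = missing,
    stringsAsFactors = FALSE
  )
  for (p in names(pops)) {
    out[[paste0("derived_", p)]] <- as.integer(pops[[p]]$derived)
    out[[paste0("called_", p)]] <- as.integer(pops[[p]]$called)
  }
  attr(out, "populations") <- names(pops)
  class(out) <- c("site_counts", "data.frame")
  out
}

# Small simulated trio panel used by several IO/scan tests; `...` overrides
# any default.
default_test_config <- function(n_sites = 300, seed = 7, ...) {
  args <- list(
    n_sites = n_sites,
    chrom_plan = c(chr1 = 2e6, chr2 = 2e6),
    drift = c(TGT = 0.02, ING = 0.02, OUT = 0.05),
    sample_sizes = c(TGT = 12L, ING = 12L, OUT = 12L),
    seed = seed
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}
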