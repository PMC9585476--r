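# The genome-wide scan: filters, thresholds, hit annotation, local zoom and
# the trio-swap contrast.

toy_trio <- trio_spec("TGT", "ING", "OUT")

test_that("site filters remove by rule with a conserved report", {
  # 10 sites: 2 fail depth, 1 fails missingness, 1 monomorphic, 6 clean
  sc <- make_site_counts(
    chrom = rep("chr1", 10), pos = 1:10 * 100,
    depth = c(9.5, 8, rep(30, 8)),
    missing = c(0, 0, 0.06, rep(0, 7)),
    TGT = list(derived = c(5, 5, 5, 0, 5, 5, 5, 5, 5, 5), called = rep(20, 10)),
    ING = list(derived = c(5, 5, 5, 0, 5, 5, 5, 5, 5, 5), called = rep(20, 10)),
    OUT = list(derived = c(5, 5, 5, 0, 5, 5, 5, 5, 5, 5), called = rep(20, 10))
  )
  flt <- filter_sites(sc, site_filter_config(), toy_trio)
  expect_equal(flt$report$n_kept, 6)
  expect_equal(flt$report$removed_depth, 2)
  expect_equal(flt$report$removed_missing, 1)
  expect_equal(flt$report$removed_monomorphic, 1)
  with(flt$report, expect_equal(
    n_kept + removed_depth + removed_missing + removed_monomorphic + removed_low_call,
    n_input))

  # depth rule off: missing-depth sites pass
  sc$site_mean_depth <- NA_real_
  flt2 <- filter_sites(sc, site_filter_config(min_site_mean_depth = 0), toy_trio)
  expect_equal(flt2$report$removed_depth, 0)
  expect_equal(flt2$report$n_kept, 8)
})

test_that("filter report conserves counts on random panels", {
  for (seed in c(2, 4)) {
    cfg <- default_test_config(n_sites = 400, seed = seed, missing_rate = 0.08)
    sc <- counts_from_panel(sample_genotypes(simulate_trio_frequencies(cfg), cfg))
    rep <- filter_sites(sc, site_filter_config(), toy_trio)$report
    expect_equal(rep$n_kept + rep$removed_depth + rep$removed_missing +
                   rep$removed_monomorphic + rep$removed_low_call,
                 rep$n_input)
  }
})

test_that("scan output is invariant to input record order", {
  cfg <- default_test_config(n_sites = 300, seed = 15)
  sc <- counts_from_panel(sample_genotypes(simulate_trio_frequencies(cfg), cfg))
  shuffled <- sc[withr::with_seed(1, sample(nrow(sc))), ]
  attr(shuffled, "populations") <- attr(sc, "populations")
  class(shuffled) <- class(sc)
  s1 <- compute_pbs(sc, toy_trio)
  s2 <- compute_pbs(shuffled, toy_trio)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$thresholds, s2$thresholds)
})

test_that("percentile thresholds bound the expected tail fractions on a null scan", {
  cfg <- default_test_config(n_sites = 4000, seed = 23,
                             drift = c(TGT = 0.02, ING = 0.02, OUT = 0.02))
  scan <- compute_pbs(counts_from_panel(
    sample_genotypes(simulate_trio_frequencies(cfg), cfg)), toy_trio)
  p <- scan$table$pbs[!is.na(scan$table$pbs)]
  frac_above_p90 <- mean(p > scan$thresholds$p90)
  expect_lt(abs(frac_above_p90 - 0.10), 2 / length(p))  # exact up to interpolation
  expect_true(scan$thresholds$p90 <= scan$thresholds$p99995)
  expect_true(scan$thresholds$p99995 <= scan$thresholds$p99999)
})

test_that("swapped trios satisfy PBS_A + PBS_B = T_AB sitewise", {
  cfg <- default_test_config(n_sites = 500, seed = 29)
  sc <- counts_from_panel(sample_genotypes(simulate_trio_frequencies(cfg), cfg))
  a <- compute_pbs(sc, trio_spec("TGT", "ING", "OUT"))
  b <- compute_pbs(sc, trio_spec("ING", "TGT", "OUT"))
  stopifnot(identical(a$table$site_id, b$table$site_id))
  ok <- !is.na(a$table$pbs) & !is.na(b$table$pbs)
  expect_lt(max(abs(a$table$pbs[ok] + b$table$pbs[ok] - a$table$t_ab[ok])), 1e-12)
})

test_that("hit annotation respects the 20-kb flank boundary and tiers", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1",
                      start = 100000L, end = 110000L,
                      stringsAsFactors = FALSE)
  # 1000 background sites + 10 engineered hits
  pos <- c(seq(1e6, 2e6, length.out = 1000),
           100000 + 1 - 20000,    # exactly at the upstream flank edge
           100000 + 1 - 20001,    # one bp beyond it
           seq(3e6, 3.7e6, length.out = 8))
  tab <- data.frame(
    chrom = "chr1", pos = as.integer(round(pos)),
    site_id = paste0("chr1:", as.integer(round(pos))),
    pbs = c(runif(1000, 0, 0.1), rep(0.9, 2), rep(0.9, 1), rep(0.5, 7)),
    stringsAsFactors = FALSE
  )
  th <- structure(list(p90 = 0.09, p99995 = 0.3, p99999 = 0.7),
                  class = "scan_thresholds")
  hits <- extract_and_annotate_hits(tab, genes, flank_bp = 20000, thresholds = th)
  expect_equal(nrow(hits), 10)
  expect_equal(sum(hits$tier == "99.999"), 3)
  expect_equal(sum(hits$tier == "99.995"), 7)
  at_edge <- hits[hits$pos == 100000 + 1 - 20000, ]
  expect_identical(at_edge$genes, "G1")            # boundary inclusive
  beyond <- hits[hits$pos == 100000 + 1 - 20001, ]
  expect_identical(beyond$genes, "intergenic")     # 20,001 bp upstream
})

test_that("local zoom reports squared dosage correlation with the index variant", {
  tab <- data.frame(
    chrom = "chr1", pos = c(1000L, 2000L, 3000L, 4000L, 5000L),
    site_id = paste0("s", 1:5),
    pbs = c(0.1, 0.8, 0.8, 0.2, 0.3),
    stringsAsFactors = FALSE
  )
  dosage <- rbind(
    s1 = c(0, 1, 2, 1, 0, 2),
    s2 = c(0, 0, 2, 2, 1, 1),   # index (top PBS, smallest pos on tie)
    s3 = c(0, 0, 2, 2, 1, 1),   # identical to index
    s4 = c(2, 2, 0, 0, 1, 1),   # perfectly anticorrelated
    s5 = c(0, 1, 0, NA, 1, 2)   # one missing call
  )
  gene <- list(gene_id = "G", chrom = "chr1", start = 500L, end = 5500L)
  zoom <- local_zoom(tab, dosage, gene, flank_bp = 0)
  expect_true(zoom$is_index[zoom$site_id == "s2"])
  expect_equal(zoom$r2[zoom$site_id == "s2"], 1)
  expect_equal(zoom$r2[zoom$site_id == "s3"], 1)
  expect_equal(zoom$r2[zoom$site_id == "s4"], 1)   # r^2 ignores sign
  # hand-computed Pearson^2 oracles
  expect_equal(zoom$r2[zoom$site_id == "s1"],
               cor(c(0, 1, 2, 1, 0, 2), c(0, 0, 2, 2, 1, 1))^2)
  ok <- !is.na(dosage["s5", ])
  expect_equal(zoom$r2[zoom$site_id == "s5"],
               cor(dosage["s5", ok], dosage["s2", ok])^2)

  expect_error(local_zoom(tab, dosage,
                          list(gene_id = "far", chrom = "chr2",
                               start = 1L, end = 10L)),
               "far")
})

test_that("trio contrast windows each side and detects a downward shift", {
  v <- withr::with_seed(3, rnorm(20000))
  same <- trio_contrast(v, v)
  expect_gt(same$p_value, 0.3)
  expect_lt(same$p_value, 0.7)
  # windowing keeps the open interval between the 90th and 99.995th percentile
  expect_lt(abs(same$n1 / length(v) - (0.99995 - 0.9)), 0.001)

  # a pure location shift is invisible to own-percentile windowing by design;
  # pooled-percentile windowing exposes it
  pooled <- trio_contrast(v - 0.2, v, mode = "pooled")
  expect_lt(pooled$p_value, 0.05)

  # a contracted upper tail is detected under own windowing too
  contracted <- trio_contrast(withr::with_seed(4, rnorm(20000, 0, 0.8)), v)
  expect_lt(contracted$p_value, 0.05)
  expect_error(trio_contrast(v[1:50], v), "fewer than 10")
})

test_that("sweep recovery power rises with the target sweep frequency", {
  power_at <- function(freq) {
    base <- sim_config(n_sites = 20000, seed = 77,
                       drift = c(TGT = 0.02, ING = 0.02, OUT = 0.05),
                       sample_sizes = c(TGT = 48L, ING = 48L, OUT = 48L))
    fr0 <- simulate_trio_frequencies(base)
    idx <- which(fr0$ancestral_freq <= 0.2)[seq_len(30)]
    cfg <- sim_config(n_sites = 20000, seed = 77,
                      drift = c(TGT = 0.02, ING = 0.02, OUT = 0.05),
                      sample_sizes = c(TGT = 48L, ING = 48L, OUT = 48L),
                      sweep_spec = lapply(idx, function(i) sweep_locus(i, "TGT", freq)))
    fr <- simulate_trio_frequencies(cfg)
    scan <- compute_pbs(counts_from_panel(sample_genotypes(fr, cfg)), toy_trio)
    th <- percentile(scan$table$pbs, 99)
    ids <- paste0(fr$chrom, ":", fr$pos)[idx]
    hit <- scan$table$pbs[match(ids, scan$table$site_id)] > th
    mean(hit, na.rm = TRUE)
  }
  pw <- vapply(c(0.4, 0.6, 0.9), power_at, numeric(1))
  expect_true(all(diff(pw) >= 0))
  expect_gt(pw[3], pw[1])
})
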