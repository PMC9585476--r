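# Gene-set curation, variant assignment, the Mann-Whitney shift test and
# Bonferroni control.

mk_set <- function(id, genes) {
  structure(list(set_id = id, description = "", genes = genes),
            class = "gene_set")
}

mk_genes <- function(ids, chrom, start) {
  data.frame(gene_id = ids, chrom = chrom, start = as.integer(start),
             end = as.integer(start + 1000L), stringsAsFactors = FALSE)
}

test_that("curation drops unmapped and non-autosomal genes and small sets", {
  genes <- mk_genes(sprintf("g%02d", 1:15),
                    c(rep("chr1", 12), rep("chrX", 3)),
                    seq(1e4, 15e4, length.out = 15))
  auto <- "chr1"

  # 12 genes, 3 on chrX -> 9 remain -> dropped
  s1 <- mk_set("S1", c(sprintf("g%02d", 1:9), "g13", "g14", "g15"))
  # 12 genes, 2 unmapped -> 10 remain -> kept
  s2 <- mk_set("S2", c(sprintf("g%02d", 1:10), "nope1", "nope2"))
  cur <- prepare_gene_sets(list(s1, s2), genes, autosomes = auto, min_size = 10)
  expect_length(cur$sets, 1)
  expect_identical(cur$sets[[1]]$set_id, "S2")
  expect_identical(cur$report$retained, c(FALSE, TRUE))
  expect_equal(cur$report$n_nonautosomal[1], 3)
  expect_equal(cur$report$n_unmapped[2], 2)

  # engineered 5-set collection where exactly 2 survive
  sets5 <- list(
    mk_set("A", sprintf("g%02d", 1:12)),           # 12 autosomal -> kept
    mk_set("B", sprintf("g%02d", 1:10)),           # 10 -> kept
    mk_set("C", sprintf("g%02d", 1:9)),            # 9 -> dropped
    mk_set("D", c(sprintf("g%02d", 1:8), "g13", "g14")),  # 8 autosomal -> dropped
    mk_set("E", c(sprintf("g%02d", 1:5), paste0("x", 1:7)))  # 5 mapped -> dropped
  )
  cur5 <- prepare_gene_sets(sets5, genes, autosomes = auto, min_size = 10)
  expect_length(cur5$sets, 2)
  expect_identical(sort(vapply(cur5$sets, `[[`, "", "set_id")), c("A", "B"))
  expect_equal(sum(cur5$report$retained), 2)

  expect_error(prepare_gene_sets(list(s1), genes, autosomes = auto),
               "no gene set survives")
})

test_that("variants map to every flanked gene and pool once per set", {
  genes <- mk_genes(c("gA", "gB", "gC"), "chr1", c(10000, 10500, 50000))
  # gA body: 10001..11000 (+flank 9001..12000); gB: 10501..11500 (9501..12500)
  tab <- data.frame(
    chrom = "chr1",
    pos = c(9200L, 10700L, 11200L, 12400L, 30000L, 50500L, 51500L,
            52100L, 90000L, 95000L),
    site_id = paste0("v", 1:10),
    pbs = seq(0.1, 1.0, by = 0.1),
    stringsAsFactors = FALSE
  )
  asg <- variants_to_genes(tab, genes, flank_bp = 1000)
  expect_setequal(asg$gene_variant_idx$gA, c(1, 2, 3))
  expect_setequal(asg$gene_variant_idx$gB, c(2, 3, 4))
  expect_setequal(asg$gene_variant_idx$gC, c(6, 7))   # 52100 is past the flank
  expect_setequal(asg$unassigned_idx, c(5, 8, 9, 10))

  scan_tab <- tab
  res <- run_polygenic_scan(scan_tab,
                            list(mk_set("AB", c("gA", "gB")),
                                 mk_set("C", "gC")),
                            genes, flank_bp = 1000)
  ab <- res[res$set_id == "AB", ]
  expect_equal(ab$n_variants_in_set, 4)           # v2, v3 deduplicated
  expect_equal(ab$n_variants_background, 6)       # complement per test
})

test_that("the shift test reproduces exact and asymptotic references", {
  toy <- mwu_shift_test(c(3, 4, 5), c(1, 2))
  expect_equal(toy$U, 6)
  expect_equal(toy$p_one_sided, 0.1)              # exact: 1 of C(5,2) orderings

  ident <- mwu_shift_test(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_gte(ident$p_one_sided, 0.5)

  shifted <- withr::with_seed(10, mwu_shift_test(rnorm(200, 1), rnorm(200)))
  expect_lt(shifted$p_one_sided, 1e-6)

  # asymptotic path agrees with the reference implementation
  x <- withr::with_seed(11, rnorm(60)); y <- withr::with_seed(12, rnorm(150))
  ours <- mwu_shift_test(x, y)
  ref <- wilcox.test(x, y, alternative = "greater", exact = FALSE, correct = TRUE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p_one_sided, ref$p.value, tolerance = 1e-12)

  # the asymptotic path stays within 0.02 of the exact null distribution
  # (reference: the exact tie-free Wilcoxon distribution) for 15 vs 15
  x15 <- withr::with_seed(13, rnorm(15)); y15 <- withr::with_seed(14, rnorm(15))
  ours15 <- pbscan:::mwu_test(x15, y15, "greater")
  p_exact <- stats::pwilcox(ours15$U - 1, 15, 15, lower.tail = FALSE)
  expect_lt(abs(p_exact - ours15$p), 0.02)
})

test_that("U statistics of the two one-sided tests sum to n1 * n2, ties at half weight", {
  withr::with_seed(21, {
    for (i in 1:25) {
      n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
      x <- sample(0:5, n1, replace = TRUE)   # heavy ties
      y <- sample(0:5, n2, replace = TRUE)
      u1 <- mwu_shift_test(x, y)$U
      u2 <- mwu_shift_test(y, x)$U
      expect_equal(u1 + u2, n1 * n2)
    }
  })
})

test_that("Bonferroni adjustment scales by the curated-set count and caps at 1", {
  genes <- mk_genes(sprintf("g%02d", 1:20), "chr1",
                    seq(1e4, 5e5, length.out = 20))
  pos <- as.integer(seq(5e3, 6e5, by = 500))
  tab <- data.frame(
    chrom = "chr1",
    pos = pos,
    site_id = paste0("v", seq_along(pos)),
    pbs = withr::with_seed(31, runif(length(pos))),
    stringsAsFactors = FALSE
  )
  one <- run_polygenic_scan(tab, list(mk_set("S", sprintf("g%02d", 1:10))),
                            genes, flank_bp = 0)
  expect_equal(one$p_bonferroni, one$p_one_sided)  # m = 1

  many <- run_polygenic_scan(
    tab, lapply(1:12, function(i) {
      mk_set(paste0("S", i),
             sprintf("g%02d", ((i - 1) %% 10) + 1:8))
    }), genes, flank_bp = 0)
  expect_equal(attr(many, "m"), 12)
  expect_equal(many$p_bonferroni, pmin(1, 12 * many$p_one_sided))
  expect_identical(many$significant, many$p_bonferroni < 0.05)
  expect_true(all(diff(many$p_one_sided) >= 0))    # sorted by p
})

test_that("an engineered sweep-enriched set is recovered as the sole significant result", {
  plan <- c(chr1 = 60e6, chr2 = 60e6, chr3 = 60e6)
  base <- sim_config(n_sites = 20000, seed = 55, chrom_plan = plan,
                     drift = c(TGT = 0.02, ING = 0.02, OUT = 0.05),
                     sample_sizes = c(TGT = 48L, ING = 48L, OUT = 48L))
  fr0 <- simulate_trio_frequencies(base)
  idx <- which(fr0$ancestral_freq <= 0.2)[seq_len(30)]
  cfg <- sim_config(n_sites = 20000, seed = 55, chrom_plan = plan,
                    drift = c(TGT = 0.02, ING = 0.02, OUT = 0.05),
                    sample_sizes = c(TGT = 48L, ING = 48L, OUT = 48L),
                    sweep_spec = lapply(idx, function(i) sweep_locus(i, "TGT", 0.9)))
  fr <- simulate_trio_frequencies(cfg)
  scan <- compute_pbs(counts_from_panel(sample_genotypes(fr, cfg)),
                      trio_spec("TGT", "ING", "OUT"))
  gm <- simulate_gene_model(n_genes = 2000, chrom_plan = plan, n_sets = 20,
                            genes_per_set = 40, enriched_set_fraction = 1,
                            sweep_positions = fr[idx, c("chrom", "pos")],
                            seed = 56)
  cur <- prepare_gene_sets(gm$sets, gm$genes, min_size = 10)
  res <- run_polygenic_scan(scan, cur$sets, gm$genes)
  expect_identical(res$set_id[1], "SELECTED_SET")
  expect_identical(res$set_id[res$significant], "SELECTED_SET")
})
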