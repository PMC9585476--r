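# Polygenic-selection machinery: gene-set curation, variant-to-gene
# assignment with flanks, one-sided Mann-Whitney U shift tests of per-set
# PBS distributions against the genomic background, and Bonferroni control.

#' Curate gene sets against the gene interval list
#'
#' Per set: drop genes without an interval (unmapped) and genes on
#' non-autosomes, then drop sets left with fewer than `min_size` genes.
#'
#' @param sets list of `gene_set` objects (see [read_gmt()]).
#' @param genes a `gene_intervals` data.frame.
#' @param autosomes chromosome names counted as autosomal.
#' @param min_size minimum surviving genes per set (default 10).
#' @return list with `sets` (curated list) and `report` (data.frame per
#'   input set: genes in, unmapped, non-autosomal, kept, retained flag).
#' @export
prepare_gene_sets <- function(sets, genes, autosomes = unique(genes$chrom),
                              min_size = 10L) {
  autosomal_genes <- genes$gene_id[genes$chrom %in% autosomes]
  rows <- lapply(sets, function(s) {
    unmapped <- setdiff(s$genes, genes$gene_id)
    nonauto <- setdiff(intersect(s$genes, genes$gene_id), autosomal_genes)
    kept <- setdiff(s$genes, c(unmapped, nonauto))
    data.frame(set_id = s$set_id, n_in = length(s$genes),
               n_unmapped = length(unmapped), n_nonautosomal = length(nonauto),
               n_kept = length(kept), retained = length(kept) >= min_size,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  curated <- Map(function(s, keep_n) {
    s$genes <- intersect(s$genes, autosomal_genes)
    s
  }, sets, report$n_kept)
  curated <- curated[report$retained]
  if (!length(curated)) {
    stop_config("prepare_gene_sets: no gene set survives curation (min_size = %d)",
                min_size)
  }
  list(sets = unname(curated), report = report)
}

#' Assign scanned variants to flanked genes
#'
#' Maps each scanned variant to every gene whose body extended by `flank_bp`
#' contains it.  Returns per-gene PBS values and variant indices (indices
#' into the scan table), so set-level pooling can deduplicate variants
#' shared by two genes of the same set.
#'
#' @param scan a `pbs_scan` object or its per-site table.
#' @param genes a `gene_intervals` data.frame.
#' @param flank_bp assignment window flank (default 20 kb; 0 = gene body
#'   only).
#' @return list with `gene_values` (gene_id -> numeric PBS vector),
#'   `gene_variant_idx` (gene_id -> integer indices), `pbs` (all defined
#'   PBS values), `unassigned_idx` (variants inside no flanked gene).
#' @export
variants_to_genes <- function(scan, genes, flank_bp = 20000) {
  tab <- if (inherits(scan, "pbs_scan")) scan$table else scan
  ok <- !is.na(tab$pbs)
  tab <- tab[ok, , drop = FALSE]
  var_gr <- GenomicRanges::GRanges(
    tab$chrom, IRanges::IRanges(start = tab$pos, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(1L, genes$start + 1L - flank_bp),
                     end = genes$end + flank_bp))
  ov <- GenomicRanges::findOverlaps(var_gr, gene_gr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  gene_variant_idx <- split(qh, genes$gene_id[sh])
  gene_variant_idx <- lapply(gene_variant_idx, unique)
  list(
    gene_values = lapply(gene_variant_idx, function(i) tab$pbs[i]),
    gene_variant_idx = gene_variant_idx,
    pbs = tab$pbs,
    unassigned_idx = setdiff(seq_len(nrow(tab)), unique(qh))
  )
}

# Mann-Whitney U with average-rank tie handling.  p-value: exact enumeration
# over all C(n1+n2, n1) group assignments when the combined sample is below
# `exact_below` (ties handled correctly by construction), otherwise the
# normal approximation with tie correction and continuity correction.
mwu_test <- function(x, y, alternative = c("greater", "less"),
                     exact_below = 20L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) {
    stop_config("mwu_test: both samples must be non-empty")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n < exact_below && choose(n, n1) <= 2e5) {
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- if (alternative == "greater") mean(u_all >= U) else mean(u_all <= U)
  } else {
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      mu <- n1 * n2 / 2
      z <- if (alternative == "greater") (U - mu - 0.5) / sigma
           else (U - mu + 0.5) / sigma
      p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
           else stats::pnorm(z)
    }
  }
  list(U = U, p = p, n1 = n1, n2 = n2)
}

#' One-sided Mann-Whitney U shift test (set above background)
#'
#' Tests whether `set_values` is stochastically larger than
#' `background_values`.  Ties take average ranks (contributing 1/2 to each
#' side's U); the p-value uses exact enumeration for combined samples below
#' 20 observations and the tie- and continuity-corrected normal
#' approximation otherwise.
#'
#' @param set_values,background_values non-empty numeric vectors.
#' @return list with `U`, `p_one_sided`, `n_set`, `n_background`.
#' @examples
#' mwu_shift_test(c(3, 4, 5), c(1, 2))  # U = 6, exact p = 0.1
#' @export
mwu_shift_test <- function(set_values, background_values) {
  res <- mwu_test(set_values, background_values, alternative = "greater")
  list(U = res$U, p_one_sided = res$p, n_set = res$n1, n_background = res$n2)
}

#' Gene-set polygenic-selection scan
#'
#' For each curated set, pools the PBS values of variants assigned to its
#' genes (each variant counted once per set), takes as background all other
#' scanned variants (or, with `background = "genic"`, all variants assigned
#' to some curated gene outside the set), and runs the one-sided shift test.
#' Bonferroni control uses m = number of curated sets.
#'
#' @param scan a `pbs_scan` object or per-site table.
#' @param curated_sets list of curated `gene_set`s from
#'   [prepare_gene_sets()].
#' @param genes a `gene_intervals` data.frame.
#' @param flank_bp variant-to-gene assignment flank (default 20 kb).
#' @param background `"all"` (default) or `"genic"`.
#' @param alpha significance level on the Bonferroni-adjusted p (0.05).
#' @return data.frame of class `polygenic_scan`, one row per set sorted by
#'   p: `set_id`, `n_genes_used`, `n_variants_in_set`,
#'   `n_variants_background`, `U`, `p_one_sided`, `p_bonferroni`,
#'   `significant`.
#' @export
run_polygenic_scan <- function(scan, curated_sets, genes, flank_bp = 20000,
                               background = c("all", "genic"), alpha = 0.05) {
  background <- match.arg(background)
  if (!length(curated_sets)) {
    stop_config("run_polygenic_scan: need at least one curated set")
  }
  assign <- variants_to_genes(scan, genes, flank_bp)
  all_idx <- seq_along(assign$pbs)
  genic_idx <- sort(unique(unlist(assign$gene_variant_idx, use.names = FALSE)))
  m <- length(curated_sets)

  rows <- lapply(curated_sets, function(s) {
    idx <- sort(unique(unlist(assign$gene_variant_idx[
      intersect(s$genes, names(assign$gene_variant_idx))], use.names = FALSE)))
    bg_pool <- if (background == "all") all_idx else genic_idx
    bg <- setdiff(bg_pool, idx)
    if (!length(idx) || !length(bg)) {
      return(data.frame(set_id = s$set_id, n_genes_used = length(s$genes),
                        n_variants_in_set = length(idx),
                        n_variants_background = length(bg),
                        U = NA_real_, p_one_sided = NA_real_,
                        p_bonferroni = NA_real_, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    res <- mwu_shift_test(assign$pbs[idx], assign$pbs[bg])
    p_adj <- min(1, m * res$p_one_sided)
    data.frame(set_id = s$set_id, n_genes_used = length(s$genes),
               n_variants_in_set = length(idx),
               n_variants_background = length(bg),
               U = res$U, p_one_sided = res$p_one_sided,
               p_bonferroni = p_adj, significant = p_adj < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_one_sided), ]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "background") <- background
  class(out) <- c("polygenic_scan", "data.frame")
  out
}

#' @export
print.polygenic_scan <- function(x, ...) {
  cat(sprintf("Polygenic-selection scan: %d gene set(s), Bonferroni m = %d, background = %s\n",
              nrow(x), attr(x, "m"), attr(x, "background")))
  cat(sprintf("  %d set(s) significant at adjusted 0.05\n", sum(x$significant)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  invisible(x)
}
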