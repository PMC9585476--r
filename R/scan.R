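# The genome-wide PBS scan: site filtering, per-site PBS for a named trio,
# percentile thresholds, hit extraction with gene annotation, local-zoom LD
# tables, and the trio-swap distribution contrast.

#' Trio design for a PBS scan
#'
#' @param target population scored for branch-specific selection (A).
#' @param ingroup closely related reference (B).
#' @param outgroup distant reference (C).
#' @return A list of class `trio_spec`.
#' @export
trio_spec <- function(target, ingroup, outgroup) {
  labs <- c(target, ingroup, outgroup)
  if (length(unique(labs)) != 3L) {
    stop_config("trio_spec: target, ingroup and outgroup must be three distinct labels")
  }
  structure(list(target = target, ingroup = ingroup, outgroup = outgroup),
            class = "trio_spec")
}

#' Site filters applied before PBS calculation
#'
#' Defaults follow the standard high-coverage scan recipe: site mean depth of
#' at least 10 reads, missing rate below 5%, and the site polymorphic in at
#' least one of the three trio populations.  Set `min_site_mean_depth = 0`
#' to disable the depth rule (sites lacking DP pass only then).
#'
#' @param min_site_mean_depth minimum site-level mean depth (reads).
#' @param max_missing_fraction maximum missing-call fraction (strict `<`).
#' @param require_polymorphic_in_any drop sites monomorphic in all three
#'   trio populations.
#' @return A list of class `site_filter_config`.
#' @export
site_filter_config <- function(min_site_mean_depth = 10,
                               max_missing_fraction = 0.05,
                               require_polymorphic_in_any = TRUE) {
  if (min_site_mean_depth < 0 || max_missing_fraction < 0) {
    stop_config("site_filter_config: thresholds must be non-negative")
  }
  structure(list(min_site_mean_depth = min_site_mean_depth,
                 max_missing_fraction = max_missing_fraction,
                 require_polymorphic_in_any = isTRUE(require_polymorphic_in_any)),
            class = "site_filter_config")
}

counts_cols <- function(sites, pop, what) {
  col <- paste0(what, "_", pop)
  if (is.null(sites[[col]])) {
    stop_config("site_counts table has no column '%s'; population '%s' not tabulated",
                col, pop)
  }
  sites[[col]]
}

#' Filter sites ahead of the PBS scan
#'
#' Applies, in order: the depth rule (`site_mean_depth >= min`, with missing
#' depth failing unless the rule is disabled), the missingness rule
#' (`missing_fraction < max`), the polymorphism rule (derived frequency
#' strictly between 0 and 1 in at least one trio population), and a
#' low-call rule (any trio population with fewer than 2 called chromosomes).
#' Each removed site is attributed to the first rule it fails, so the report
#' counts are conserved: removals + survivors = input.
#'
#' @param sites a `site_counts` data.frame.
#' @param cfg a [site_filter_config()].
#' @param trio a [trio_spec()].
#' @return list with `sites` (the surviving subset) and `report` (named
#'   removal counts plus `n_input`, `n_kept`).
#' @export
filter_sites <- function(sites, cfg = site_filter_config(), trio) {
  stopifnot(inherits(trio, "trio_spec"))
  pops <- unlist(trio[c("target", "ingroup", "outgroup")])
  n <- nrow(sites)

  if (cfg$min_site_mean_depth > 0) {
    pass_depth <- !is.na(sites$site_mean_depth) &
      sites$site_mean_depth >= cfg$min_site_mean_depth
  } else {
    pass_depth <- rep(TRUE, n)
  }
  pass_missing <- sites$missing_fraction < cfg$max_missing_fraction

  d <- lapply(pops, function(p) counts_cols(sites, p, "derived"))
  m <- lapply(pops, function(p) counts_cols(sites, p, "called"))
  poly_any <- Reduce(`|`, Map(function(dc, cc) dc > 0 & dc < cc, d, m))
  pass_poly <- if (cfg$require_polymorphic_in_any) poly_any else rep(TRUE, n)
  pass_calls <- Reduce(`&`, lapply(m, function(cc) cc >= 2))

  fail_rule <- rep(NA_character_, n)
  fail_rule[!pass_calls] <- "low_call"
  fail_rule[!pass_poly] <- "monomorphic"
  fail_rule[!pass_missing] <- "missing"
  fail_rule[!pass_depth] <- "depth"    # last assignment wins = first rule

  keep <- is.na(fail_rule)
  report <- list(
    n_input = n,
    n_kept = sum(keep),
    removed_depth = sum(fail_rule == "depth", na.rm = TRUE),
    removed_missing = sum(fail_rule == "missing", na.rm = TRUE),
    removed_monomorphic = sum(fail_rule == "monomorphic", na.rm = TRUE),
    removed_low_call = sum(fail_rule == "low_call", na.rm = TRUE)
  )
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- attr(sites, "populations")
  class(out) <- class(sites)
  list(sites = out, report = report)
}

scan_thresholds <- function(pbs_values) {
  th <- percentile(pbs_values, c(90, 99.995, 99.999))
  structure(list(p90 = th[1], p99995 = th[2], p99999 = th[3]),
            class = "scan_thresholds")
}

#' Per-site PBS for a trio from a site-counts table
#'
#' The computational heart of the scan: filters sites, computes per-site
#' Weir-Cockerham F_ST for the three population pairs, log-transforms to
#' branch lengths (negative estimates clamped to 0, F_ST = 1 kept finite)
#' and evaluates `PBS = (T_AB + T_AC - T_BC)/2` for the target.  Raw
#' (unclamped) F_ST values are retained for audit.  Percentile thresholds
#' (90th, 99.995th, 99.999th) are computed on the surviving sites' defined
#' PBS values.
#'
#' @param sites a `site_counts` data.frame covering the trio populations.
#' @param trio a [trio_spec()].
#' @param cfg a [site_filter_config()].
#' @return An object of class `pbs_scan`: list with `table` (per-site
#'   `chrom`, `pos`, `site_id`, `fst_ab`, `fst_ac`, `fst_bc`, `t_ab`,
#'   `t_ac`, `t_bc`, `pbs`), `thresholds`, `filter_report`, `trio`.
#' @export
compute_pbs <- function(sites, trio, cfg = site_filter_config()) {
  stopifnot(inherits(trio, "trio_spec"))
  input_order <- order(sites$chrom, sites$pos)
  sites <- sites[input_order, , drop = FALSE]
  flt <- filter_sites(sites, cfg, trio)
  s <- flt$sites
  if (nrow(s) == 0L) {
    stop_config("compute_pbs: no sites survive filtering")
  }
  A <- trio$target; B <- trio$ingroup; C <- trio$outgroup
  dA <- counts_cols(s, A, "derived"); nA <- counts_cols(s, A, "called")
  dB <- counts_cols(s, B, "derived"); nB <- counts_cols(s, B, "called")
  dC <- counts_cols(s, C, "derived"); nC <- counts_cols(s, C, "called")

  ab <- wc_components(dA, nA, dB, nB)
  ac <- wc_components(dA, nA, dC, nC)
  bc <- wc_components(dB, nB, dC, nC)
  t_ab <- branch_length(ab$fst)
  t_ac <- branch_length(ac$fst)
  t_bc <- branch_length(bc$fst)

  tab <- data.frame(
    chrom = s$chrom, pos = s$pos, site_id = s$site_id,
    fst_ab = ab$fst, fst_ac = ac$fst, fst_bc = bc$fst,
    t_ab = t_ab, t_ac = t_ac, t_bc = t_bc,
    pbs = pbs(t_ab, t_ac, t_bc),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab,
                 thresholds = scan_thresholds(tab$pbs),
                 filter_report = flt$report,
                 trio = trio),
            class = "pbs_scan")
}

#' Run a genome-wide PBS scan from VCF + population map
#'
#' Thin orchestration over [read_popmap()], [read_vcf_counts()] and
#' [compute_pbs()].  Trio labels are validated against the population map
#' before any genotypes are read.
#'
#' @param vcf_path VCF with GT (and ideally DP, INFO AA).
#' @param popmap_path two-column population map.
#' @param trio a [trio_spec()].
#' @param cfg a [site_filter_config()].
#' @return A `pbs_scan` object (see [compute_pbs()]).
#' @export
run_pbs_scan <- function(vcf_path, popmap_path, trio,
                         cfg = site_filter_config()) {
  stopifnot(inherits(trio, "trio_spec"))
  popmap <- read_popmap(popmap_path)
  pops <- unlist(trio[c("target", "ingroup", "outgroup")])
  absent <- setdiff(pops, popmap)
  if (length(absent)) {
    stop_config("run_pbs_scan: trio population(s) %s absent from population map",
                paste(absent, collapse = ", "))
  }
  sites <- read_vcf_counts(vcf_path, popmap, populations = unname(pops))
  compute_pbs(sites, trio, cfg)
}

#' Extract top-percentile hits and annotate them with nearby genes
#'
#' Hits are sites with PBS above the 99.995th-percentile threshold; sites
#' also above the 99.999th percentile are tier "99.999", the rest tier
#' "99.995".  Each hit is labelled with every gene whose body extended by
#' `flank_bp` on both sides contains it (boundary-inclusive); hits in no
#' flanked gene are labelled `intergenic`.
#'
#' @param scan a `pbs_scan` object (or its `table` plus `thresholds`).
#' @param genes a `gene_intervals` data.frame (0-based half-open).
#' @param flank_bp flank added to each gene body (default 20 kb).
#' @param thresholds optional `scan_thresholds` override.
#' @return data.frame of hits: site columns, `pbs`, `tier`, `genes`
#'   (semicolon-separated gene ids or "intergenic").
#' @export
extract_and_annotate_hits <- function(scan, genes, flank_bp = 20000,
                                      thresholds = NULL) {
  tab <- if (inherits(scan, "pbs_scan")) scan$table else scan
  thresholds <- thresholds %||%
    (if (inherits(scan, "pbs_scan")) scan$thresholds else NULL)
  if (is.null(thresholds)) {
    stop_config("extract_and_annotate_hits: thresholds required")
  }
  hit <- !is.na(tab$pbs) & tab$pbs > thresholds$p99995
  hits <- tab[hit, , drop = FALSE]
  hits$tier <- ifelse(hits$pbs > thresholds$p99999, "99.999", "99.995")
  hits$genes <- "intergenic"
  if (nrow(hits) > 0 && nrow(genes) > 0) {
    hit_gr <- GenomicRanges::GRanges(
      hits$chrom, IRanges::IRanges(start = hits$pos, width = 1L))
    gene_gr <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(start = pmax(1L, genes$start + 1L - flank_bp),
                       end = genes$end + flank_bp))
    ov <- GenomicRanges::findOverlaps(hit_gr, gene_gr)
    if (length(ov)) {
      lab <- tapply(genes$gene_id[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov),
                    function(g) paste(sort(unique(g)), collapse = ";"))
      hits$genes[as.integer(names(lab))] <- unname(lab)
    }
  }
  rownames(hits) <- NULL
  hits
}

#' Local PBS + LD table around one gene
#'
#' Restricts the scan table to the gene body plus `flank_bp` on each side,
#' identifies the index variant (highest PBS; ties broken by smallest
#' position) and reports each site's squared genotype-dosage correlation
#' (composite r^2) with the index variant, missing calls pairwise-excluded.
#'
#' @param scan a `pbs_scan` object or its per-site table.
#' @param dosage sites x samples derived-allele dosage matrix with
#'   `rownames = site_id` (e.g. from [sample_genotypes()]).
#' @param gene a single-row `gene_intervals` data.frame (or list with
#'   `gene_id`, `chrom`, `start`, `end`).
#' @param flank_bp window flank (default 20 kb).
#' @return data.frame: site columns, `pbs`, `r2`, logical `is_index`.
#' @export
local_zoom <- function(scan, dosage, gene, flank_bp = 20000) {
  tab <- if (inherits(scan, "pbs_scan")) scan$table else scan
  g <- as.list(gene)
  win <- tab$chrom == g$chrom &
    tab$pos >= g$start + 1L - flank_bp &
    tab$pos <= g$end + flank_bp
  win <- win & !is.na(tab$pbs)
  if (!any(win)) {
    stop_config("local_zoom: no scanned sites in the window of gene '%s'", g$gene_id)
  }
  loc <- tab[win, , drop = FALSE]
  top <- which(loc$pbs == max(loc$pbs))
  idx <- top[which.min(loc$pos[top])]
  rows <- match(loc$site_id, rownames(dosage))
  if (anyNA(rows)) {
    stop_config("local_zoom: %d window site(s) missing from the dosage matrix",
                sum(is.na(rows)))
  }
  ref_vec <- dosage[rows[idx], ]
  loc$r2 <- apply(dosage[rows, , drop = FALSE], 1L, function(v) {
    ok <- !is.na(v) & !is.na(ref_vec)
    if (sum(ok) < 2 || stats::sd(v[ok]) == 0 || stats::sd(ref_vec[ok]) == 0) {
      if (all(v[ok] == ref_vec[ok])) 1 else NA_real_
    } else {
      stats::cor(v[ok], ref_vec[ok])^2
    }
  })
  loc$is_index <- seq_len(nrow(loc)) == idx
  rownames(loc) <- NULL
  loc
}

#' Trio-swap PBS distribution contrast
#'
#' Compares the bulk of two PBS distributions (e.g. target A vs the swapped
#' trio with B as target) after windowing each to the open interval between
#' its own 90th and 99.995th percentiles, which discards both the noise
#' floor and the extreme sweep tail.  A one-sided Mann-Whitney U test of
#' "first distribution lower than second" is reported.
#'
#' @param scan1,scan2 `pbs_scan` objects or numeric PBS vectors.
#' @param window percent bounds, default `c(90, 99.995)`.
#' @param mode `"own"` (default): each side windowed by its own percentiles;
#'   `"pooled"`: both sides windowed by the pooled distribution's.
#' @return object of class `trio_contrast`: `U`, `p_value`, `median1`,
#'   `median2`, `n1`, `n2`, `window`, `mode`.
#' @export
trio_contrast <- function(scan1, scan2, window = c(90, 99.995),
                          mode = c("own", "pooled")) {
  mode <- match.arg(mode)
  v1 <- if (inherits(scan1, "pbs_scan")) scan1$table$pbs else scan1
  v2 <- if (inherits(scan2, "pbs_scan")) scan2$table$pbs else scan2
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  clip <- function(v, lo, hi) v[v > lo & v < hi]
  if (mode == "own") {
    v1w <- clip(v1, percentile(v1, window[1]), percentile(v1, window[2]))
    v2w <- clip(v2, percentile(v2, window[1]), percentile(v2, window[2]))
  } else {
    pooled <- c(v1, v2)
    lo <- percentile(pooled, window[1]); hi <- percentile(pooled, window[2])
    v1w <- clip(v1, lo, hi); v2w <- clip(v2, lo, hi)
  }
  if (length(v1w) < 10 || length(v2w) < 10) {
    stop_config("trio_contrast: fewer than 10 values on one side after windowing (%d, %d)",
                length(v1w), length(v2w))
  }
  res <- mwu_test(v1w, v2w, alternative = "less")
  structure(list(U = res$U, p_value = res$p,
                 median1 = stats::median(v1w), median2 = stats::median(v2w),
                 n1 = length(v1w), n2 = length(v2w),
                 window = window, mode = mode),
            class = "trio_contrast")
}

#' @export
print.trio_contrast <- function(x, ...) {
  cat("Trio-swap PBS contrast (one-sided Mann-Whitney U: first < second)\n")
  cat(sprintf("  window: (%g, %g) percentiles, %s mode\n",
              x$window[1], x$window[2], x$mode))
  cat(sprintf("  n = %d vs %d; medians %.5f vs %.5f\n",
              x$n1, x$n2, x$median1, x$median2))
  cat(sprintf("  U = %.1f, p = %.3g\n", x$U, x$p_value))
  invisible(x)
}

#' @export
print.pbs_scan <- function(x, ...) {
  cat(sprintf("PBS scan: target %s vs ingroup %s, outgroup %s\n",
              x$trio$target, x$trio$ingroup, x$trio$outgroup))
  cat(sprintf("  %d / %d sites retained after filtering\n",
              x$filter_report$n_kept, x$filter_report$n_input))
  cat(sprintf("  thresholds: p90 = %.4f, p99.995 = %.4f, p99.999 = %.4f\n",
              x$thresholds$p90, x$thresholds$p99995, x$thresholds$p99999))
  invisible(x)
}

#' @export
summary.pbs_scan <- function(object, ...) {
  p <- object$table$pbs
  out <- list(
    trio = object$trio,
    filter_report = object$filter_report,
    thresholds = object$thresholds,
    pbs_summary = summary(p[!is.na(p)]),
    n_above_p99995 = sum(p > object$thresholds$p99995, na.rm = TRUE),
    n_above_p99999 = sum(p > object$thresholds$p99999, na.rm = TRUE)
  )
  class(out) <- "summary.pbs_scan"
  out
}

#' @export
print.summary.pbs_scan <- function(x, ...) {
  cat(sprintf("PBS scan summary (target %s)\n", x$trio$target))
  rep <- x$filter_report
  cat(sprintf("  sites: %d in, %d kept (depth %d, missing %d, monomorphic %d, low-call %d removed)\n",
              rep$n_input, rep$n_kept, rep$removed_depth, rep$removed_missing,
              rep$removed_monomorphic, rep$removed_low_call))
  print(x$pbs_summary)
  cat(sprintf("  hits: %d above 99.995th, %d above 99.999th percentile\n",
              x$n_above_p99995, x$n_above_p99999))
  invisible(x)
}

#' Manhattan-style plot of a PBS scan
#'
#' Base-graphics per-site PBS with dashed lines at the 99.995th and
#' 99.999th-percentile thresholds.
#'
#' @param x a `pbs_scan` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pbs_scan <- function(x, ...) {
  tab <- x$table
  chroms <- unique(tab$chrom)
  offset <- c(0, cumsum(vapply(chroms, function(ch) {
    max(tab$pos[tab$chrom == ch])
  }, numeric(1))))
  names(offset) <- c(chroms, "end")
  gx <- tab$pos + offset[tab$chrom]
  col <- (match(tab$chrom, chroms) %% 2) + 1
  graphics::plot(gx, tab$pbs, pch = 16, cex = 0.4,
                 col = c("grey40", "steelblue")[col],
                 xlab = "genome position", ylab = "PBS", ...)
  graphics::abline(h = x$thresholds$p99995, lty = 2, col = "orange")
  graphics::abline(h = x$thresholds$p99999, lty = 2, col = "red")
  invisible(x)
}
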