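# Readers and writers for every external format the pipeline touches:
# population maps, VCF (via vcfR), BED gene intervals, GMT gene sets, and the
# tab-delimited ROH and haplogroup-count tables.  All readers accept
# gzip-compressed input (R connections decompress transparently).

#' Read a two-column population map
#'
#' Tab-delimited, header line, columns sample id and population label.
#'
#' @param path file path (optionally gzipped).
#' @return named character vector: sample id -> population label, with the
#'   set of labels in `attr(, "populations")`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) {
    stop_config("read_popmap: expected two tab-delimited columns in %s", path)
  }
  if (nrow(df) == 0L) {
    stop_config("read_popmap: %s contains no samples", path)
  }
  dup <- df[[1]][duplicated(df[[1]])]
  if (length(dup)) {
    stop_config("read_popmap: duplicated sample(s): %s",
                paste(unique(dup), collapse = ", "))
  }
  out <- stats::setNames(as.character(df[[2]]), df[[1]])
  attr(out, "populations") <- unique(as.character(df[[2]]))
  out
}

#' Write a population map
#' @param popmap named character vector (sample -> population).
#' @param path output path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(
    data.frame(sample = names(popmap), population = as.character(popmap)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# Dosage lookup for diploid GT strings ("0/0", "0|1", "./.", ...): number of
# ALT alleles, NA when any allele is missing.
gt_to_alt_dosage <- function(gt) {
  u <- unique(gt)
  a1 <- substr(u, 1, 1)
  a2 <- substr(u, 3, 3)
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | is.na(u) | u == "."] <- NA_integer_
  as.integer(d)[match(gt, u)]
}

#' Read per-site, per-population derived-allele counts from a VCF
#'
#' Streams bi-allelic SNV records into the `site_counts` table that all
#' F_ST/PBS math consumes.  The derived allele is resolved from the `AA`
#' INFO tag (uppercased): `AA == REF` makes ALT the derived allele,
#' `AA == ALT` flips the count.  Sites whose `AA` is missing or matches
#' neither allele are retained but flagged unpolarizable (their "derived"
#' counts are ALT counts; F_ST and PBS need no polarity, DAF refuses them).
#' Multi-allelic and non-SNV records are skipped with a logged count.
#'
#' @param vcf_path VCF file (plain or gzipped), FORMAT must include GT; DP is
#'   used for site mean depth when present.
#' @param popmap named vector from [read_popmap()].
#' @param populations labels to tabulate; must be a subset of the popmap's.
#' @return A `site_counts` data.frame: `chrom`, `pos`, `site_id`, `ref`,
#'   `alt`, `ancestral`, `polarizable`, `site_mean_depth` (NA when DP
#'   absent), `missing_fraction`, then `derived_<pop>` and `called_<pop>`
#'   per population.
#' @export
read_vcf_counts <- function(vcf_path, popmap, populations = NULL) {
  populations <- populations %||% unique(as.character(popmap))
  if (!all(populations %in% popmap)) {
    stop_config("read_vcf_counts: population(s) %s not present in popmap",
                paste(setdiff(populations, popmap), collapse = ", "))
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))

  vcf_samples <- colnames(vcf@gt)[-1]
  wanted <- names(popmap)[popmap %in% populations]
  missing_samples <- setdiff(wanted, vcf_samples)
  if (length(missing_samples)) {
    stop_config("read_vcf_counts: sample(s) %s absent from VCF header",
                paste(missing_samples, collapse = ", "))
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snv)
  if (n_skip > 0) {
    pbscan_log("read_vcf_counts: skipped %d multi-allelic/non-SNV record(s)", n_skip)
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  aa <- toupper(vcfR::extract.info(vcf, element = "AA"))

  keep <- which(snv)
  ref <- ref[keep]; alt <- alt[keep]; aa <- aa[keep]
  gt <- gt[keep, wanted, drop = FALSE]
  dp <- if (is.null(dp)) NULL else dp[keep, wanted, drop = FALSE]

  dosage <- matrix(gt_to_alt_dosage(as.vector(gt)), nrow = nrow(gt))
  polarizable <- !is.na(aa) & (aa == ref | aa == alt)
  n_unpol <- sum(!polarizable)
  if (n_unpol > 0) {
    pbscan_log("read_vcf_counts: %d site(s) flagged unpolarizable (AA missing or off-allele)",
               n_unpol)
  }

  ids <- fix[keep, "ID"]
  pos <- as.integer(fix[keep, "POS"])
  chrom <- fix[keep, "CHROM"]
  out <- data.frame(
    chrom = chrom,
    pos = pos,
    site_id = ifelse(is.na(ids) | ids == ".", paste0(chrom, ":", pos), ids),
    ref = ref,
    alt = alt,
    ancestral = ifelse(polarizable, aa, NA_character_),
    polarizable = polarizable,
    stringsAsFactors = FALSE
  )
  out$site_mean_depth <- if (is.null(dp)) NA_real_ else rowMeans(dp, na.rm = TRUE)
  out$site_mean_depth[is.nan(out$site_mean_depth)] <- NA_real_
  out$missing_fraction <- rowMeans(is.na(dosage))

  flip <- polarizable & aa == alt   # derived allele is REF
  pop_of <- as.character(popmap[wanted])
  for (p in populations) {
    cols <- pop_of == p
    sub <- dosage[, cols, drop = FALSE]
    called <- 2L * rowSums(!is.na(sub))
    alt_count <- rowSums(sub, na.rm = TRUE)
    derived <- ifelse(flip, called - alt_count, alt_count)
    out[[paste0("derived_", p)]] <- as.integer(derived)
    out[[paste0("called_", p)]] <- as.integer(called)
  }
  zero <- Reduce(`+`, lapply(populations, function(p) out[[paste0("called_", p)]])) == 0
  if (any(zero)) {
    pbscan_log("read_vcf_counts: %d site(s) have no called chromosomes in the selected populations",
               sum(zero))
  }
  attr(out, "populations") <- populations
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Write a simulated panel to VCF v4.2
#'
#' Emits bi-allelic SNVs with `INFO AA=<ancestral base>` and per-sample
#' `GT:DP` (DP = the site's mean depth for called genotypes, missing calls as
#' `./.`).  Records are sorted by (chrom, pos); unsorted input is sorted with
#' a log message.  [read_vcf_counts()] on the output reproduces the panel's
#' counts exactly.
#'
#' @param panel a `sim_panel` from [sample_genotypes()].
#' @param path output path (`.vcf`; use [write_popmap()] for the map).
#' @return the path, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "sim_panel"))
  sites <- panel$sites
  dosage <- panel$dosage
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    pbscan_log("write_vcf: input records unsorted; sorting by (chrom, pos)")
    sites <- sites[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
  }
  # Derived dosage -> ALT dosage: when the ancestral allele is ALT, the
  # derived allele is REF, so ALT dosage = 2 - derived dosage.
  altd <- dosage
  flipped <- !sites$aa_is_ref
  altd[flipped, ] <- 2L - altd[flipped, , drop = FALSE]

  gt_strings <- c("0/0", "0/1", "1/1")
  dp_int <- as.integer(round(sites$site_mean_depth))
  cells <- matrix("./.", nrow = nrow(altd), ncol = ncol(altd))
  called <- !is.na(altd)
  cells[called] <- paste0(gt_strings[altd[called] + 1L], ":",
                          rep(dp_int, ncol(altd))[called])

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pbscan",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dosage)), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, sites$site_id, sites$ref, sites$alt, ".", "PASS",
    paste0("AA=", sites$ancestral), "GT:DP",
    apply(cells, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read BED3+name gene intervals
#'
#' 0-based half-open coordinates are kept as-is (so a gene covering BED
#' `[start, end)` contains 1-based positions `start+1 .. end`).  Output is
#' sorted by (chrom, start).
#'
#' @param path BED file with columns chrom, start, end, name.
#' @return A `gene_intervals` data.frame: `gene_id`, `chrom`, `start`, `end`.
#' @export
read_bed_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("gene_intervals", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop_config("read_bed_genes: line %d has fewer than 4 fields",
                which(nf < 4L)[1])
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad)) {
    stop_config("read_bed_genes: invalid interval (start >= end or non-numeric) at line %d",
                which(bad)[1])
  }
  out <- data.frame(
    gene_id = vapply(fields, `[[`, "", 4L),
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end, stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) {
    stop_config("read_bed_genes: duplicate gene_id '%s'",
                out$gene_id[duplicated(out$gene_id)][1])
  }
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("gene_intervals", "data.frame")
  out
}

#' Write gene intervals as BED3+name
#' @param genes a `gene_intervals` data.frame.
#' @param path output path.
#' @export
write_bed_genes <- function(genes, path) {
  writeLines(paste(genes$chrom, genes$start, genes$end, genes$gene_id,
                   sep = "\t"), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then gene names, tab-delimited.
#' Duplicate genes within a set are removed with a log message.
#'
#' @param path GMT file.
#' @return list of `gene_set` objects (`set_id`, `description`, `genes`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_config("read_gmt: line %d has fewer than 3 fields", which(nf < 3L)[1])
  }
  lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      pbscan_log("read_gmt: set '%s': removed %d duplicate gene name(s)",
                 f[1], sum(duplicated(genes)))
      genes <- unique(genes)
    }
    if (!length(genes)) {
      stop_config("read_gmt: set '%s' (line %d) has no genes", f[1], i)
    }
    structure(list(set_id = f[1], description = f[2], genes = genes),
              class = "gene_set")
  })
}

#' Write gene sets in GMT format
#' @param sets list of `gene_set` objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(sets, function(s) {
    paste(c(s$set_id, s$description, s$genes), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a tab-delimited ROH segment table
#'
#' Columns `sample`, `chrom`, `start`, `end` (1-based inclusive) and
#' optionally `length`; lengths are validated as `end - start + 1 > 0`.
#'
#' @param path file path.
#' @return A `roh_segments` data.frame.
#' @export
read_roh <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop_config("read_roh: missing column(s): %s",
                paste(setdiff(need, names(df)), collapse = ", "))
  }
  len <- df$end - df$start + 1L
  if (any(len <= 0)) {
    stop_config("read_roh: non-positive segment length at row %d", which(len <= 0)[1])
  }
  if (!is.null(df$length) && any(df$length != len)) {
    stop_config("read_roh: stated length disagrees with end - start + 1 at row %d",
                which(df$length != len)[1])
  }
  df$length <- as.integer(len)
  df <- df[, c("sample", "chrom", "start", "end", "length")]
  class(df) <- c("roh_segments", "data.frame")
  df
}

#' Write an ROH segment table
#' @param segments a `roh_segments` data.frame.
#' @param path output path.
#' @export
write_roh <- function(segments, path) {
  utils::write.table(as.data.frame(segments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population x haplogroup count table
#'
#' Tab-delimited; first column = population label, remaining columns =
#' haplogroup counts (non-negative integers).
#'
#' @param path file path.
#' @return A `haplogroup_table` integer matrix with `attr(, "n")` = row sums.
#' @export
read_haplogroup_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop_config("read_haplogroup_table: expected population column plus counts")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(is.na(suppressWarnings(as.numeric(m))) | m < 0 |
                 as.numeric(m) != floor(as.numeric(m)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop_config("read_haplogroup_table: non-integer or negative count at row %d, column '%s'",
                rc[1], colnames(m)[rc[2]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  attr(m, "n") <- rowSums(m)
  structure(m, class = c("haplogroup_table", class(m)))
}

#' Write a haplogroup count table
#' @param table a `haplogroup_table` matrix.
#' @param path output path.
#' @export
write_haplogroup_table <- function(table, path) {
  df <- data.frame(population = rownames(table),
                   as.data.frame(unclass(table), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
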