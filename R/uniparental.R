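# Haplogroup-frequency summaries (diversity statistic, frequency-space PCA)
# and runs-of-homozygosity classification and summary metrics.

#' Haplogroup diversity per population
#'
#' `HD = n (1 - sum x^2) / (n - 1)`, where n is the population's sample size
#' (row sum of the count table) and x the within-population haplogroup
#' frequencies — the unbiased heterozygosity analogue over haplogroups.
#' Populations with n < 2 are skipped with a warning.
#'
#' @param table a `haplogroup_table` (populations x haplogroups counts).
#' @return data.frame: `population`, `n`, `hd`.
#' @examples
#' m <- matrix(c(5, 5, 9, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("P1", "P2"), c("H1", "H2")))
#' haplogroup_diversity(m)   # HD 0.5556 and 0.2
#' @export
haplogroup_diversity <- function(table) {
  m <- unclass(table)
  n <- rowSums(m)
  ok <- n >= 2
  if (any(!ok)) {
    warning(sprintf("haplogroup_diversity: skipping population(s) with n < 2: %s",
                    paste(rownames(m)[!ok], collapse = ", ")))
  }
  m <- m[ok, , drop = FALSE]
  n <- n[ok]
  x2 <- rowSums((m / n)^2)
  data.frame(population = rownames(m), n = as.integer(n),
             hd = n * (1 - x2) / (n - 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' PCA of haplogroup frequency vectors
#'
#' Rows are converted to frequencies, column-mean-centred (no variance
#' scaling — frequencies share a scale) and decomposed by SVD.  Component
#' signs are fixed by making the largest-magnitude loading of each axis
#' positive, so coordinates are deterministic.
#'
#' @param table a `haplogroup_table` with at least 3 populations and 2
#'   haplogroups.
#' @param n_components number of axes requested (default 2); reduced with a
#'   warning when the centred matrix has lower rank.
#' @param scale. centre-and-scale columns instead (default FALSE).
#' @return list with `coordinates` (populations x components), `loadings`,
#'   `explained_variance` (fractions, non-increasing).
#' @export
haplogroup_frequency_pca <- function(table, n_components = 2L, scale. = FALSE) {
  m <- unclass(table)
  if (nrow(m) < 3 || ncol(m) < 2) {
    stop_config("haplogroup_frequency_pca: need >= 3 populations and >= 2 haplogroups")
  }
  freqs <- m / rowSums(m)
  pc <- stats::prcomp(freqs, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k <- min(n_components, rank)
  if (k < n_components) {
    warning(sprintf("haplogroup_frequency_pca: rank %d < %d components requested",
                    rank, n_components))
  }
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(coordinates = scores, loadings = rot,
       explained_variance = ev[seq_len(k)])
}

#' Classify and summarise runs of homozygosity
#'
#' Segments are classed by length as short (<= 0.5 Mb), medium (0.5-1 Mb,
#' left-open right-closed) or long (> 1 Mb), then counted and totalled per
#' population and per individual.  Samples absent from the population map
#' are dropped with a warning.
#'
#' @param segments a `roh_segments` data.frame.
#' @param popmap named vector sample -> population (from [read_popmap()]);
#'   omit to summarise by individual only.
#' @param bounds class boundaries in bp, default `c(0.5e6, 1e6)`.
#' @return object of class `roh_summary`: list with `by_population` and
#'   `by_individual` data.frames (`class`, `n_segments`, `total_bp`,
#'   `mean_bp`).
#' @export
roh_classify_summarize <- function(segments, popmap = NULL,
                                   bounds = c(0.5e6, 1e6)) {
  seg <- as.data.frame(segments)
  if (any(seg$length <= 0)) {
    stop_config("roh_classify_summarize: non-positive segment length")
  }
  seg$class <- cut(seg$length, breaks = c(0, bounds, Inf),
                   labels = c("short", "medium", "long"), right = TRUE)
  if (!is.null(popmap)) {
    known <- seg$sample %in% names(popmap)
    if (any(!known)) {
      warning(sprintf("roh_classify_summarize: dropping %d segment(s) of sample(s) absent from popmap",
                      sum(!known)))
      seg <- seg[known, , drop = FALSE]
    }
    seg$population <- as.character(popmap[seg$sample])
  } else {
    seg$population <- "all"
  }
  summarise_by <- function(key) {
    agg <- stats::aggregate(seg$length,
                            by = list(group = seg[[key]], class = seg$class),
                            FUN = function(v) c(n = length(v), total = sum(v)),
                            drop = TRUE)
    out <- data.frame(group = agg$group, class = as.character(agg$class),
                      n_segments = as.integer(agg$x[, "n"]),
                      total_bp = agg$x[, "total"],
                      stringsAsFactors = FALSE)
    out$mean_bp <- out$total_bp / out$n_segments
    names(out)[1] <- key
    out[order(out[[key]], match(out$class, c("short", "medium", "long"))), ,
        drop = FALSE]
  }
  by_pop <- if (nrow(seg)) summarise_by("population") else
    data.frame(population = character(0), class = character(0),
               n_segments = integer(0), total_bp = numeric(0),
               mean_bp = numeric(0))
  by_ind <- if (nrow(seg)) summarise_by("sample") else
    data.frame(sample = character(0), class = character(0),
               n_segments = integer(0), total_bp = numeric(0),
               mean_bp = numeric(0))
  rownames(by_pop) <- rownames(by_ind) <- NULL
  structure(list(by_population = by_pop, by_individual = by_ind,
                 bounds = bounds),
            class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat(sprintf("ROH summary (class bounds %.1f / %.1f Mb)\n",
              x$bounds[1] / 1e6, x$bounds[2] / 1e6))
  print.data.frame(x$by_population, digits = 4)
  invisible(x)
}
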