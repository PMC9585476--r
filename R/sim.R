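# Synthetic trio + outgroup data with the statistical structure the scan
# assumes: Balding-Nichols drift around a shared ancestral frequency,
# branch-specific sweep overrides, Hardy-Weinberg genotypes with missingness
# and a site-level depth model, gene/gene-set structure with one enriched
# pathway, haplogroup count tables and per-individual ROH segments.

#' Sweep locus specification
#'
#' Overrides the drift draw for one population at one site, pinning its
#' derived-allele frequency to `target_derived_freq` — the frequency a
#' completed or ongoing selective sweep would leave on the target branch.
#'
#' @param site_index 1-based index into the simulated site table.
#' @param target_population population label whose frequency is overridden.
#' @param target_derived_freq value in `[0, 1]`.
#' @return A list of class `sweep_locus`.
#' @export
sweep_locus <- function(site_index, target_population, target_derived_freq) {
  if (!is_count(site_index) || site_index < 1) {
    stop_config("sweep_locus: site_index must be a positive integer")
  }
  if (target_derived_freq < 0 || target_derived_freq > 1) {
    stop_config("sweep_locus: target_derived_freq must lie in [0, 1]")
  }
  structure(
    list(site_index = as.integer(site_index),
         target_population = as.character(target_population),
         target_derived_freq = as.numeric(target_derived_freq)),
    class = "sweep_locus"
  )
}

#' Simulation recipe for a synthetic trio panel
#'
#' Bundles every knob of the generator so that one object (including its
#' seed) reproduces a panel exactly.  Drift parameters are the
#' Balding-Nichols `c` per population: the expected F_ST-scale divergence of
#' that population from the shared ancestral pool.
#'
#' Defaults mirror a small high-coverage resequencing panel of a target
#' population with two reference populations: 48 diploids per population
#' (the study-design size for an isolated-population NGS panel), 30x mean
#' depth, 2% missingness.
#'
#' @param n_sites number of bi-allelic sites.
#' @param chrom_plan named integer vector: chromosome lengths in bp.
#' @param drift named numeric vector: per-population drift parameter `c`,
#'   strictly in (0, 1).
#' @param sample_sizes named integer vector of diploid counts per population
#'   (same names as `drift`), each >= 2.
#' @param sweep_spec list of [sweep_locus()] objects.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param depth_mean,depth_overdispersion site-level mean read depth model:
#'   depth ~ NegBin with mean `depth_mean` and variance
#'   `mu + mu^2 * depth_overdispersion` (0 = Poisson).
#' @param ancestral_freq_bounds length-2 vector in (0, 1): the ancestral
#'   derived-allele frequency is drawn uniformly within these bounds.
#' @param seed integer master seed; component sub-streams are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 10000L,
                       chrom_plan = c(chr1 = 50e6, chr2 = 50e6),
                       drift = c(TGT = 0.02, ING = 0.02, OUT = 0.05),
                       sample_sizes = c(TGT = 48L, ING = 48L, OUT = 48L),
                       sweep_spec = list(),
                       missing_rate = 0.02,
                       depth_mean = 30,
                       depth_overdispersion = 0.05,
                       ancestral_freq_bounds = c(0.05, 0.95),
                       seed = 1L) {
  if (!is_count(n_sites) || n_sites < 1) {
    stop_config("sim_config: n_sites must be a positive integer")
  }
  if (is.null(names(chrom_plan)) || any(chrom_plan < 1)) {
    stop_config("sim_config: chrom_plan must be a named vector of positive lengths")
  }
  if (is.null(names(drift)) || any(drift <= 0) || any(drift >= 1)) {
    stop_config("sim_config: every drift parameter must lie strictly in (0, 1)")
  }
  if (!identical(sort(names(drift)), sort(names(sample_sizes)))) {
    stop_config("sim_config: drift and sample_sizes must name the same populations")
  }
  if (any(sample_sizes < 2)) {
    stop_config("sim_config: sample sizes must be >= 2 diploids")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_config("sim_config: missing_rate must lie in [0, 1)")
  }
  if (depth_mean <= 0 || depth_overdispersion < 0) {
    stop_config("sim_config: depth model parameters must be positive")
  }
  if (length(ancestral_freq_bounds) != 2L ||
      ancestral_freq_bounds[1] <= 0 || ancestral_freq_bounds[2] >= 1 ||
      ancestral_freq_bounds[1] > ancestral_freq_bounds[2]) {
    stop_config("sim_config: ancestral_freq_bounds must be (low, high) within (0, 1)")
  }
  for (sw in sweep_spec) {
    if (!inherits(sw, "sweep_locus")) {
      stop_config("sim_config: sweep_spec entries must be sweep_locus objects")
    }
    if (sw$site_index > n_sites) {
      stop_config("sim_config: sweep site_index %d exceeds n_sites", sw$site_index)
    }
    if (!sw$target_population %in% names(drift)) {
      stop_config("sim_config: sweep population '%s' not in drift map",
                  sw$target_population)
    }
  }
  structure(
    list(n_sites = as.integer(n_sites),
         chrom_plan = chrom_plan,
         drift = drift,
         sample_sizes = sample_sizes,
         sweep_spec = sweep_spec,
         missing_rate = missing_rate,
         depth_mean = depth_mean,
         depth_overdispersion = depth_overdispersion,
         ancestral_freq_bounds = ancestral_freq_bounds,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic site coordinates: sites spread over the chromosome plan in
# proportion to length, at sorted uniform positions.
sim_site_coords <- function(config) {
  plan <- config$chrom_plan
  n <- config$n_sites
  alloc <- floor(n * plan / sum(plan))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  with_seed(substream_seed(config$seed, "polarity") + 1L, {
    chrom <- rep(names(plan), alloc)
    pos <- unlist(lapply(seq_along(plan), function(i) {
      sort(sample.int(plan[i], alloc[i]))
    }), use.names = FALSE)
    data.frame(chrom = chrom, pos = as.integer(pos),
               stringsAsFactors = FALSE)
  })
}

#' Draw per-site, per-population derived-allele frequencies
#'
#' Balding-Nichols model: the ancestral pooled frequency `p` of each site is
#' uniform within `ancestral_freq_bounds`; each population's frequency is an
#' independent Beta draw with mean `p` and variance `p (1 - p) c`, i.e.
#' `Beta(p (1 - c)/c, (1 - p)(1 - c)/c)`, so `c` is the expected F_ST of
#' that population against the ancestral pool.  Sweep loci are then
#' overwritten exactly per their [sweep_locus()] entries.
#'
#' @param config a [sim_config()].
#' @return A data.frame of class `trio_freqs`: `chrom`, `pos`,
#'   `ancestral_freq`, then one derived-frequency column per population.
#' @export
simulate_trio_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pops <- names(config$drift)
  coords <- sim_site_coords(config)
  out <- with_seed(substream_seed(config$seed, "frequencies"), {
    p <- stats::runif(config$n_sites,
                      config$ancestral_freq_bounds[1],
                      config$ancestral_freq_bounds[2])
    freqs <- sapply(pops, function(pop) {
      c_drift <- config$drift[[pop]]
      shape_scale <- (1 - c_drift) / c_drift
      stats::rbeta(config$n_sites, p * shape_scale, (1 - p) * shape_scale)
    })
    cbind(data.frame(ancestral_freq = p), as.data.frame(freqs))
  })
  for (sw in config$sweep_spec) {
    out[sw$site_index, sw$target_population] <- sw$target_derived_freq
  }
  res <- cbind(coords, out)
  attr(res, "populations") <- pops
  class(res) <- c("trio_freqs", "data.frame")
  res
}

#' Sample diploid genotypes from a frequency table
#'
#' Genotypes are Hardy-Weinberg binomial draws of derived-allele dosage per
#' population; calls are masked missing independently at `missing_rate`; a
#' site-level mean depth is drawn from the negative-binomial depth model; and
#' each site's ancestral allele is assigned to REF or ALT by a fair coin so
#' downstream polarization code is exercised in both directions.
#'
#' @param freq_table output of [simulate_trio_frequencies()].
#' @param config the same [sim_config()].
#' @return A list of class `sim_panel` with elements
#'   \describe{
#'     \item{dosage}{integer matrix sites x samples of derived-allele dosage
#'       (0/1/2, NA = missing call)}
#'     \item{sites}{data.frame of site metadata: `chrom`, `pos`, `site_id`,
#'       `ref`, `alt`, `ancestral`, `aa_is_ref`, `site_mean_depth`}
#'     \item{samples}{data.frame `sample`, `population`}
#'   }
#' @export
sample_genotypes <- function(freq_table, config) {
  stopifnot(inherits(config, "sim_config"))
  pops <- attr(freq_table, "populations") %||% names(config$drift)
  if (!all(pops %in% names(config$sample_sizes))) {
    stop_config("sample_genotypes: frequency table populations do not match config sample_sizes")
  }
  n_sites <- nrow(freq_table)
  fmat <- as.matrix(freq_table[, pops, drop = FALSE])
  if (any(fmat < 0 | fmat > 1)) {
    stop_config("sample_genotypes: frequencies must lie in [0, 1]")
  }

  samples <- data.frame(
    sample = unlist(lapply(pops, function(p) {
      sprintf("%s_%03d", p, seq_len(config$sample_sizes[[p]]))
    }), use.names = FALSE),
    population = rep(pops, config$sample_sizes[pops]),
    stringsAsFactors = FALSE
  )
  n_samples <- nrow(samples)

  dosage <- with_seed(substream_seed(config$seed, "genotypes"), {
    m <- matrix(0L, nrow = n_sites, ncol = n_samples)
    col0 <- 0L
    for (p in pops) {
      k <- config$sample_sizes[[p]]
      m[, col0 + seq_len(k)] <-
        stats::rbinom(n_sites * k, 2L, rep(fmat[, p], times = k))
      col0 <- col0 + k
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(n_sites * n_samples) < config$missing_rate
      m[miss] <- NA_integer_
    }
    m
  })

  depth <- with_seed(substream_seed(config$seed, "depth"), {
    if (config$depth_overdispersion == 0) {
      stats::rpois(n_sites, config$depth_mean)
    } else {
      stats::rnbinom(n_sites, mu = config$depth_mean,
                     size = 1 / config$depth_overdispersion)
    }
  })

  site_meta <- with_seed(substream_seed(config$seed, "polarity"), {
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, n_sites, replace = TRUE)
    der <- vapply(anc, function(b) sample(setdiff(bases, b), 1L), character(1))
    aa_is_ref <- stats::runif(n_sites) < 0.5
    data.frame(
      chrom = freq_table$chrom,
      pos = freq_table$pos,
      site_id = paste0(freq_table$chrom, ":", freq_table$pos),
      ref = ifelse(aa_is_ref, anc, der),
      alt = ifelse(aa_is_ref, der, anc),
      ancestral = anc,
      aa_is_ref = aa_is_ref,
      site_mean_depth = as.numeric(depth),
      stringsAsFactors = FALSE
    )
  })
  colnames(dosage) <- samples$sample
  rownames(dosage) <- site_meta$site_id
  structure(list(dosage = dosage, sites = site_meta, samples = samples,
                 populations = pops),
            class = "sim_panel")
}

#' Summarise a simulated panel into per-population allele counts
#'
#' Convenience bridge from a [sample_genotypes()] panel straight to the
#' `site_counts` table the scan consumes, without a VCF round trip.
#'
#' @param panel a `sim_panel`.
#' @return A `site_counts` data.frame (see [read_vcf_counts()]).
#' @export
counts_from_panel <- function(panel) {
  stopifnot(inherits(panel, "sim_panel"))
  pops <- panel$populations
  n_sites <- nrow(panel$sites)
  out <- panel$sites[, c("chrom", "pos", "site_id", "ref", "alt", "ancestral")]
  out$polarizable <- TRUE
  out$site_mean_depth <- panel$sites$site_mean_depth
  out$missing_fraction <- rowMeans(is.na(panel$dosage))
  for (p in pops) {
    cols <- panel$samples$population == p
    sub <- panel$dosage[, cols, drop = FALSE]
    out[[paste0("derived_", p)]] <- as.integer(rowSums(sub, na.rm = TRUE))
    out[[paste0("called_", p)]] <- as.integer(2L * rowSums(!is.na(sub)))
  }
  attr(out, "populations") <- pops
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Simulate gene intervals and gene sets, with one sweep-enriched set
#'
#' Places non-overlapping gene intervals on the chromosome plan and samples
#' gene sets without replacement.  When sweep positions are supplied, the
#' first ("selected") set is engineered so that its gene bodies cover at
#' least `enriched_set_fraction` of the sweep loci, emulating a pathway under
#' polygenic selection.
#'
#' @param n_genes total genes to place (must be >= `genes_per_set`).
#' @param chrom_plan named vector of chromosome lengths (bp).
#' @param n_sets number of gene sets.
#' @param genes_per_set genes sampled per set.
#' @param enriched_set_fraction fraction of sweep loci the designated set
#'   must cover with its gene bodies.
#' @param sweep_positions optional data.frame `chrom`, `pos` of sweep loci.
#' @param gene_length gene body length in bp (default 10 kb).
#' @param seed integer seed.
#' @return list with `genes` (a `gene_intervals` data.frame: `gene_id`,
#'   `chrom`, `start`, `end`, 0-based half-open), `sets` (list of
#'   `gene_set`s, the first named `SELECTED_SET` when sweeps are given).
#' @export
simulate_gene_model <- function(n_genes, chrom_plan, n_sets, genes_per_set,
                                enriched_set_fraction = 1.0,
                                sweep_positions = NULL,
                                gene_length = 10000L, seed = 1L) {
  if (n_genes < genes_per_set) {
    stop_config("simulate_gene_model: n_genes must be >= genes_per_set")
  }
  slots_per_chrom <- floor(chrom_plan / (2 * gene_length))
  if (sum(slots_per_chrom) < n_genes) {
    stop_config("simulate_gene_model: chromosome plan too short for %d genes of %d bp",
                n_genes, gene_length)
  }
  with_seed(substream_seed(seed, "genes"), {
    gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
    set_ids <- sprintf("SET%03d", seq_len(n_sets))
    sets <- lapply(set_ids, function(id) {
      list(set_id = id, description = "simulated pathway",
           genes = sample(gene_ids, genes_per_set))
    })

    # Host genes of the designated "selected" set are placed first, centred
    # on sweep loci, so the set's gene bodies cover the required fraction.
    # The remaining sets are then redrawn from the non-host genes, so they
    # are genuinely null rather than enriched by shared host membership.
    host <- data.frame(gene_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       stringsAsFactors = FALSE)
    if (!is.null(sweep_positions) && nrow(sweep_positions) > 0 && n_sets >= 1) {
      need <- ceiling(enriched_set_fraction * nrow(sweep_positions))
      ord <- order(sweep_positions$chrom, sweep_positions$pos)
      sw <- sweep_positions[ord, , drop = FALSE]
      covered <- rep(FALSE, nrow(sw))
      gi <- 1L
      for (i in seq_len(nrow(sw))) {
        if (covered[i] || sum(covered) >= need) next
        if (gi > length(sets[[1]]$genes)) break
        g_start <- max(0L, sw$pos[i] - as.integer(gene_length / 2))
        same <- host$chrom == sw$chrom[i]
        if (any(same) && max(host$end[same]) > g_start) {
          g_start <- max(host$end[same])    # butt against the previous host
          if (g_start >= sw$pos[i]) next    # cannot host this locus; move on
        }
        in_body <- sw$chrom == sw$chrom[i] &
          sw$pos > g_start & sw$pos <= g_start + gene_length
        host <- rbind(host, data.frame(
          gene_id = sets[[1]]$genes[gi], chrom = sw$chrom[i],
          start = as.integer(g_start),
          end = as.integer(g_start + gene_length),
          stringsAsFactors = FALSE
        ))
        covered <- covered | in_body
        gi <- gi + 1L
      }
      if (sum(covered) < need) {
        stop_config("simulate_gene_model: could not cover %d sweep loci with %d set genes",
                    need, length(sets[[1]]$genes))
      }
      sets[[1]]$set_id <- "SELECTED_SET"
      sets[[1]]$description <- "sweep-enriched pathway"
      if (n_sets > 1) {
        null_pool <- setdiff(gene_ids, host$gene_id)
        if (length(null_pool) < genes_per_set) {
          stop_config("simulate_gene_model: too few non-host genes for null sets")
        }
        for (j in 2:n_sets) {
          sets[[j]]$genes <- sample(null_pool, genes_per_set)
        }
      }
    }

    # Remaining genes go on a grid of non-overlapping slots (slot = 2x gene
    # length, gene jittered within the first half), skipping any slot that
    # intersects a host gene; non-overlap holds by construction.
    rest_ids <- setdiff(gene_ids, host$gene_id)
    slot_chrom <- rep(names(chrom_plan), slots_per_chrom)
    slot_idx <- unlist(lapply(slots_per_chrom, seq_len), use.names = FALSE)
    slot_start <- (slot_idx - 1L) * 2L * gene_length
    free <- rep(TRUE, length(slot_chrom))
    if (nrow(host)) {
      for (j in seq_len(nrow(host))) {
        free <- free & !(slot_chrom == host$chrom[j] &
                           slot_start < host$end[j] &
                           slot_start + 2L * gene_length > host$start[j])
      }
    }
    if (sum(free) < length(rest_ids)) {
      stop_config("simulate_gene_model: chromosome plan too short for %d genes of %d bp",
                  n_genes, gene_length)
    }
    keep <- sort(sample(which(free), length(rest_ids)))
    jitter <- sample.int(gene_length, length(rest_ids), replace = TRUE) - 1L
    start <- slot_start[keep] + jitter                   # 0-based
    genes <- rbind(host, data.frame(
      gene_id = rest_ids,
      chrom = slot_chrom[keep],
      start = as.integer(start),
      end = as.integer(start + gene_length),
      stringsAsFactors = FALSE
    ))
    sets <- lapply(sets, function(s) { class(s) <- "gene_set"; s })

    genes <- genes[order(genes$chrom, genes$start), ]
    rownames(genes) <- NULL
    class(genes) <- c("gene_intervals", "data.frame")
    list(genes = genes, sets = sets)
  })
}

#' Simulate a population-by-haplogroup count table
#'
#' Per population, a haplogroup frequency vector is drawn from a Dirichlet
#' distribution with the given concentration vector, then `n_per_pop`
#' individuals are assigned multinomially.
#'
#' @param pop_profiles named list: population label -> positive concentration
#'   vector (one entry per haplogroup, shared names or shared length).
#' @param n_per_pop individuals sampled per population.
#' @param seed integer seed.
#' @return A `haplogroup_table`: integer matrix populations x haplogroups
#'   with row sums `n_per_pop`.
#' @export
simulate_haplogroup_counts <- function(pop_profiles, n_per_pop, seed = 1L) {
  if (!length(pop_profiles) || is.null(names(pop_profiles))) {
    stop_config("simulate_haplogroup_counts: pop_profiles must be a named list")
  }
  k <- unique(vapply(pop_profiles, length, integer(1)))
  if (length(k) != 1L) {
    stop_config("simulate_haplogroup_counts: all concentration vectors must share length")
  }
  if (any(unlist(pop_profiles) <= 0)) {
    stop_config("simulate_haplogroup_counts: concentrations must be positive")
  }
  hap_names <- names(pop_profiles[[1]]) %||% sprintf("H%02d", seq_len(k))
  with_seed(substream_seed(seed, "haplogroups"), {
    counts <- do.call(rbind, lapply(pop_profiles, function(alpha) {
      g <- stats::rgamma(k, shape = alpha, rate = 1)   # Dirichlet via gamma
      freqs <- g / sum(g)
      as.integer(stats::rmultinom(1, n_per_pop, freqs))
    }))
    dimnames(counts) <- list(names(pop_profiles), hap_names)
    structure(counts, class = c("haplogroup_table", class(counts)))
  })
}

#' Simulate per-individual runs of homozygosity
#'
#' Segment lengths are drawn from a mixture of exponentials (component
#' weights and mean lengths in bp); each individual's segments are placed
#' uniformly on the chromosome plan and re-drawn on collision, so no two
#' segments of one individual overlap.
#'
#' @param n_individuals number of samples (`IND001`, ...).
#' @param length_mixture data.frame or list with `weight` and `mean_bp`
#'   columns; weights must sum to 1.
#' @param segs_per_individual segments per individual.
#' @param chrom_plan named vector of chromosome lengths.
#' @param seed integer seed.
#' @param max_tries placement retries per segment before giving up.
#' @return A `roh_segments` data.frame: `sample`, `chrom`, `start`, `end`
#'   (1-based inclusive), `length`.
#' @export
simulate_roh_segments <- function(n_individuals, length_mixture,
                                  segs_per_individual, chrom_plan,
                                  seed = 1L, max_tries = 100L) {
  lm <- as.data.frame(length_mixture)
  if (abs(sum(lm$weight) - 1) > 1e-9) {
    stop_config("simulate_roh_segments: mixture weights must sum to 1")
  }
  if (segs_per_individual == 0 || n_individuals == 0) {
    out <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("roh_segments", "data.frame")
    return(out)
  }
  with_seed(substream_seed(seed, "roh"), {
    rows <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      placed <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0))
      for (s in seq_len(segs_per_individual)) {
        comp <- sample.int(nrow(lm), 1L, prob = lm$weight)
        len <- max(1L, as.integer(round(stats::rexp(1, 1 / lm$mean_bp[comp]))))
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          chrom <- sample(names(chrom_plan), 1L,
                          prob = chrom_plan / sum(chrom_plan))
          if (chrom_plan[[chrom]] <= len) next
          start <- sample.int(chrom_plan[[chrom]] - len, 1L)
          end <- start + len - 1L
          clash <- placed$chrom == chrom &
            placed$start <= end & placed$end >= start
          if (!any(clash)) {
            placed <- rbind(placed,
                            data.frame(chrom = chrom, start = start, end = end))
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop_config("simulate_roh_segments: could not place segment of %d bp after %d tries",
                      len, max_tries)
        }
      }
      placed$sample <- sprintf("IND%03d", i)
      rows[[i]] <- placed
    }
    out <- do.call(rbind, rows)
    out <- out[, c("sample", "chrom", "start", "end")]
    out$length <- out$end - out$start + 1L
    rownames(out) <- NULL
    class(out) <- c("roh_segments", "data.frame")
    out
  })
}
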