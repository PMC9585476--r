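# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seeds: each pipeline component draws from its own
# seed derived from the master seed, so enlarging one component (e.g. adding
# sites) never perturbs another component's draws.
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    frequencies = 11L, genotypes = 23L, polarity = 37L, depth = 41L,
    genes = 53L, sets = 59L, haplogroups = 67L, roh = 71L, generic = 97L
  )
  off <- offsets[[component]]
  if (is.null(off)) off <- offsets[["generic"]]
  as.integer((abs(seed) * 1009L + off * 9176L) %% .Machine$integer.max)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

pbscan_log <- function(fmt, ...) {
  message(sprintf(paste0("[pbscan] ", fmt), ...))
}

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
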