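# Internal helpers shared across modules.

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "grp", "chrom", "start", "end", "barcode", "support", "region_id",
  "amplicon", "N", "n_present", "sum_n", "sumsq_n", "r_ge", "obs_count"
))

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All deterministic sampling in the package funnels through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, staying within the
# 32-bit integer range R requires of set.seed().
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483647L)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_format <- function(path, line, msg) {
  abort(sprintf("%s: line %d: %s", path, line, msg), class = "ecdnatools_format_error")
}
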