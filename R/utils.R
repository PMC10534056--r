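# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means: use (and advance) the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("coalgrowth_data_error", "error")))
}

is_phylo <- function(x) inherits(x, "phylo")

# number-of-tips helper that also validates a phylo minimally
n_tips <- function(tree) {
  stopifnot(is_phylo(tree))
  length(tree$tip.label)
}
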