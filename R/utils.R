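# Internal helpers shared across modules.

# Deterministic per-stage seed fan-out from the single top-level seed.
# Stages get fixed offsets so adding a stage never reshuffles the others.
stage_seed <- function(seed, stage) {
  offsets <- c(
    culture = 11L, network = 23L, dye = 37L, drug = 53L,
    render = 71L, noise = 89L, cohort = 107L
  )
  off <- offsets[[stage]]
  if (is.null(off)) abort(paste0("unknown stage '", stage, "'"))
  as.integer((as.numeric(seed) %% 99991) * 7919 + off)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  expr
}

assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
  bad <- if (strict) x <= lower else x < lower
  if (bad) {
    abort(paste0("`", name, "` must be ", if (strict) "> " else ">= ", lower))
  }
  invisible(x)
}

assert_cols <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("`", name, "` is missing columns: ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Wrap periodic XY coordinates into [0, L).
wrap_periodic <- function(x, L) {
  x - L * floor(x / L)
}

# Reflect depth coordinates into [0, L] (handles multiple bounces).
reflect_depth <- function(z, L) {
  period <- 2 * L
  z <- z %% period
  ifelse(z > L, period - z, z)
}
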