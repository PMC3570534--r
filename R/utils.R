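# internal helpers shared across modules

band_edges_khz <- 0:8

# canonical column names for the eight 1-kHz bands
band_cols <- function(prefix = "db") {
  paste0(prefix, "_", band_edges_khz[-9], "_", band_edges_khz[-1])
}

high_band_cols <- function(prefix = "rel") {
  paste0(prefix, "_", 3:7, "_", 4:8)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_hour <- function(hour) {
  if (!is.numeric(hour) || any(!is.finite(hour)) ||
      any(hour != floor(hour)) || any(hour < 0) || any(hour > 23)) {
    abort("`hour` must be an integer (vector) in 0..23.")
  }
  as.integer(hour)
}

# run `expr` under a local RNG state seeded with `seed` (NULL = use current)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
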