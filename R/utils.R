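#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers never observe a side effect on the stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a finite numeric scalar", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid(sprintf("'%s' = %g is outside its valid range", name, x))
  invisible(x)
}

#' Map sample indices from one clock to another by nearest sample
#' @keywords internal
map_index_to_clock <- function(idx, fs_from, fs_to) {
  as.integer(round((idx - 1) * fs_to / fs_from)) + 1L
}

# run-length encoded local extrema with plateau handling.  Returns a list of
# maxima / minima, each a data.frame(start, end, centre, value) over interior
# runs of the vector (endpoints never qualify).
local_extrema_runs <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- logical(k)
  is_min <- logical(k)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
        is_max[j] <- TRUE
      if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L])
        is_min[j] <- TRUE
    }
  }
  centre <- starts + (r$lengths - 1L) %/% 2L
  list(
    maxima = data.frame(start = starts[is_max], end = ends[is_max],
                        centre = centre[is_max], value = r$values[is_max]),
    minima = data.frame(start = starts[is_min], end = ends[is_min],
                        centre = centre[is_min], value = r$values[is_min])
  )
}
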