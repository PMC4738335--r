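#' @keywords internal
"_PACKAGE"

## Condition helpers -------------------------------------------------------

## Three error classes are used throughout:
##   mukcoloc_config_error -- an invalid spec/parameter value
##   mukcoloc_input_error  -- structurally valid call on unusable data
##   mukcoloc_parse_error  -- a file that does not conform to its format
stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mukcoloc_config_error", "mukcoloc_error")))
}

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mukcoloc_input_error", "mukcoloc_error")))
}

stop_parse <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mukcoloc_parse_error", "mukcoloc_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_config("'%s' must be > %g (got %g)", name, lower, x)
  if (x < lower || x > upper)
    stop_config("'%s' must be in [%g, %g] (got %g)", name, lower, upper, x)
  invisible(x)
}

## Median across the columns of a bin x replicate matrix. Replicate counts
## are small (typically 3), so the 2- and 3-column cases are vectorized.
row_medians <- function(m) {
  if (is.null(dim(m))) return(m)
  k <- ncol(m)
  if (k == 1L) return(m[, 1L])
  if (k == 2L) return((m[, 1L] + m[, 2L]) / 2)
  if (k == 3L) {
    a <- m[, 1L]; b <- m[, 2L]; c <- m[, 3L]
    return(pmax(pmin(a, b), pmin(pmax(a, b), c)))
  }
  apply(m, 1L, stats::median)
}

## Distribution arguments in simulator specs: either a single number
## (degenerate distribution) or a function(n) returning n draws.
draw_from <- function(dist, n, name) {
  if (is.function(dist)) {
    out <- dist(n)
    if (!is.numeric(out) || length(out) != n)
      stop_config("'%s' function must return %d numeric values", name, n)
    return(out)
  }
  if (is.numeric(dist) && length(dist) == 1L) return(rep(dist, n))
  stop_config("'%s' must be a single number or a function(n)", name)
}
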