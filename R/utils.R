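#' Round half away from zero
#'
#' Decimal rounding where exact halves round up (away from zero), the
#' convention used for all printed percentages in the package's tables.
#' Base [round()] uses round-half-to-even, which disagrees on exact halves
#' (e.g. 4.85 at one decimal).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(c(31.05, 31.04, -0.25), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# percent of a count over a total, printed-table convention (1 decimal)
percent_of <- function(n, total, digits = 1) {
  round_half_up(100 * n / total, digits)
}

#' Normalize free-text labels
#'
#' Trims surrounding whitespace, collapses internal runs of whitespace and
#' upper-cases, so that drug names and preferred terms compare reliably
#' across sloppy extracts. No synonym or ingredient expansion is attempted.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  toupper(x)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so the generator has no global side effect.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
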