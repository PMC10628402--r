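#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimal places, as
#' used for all displayed quantities in HIA reports. Unlike [base::round()],
#' which rounds half to even, `round_half_up(0.5)` is `1` and
#' `round_half_up(2.345, 2)` is `2.35`. Internal propagation always uses
#' unrounded values; this function exists for reporting only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(57.17 * 0.62, 2) # 35.45
#' round_half_up(278.97)          # 279
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small absolute guard against binary representation of exact halves
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# fixed-decimal formatting of a half-up-rounded value ("35.45", "2.86")
fmt_hu <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' Construct a central/low/high triple
#'
#' Uncertainty in this package is carried as a triple of central estimate and
#' 95% confidence bounds, propagated by evaluating every downstream formula
#' at the bounds (not by the delta method).
#'
#' @param central,low,high numeric scalars with `low <= central <= high`.
#' @return a named numeric vector `c(central, low, high)` of class
#'   `"hia_triple"`.
#' @export
triple <- function(central, low = central, high = central) {
  stopifnot(is.numeric(central), is.numeric(low), is.numeric(high),
            length(central) == 1, length(low) == 1, length(high) == 1)
  tol <- 1e-12 * max(1, abs(central))
  if (!anyNA(c(central, low, high)) &&
      (low > central + tol || central > high + tol))
    stop("triple ordering violated: need low <= central <= high, got (",
         central, ", ", low, ", ", high, ")")
  structure(c(central = central, low = low, high = high),
            class = "hia_triple")
}

is_triple <- function(x) inherits(x, "hia_triple") ||
  (is.numeric(x) && length(x) == 3)

as_triple <- function(x) {
  if (inherits(x, "hia_triple")) return(x)
  if (is.numeric(x) && length(x) == 3) {
    names(x) <- c("central", "low", "high")
    return(triple(x[[1]], x[[2]], x[[3]]))
  }
  if (is.numeric(x) && length(x) == 1) return(triple(x))
  stop("cannot interpret object as a central/low/high triple")
}

#' @export
print.hia_triple <- function(x, digits = 4, ...) {
  cat(fmt_hu(x[["central"]], digits), " (",
      fmt_hu(x[["low"]], digits), "-", fmt_hu(x[["high"]], digits), ")\n",
      sep = "")
  invisible(x)
}

# Run `expr` under a locally seeded Mersenne-Twister stream, restoring any
# pre-existing global RNG state afterwards. All stochastic generators in the
# package route through this, so seeds are mandatory and no global state
# leaks (the documented algorithm is Mersenne-Twister with inversion
# sampling for normal deviates, R's defaults, identical across platforms).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}
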