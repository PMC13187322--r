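#' Value with standard-error uncertainty
#'
#' A minimal container for a scalar measurement and its standard error,
#' used throughout the enrichment metrics so that derived quantities
#' (differences and ratios of region means) carry propagated uncertainties.
#'
#' @param value numeric scalar.
#' @param sem non-negative standard error of `value`.
#' @return An object of class `"uval"`.
#' @examples
#' uval(1.8, 0.3)
#' @export
uval <- function(value, sem = 0) {
  stopifnot(is.numeric(value), length(value) == 1L,
            is.numeric(sem), length(sem) == 1L)
  if (!is.na(sem) && sem < 0) stop("sem must be >= 0")
  structure(list(value = as.numeric(value), sem = as.numeric(sem)),
            class = "uval")
}

#' @export
print.uval <- function(x, ...) {
  cat(sprintf("%.6g +/- %.6g\n", x$value, x$sem))
  invisible(x)
}

#' @export
is_uval <- function(x) inherits(x, "uval")

as_uval <- function(x) {
  if (is_uval(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(uval(x, 0))
  if (is.list(x) && all(c("value", "sem") %in% names(x)))
    return(uval(x$value, x$sem))
  stop("cannot interpret object as uval")
}

#' Propagate uncertainty through a difference
#'
#' For independent measurements `a - b`, the variances add:
#' `sem = sqrt(sem_a^2 + sem_b^2)`.
#'
#' @param a,b [uval] objects (plain numbers are promoted with `sem = 0`).
#' @return A [uval].
#' @examples
#' propagate_difference(uval(1.8, 0.3), uval(1.2, 0.4))  # 0.6 +/- 0.5
#' @export
propagate_difference <- function(a, b) {
  a <- as_uval(a); b <- as_uval(b)
  uval(a$value - b$value, sqrt(a$sem^2 + b$sem^2))
}

#' Propagate uncertainty through a ratio
#'
#' For independent measurements `a / b` the relative variances add:
#' `sem = |a/b| * sqrt((sem_a/a)^2 + (sem_b/b)^2)`. A zero-valued numerator
#' uses the convention `sem = sem_a / |b|` (the first-order term that
#' survives when `a = 0`).
#'
#' @param a,b [uval] objects; `b$value` must be non-zero.
#' @return A [uval].
#' @examples
#' propagate_ratio(uval(0.6, 0.5), uval(1.2, 0.1))
#' @export
propagate_ratio <- function(a, b) {
  a <- as_uval(a); b <- as_uval(b)
  if (b$value == 0) stop("ratio by zero-valued denominator")
  v <- a$value / b$value
  if (a$value == 0) return(uval(0, a$sem / abs(b$value)))
  uval(v, abs(v) * sqrt((a$sem / a$value)^2 + (b$sem / b$value)^2))
}
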