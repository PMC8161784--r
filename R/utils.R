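#' Round to the nearest unit, halves away from zero
#'
#' Commercial rounding used for all displayed dollar amounts: 0.5 CAD rounds
#' up in magnitude (256.5 -> 257), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal digits to keep (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # tiny nudge guards against values like 0.49999999998 from float arithmetic
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

## internal shorthand: round a CAD amount to whole dollars
round_cad <- function(x) round_half_away(x, 0)

#' Largest-remainder integer allocation
#'
#' Distributes an integer `total` across categories proportionally to
#' `weights`, assigning floors first and then one extra unit to the largest
#' fractional remainders. Ties broken by category order. Used wherever the
#' calibrated cohort generator must turn target proportions into exact counts.
#'
#' @param total non-negative integer to distribute.
#' @param weights non-negative numeric weights (need not sum to 1).
#' @return integer vector of counts summing to `total`.
#' @export
largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- round(total - sum(base))
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## allocate an integer sum S over n units as evenly as possible (values q, q+1);
## the first r units carry the extra visit
allocate_even <- function(total, n) {
  if (n == 0L) return(integer(0))
  q <- total %/% n
  r <- total %% n
  as.integer(c(rep(q + 1, r), rep(q, n - r)))
}

## stop() with a field name so validation errors are actionable
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    fail_field(field, "must be a single number in [0, 1]")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    fail_field(field, "must be a single non-negative number")
  invisible(x)
}

check_count <- function(x, field, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x %% 1 != 0 ||
      x < if (positive) 1 else 0)
    fail_field(field, if (positive) "must be a positive integer"
               else "must be a non-negative integer")
  invisible(as.integer(x))
}

check_simplex <- function(p, field, tol = 1e-6) {
  if (any(!is.finite(p)) || any(p < 0))
    fail_field(field, "proportions must be finite and non-negative")
  if (abs(sum(p) - 1) > tol)
    fail_field(field, sprintf("proportions must sum to 1 (got %.6f)", sum(p)))
  invisible(p)
}
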