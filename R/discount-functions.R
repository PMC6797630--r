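#' Discount function families
#'
#' Constructs a discount function specification. The workhorse family is the
#' one-parameter hyperbolic, `V = R / (1 + k * D)`, with `k` in units of
#' days^-1. Three further families are supported for robustness analyses:
#' exponential `V = R * exp(-k * D)`, the two-parameter hyperboloid of
#' Myerson and Green `V = R / (1 + k * D)^s`, and the modified-Rachlin
#' hyperboloid `V = R / (1 + (k * D)^s)`.
#'
#' @param family One of `"hyperbolic"`, `"exponential"`, `"myerson_green"`,
#'   `"modified_rachlin"`.
#' @param k Discount rate (days^-1). Must be non-negative; `k = 0` is the
#'   degenerate no-discounting limit, allowed for reference curves.
#' @param s Curvature exponent, required (and `> 0`) for the two hyperboloid
#'   families, ignored otherwise.
#' @return An object of class `dd_discount_function`.
#' @examples
#' f <- discount_function("hyperbolic", k = 1 / 50)
#' present_value(f, reward = 20, delay = 50)  # half the reward at 50 days
#' @export
discount_function <- function(family = c("hyperbolic", "exponential",
                                         "myerson_green", "modified_rachlin"),
                              k, s = NULL) {
  family <- match.arg(family)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("`k` must be a single finite non-negative number (days^-1)")
  }
  needs_s <- family %in% c("myerson_green", "modified_rachlin")
  if (needs_s) {
    if (is.null(s) || !is.numeric(s) || length(s) != 1L || !is.finite(s) ||
        s <= 0) {
      stop(sprintf("family '%s' requires a curvature parameter s > 0", family))
    }
  } else {
    s <- NULL
  }
  structure(list(family = family, k = k, s = s),
            class = "dd_discount_function")
}

#' @export
print.dd_discount_function <- function(x, ...) {
  cat("Discount function:", x$family, "\n")
  cat("  k =", format(x$k), "days^-1")
  if (x$k > 0) cat("  (hyperbolic half-life", format(1 / x$k), "days)")
  cat("\n")
  if (!is.null(x$s)) cat("  s =", format(x$s), "\n")
  invisible(x)
}

#' Present subjective value of a delayed reward
#'
#' Evaluates the discounted value `V` of a reward of magnitude `reward`
#' available after `delay` days, under a discount function specification.
#' At `delay = 0` the value equals the reward for every family.
#'
#' @param fun A [discount_function()].
#' @param reward Reward magnitude (commodity units); finite.
#' @param delay Delay in days; non-negative, vectorised.
#' @return Numeric vector of present values, same length as `delay`.
#' @export
present_value <- function(fun, reward, delay) {
  stopifnot(inherits(fun, "dd_discount_function"))
  if (!is.numeric(reward) || any(!is.finite(reward))) {
    stop("`reward` must be finite numeric")
  }
  if (!is.numeric(delay) || any(!is.finite(delay)) || any(delay < 0)) {
    stop("`delay` must be non-negative and finite (days)")
  }
  k <- fun$k
  s <- fun$s
  frac <- switch(fun$family,
    hyperbolic       = 1 / (1 + k * delay),
    exponential      = exp(-k * delay),
    myerson_green    = 1 / (1 + k * delay)^s,
    modified_rachlin = 1 / (1 + (k * delay)^s)
  )
  reward * frac
}

#' Hyperbolic half-life of a discount rate
#'
#' The delay at which a hyperbolically discounted reward is worth half its
#' undelayed magnitude: `1 / k` days. A convenient, unit-interpretable
#' summary of a discount rate (e.g. `k = 1/50` means a 50-day half-life).
#'
#' @param k Discount rate in days^-1; strictly positive. Vectorised.
#' @return Half-life in days.
#' @examples
#' half_life(1 / 50)  # 50 days
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be strictly positive (days^-1)")
  }
  1 / k
}

#' Normalised area under the discounting curve
#'
#' A discount-function-agnostic index of discounting: the trapezoidal area
#' under the curve of normalised value (`V / R`) against normalised delay
#' (`delay / max_delay`), with an implicit anchor point at `(0, 1)`. Values
#' lie in `[0, 1]`; 1 means no discounting, smaller values mean steeper
#' discounting.
#'
#' @param fun A [discount_function()].
#' @param delays Strictly increasing positive delays (days), all
#'   `<= max_delay`.
#' @param max_delay Normalising maximum delay (days), positive.
#' @return A single number in `[0, 1]`.
#' @export
normalized_discount_auc <- function(fun, delays, max_delay) {
  stopifnot(inherits(fun, "dd_discount_function"))
  if (length(delays) == 0L || any(!is.finite(delays)) || any(delays <= 0)) {
    stop("`delays` must be a nonempty vector of positive finite days")
  }
  if (is.unsorted(delays, strictly = TRUE)) {
    stop("`delays` must be strictly increasing (no duplicates)")
  }
  if (!is.numeric(max_delay) || length(max_delay) != 1L || max_delay <= 0 ||
      any(delays > max_delay)) {
    stop("`max_delay` must be positive and >= max(delays)")
  }
  x <- c(0, delays / max_delay)
  y <- c(1, present_value(fun, reward = 1, delay = delays))
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
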