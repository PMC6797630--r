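# commodity and condition levels, in canonical order (food is in-domain)
COMMODITIES <- c("food", "money", "music")
CONDITIONS <- c("control", "fasted")

TRIAL_COLUMNS <- c("participant", "condition", "commodity", "trial_index",
                   "A", "DA", "B", "DB", "R")

#' Session parameters of the choice model
#'
#' Bundles the three per-session parameters of the lapse-contaminated probit
#' choice rule: the log discount rate `log_k` (natural log of a days^-1
#' rate), the comparison acuity `alpha` (the scale, in commodity units, of
#' the probit on the value difference; larger means noisier choices), and
#' the lapse rate `epsilon` (probability mass of value-independent
#' responding, split across both responses).
#'
#' Note on symbols: `alpha` and `epsilon` here belong to the *choice model*
#' and are unrelated to the free parameters of the hypothesis-comparison
#' models (see [hypothesis_model()]), which reuse the same Greek letters in
#' the source literature.
#'
#' @param log_k Real log discount rate.
#' @param alpha Positive acuity (commodity units).
#' @param epsilon Lapse rate in `[0, 0.5)`.
#' @return An object of class `dd_choice_params`.
#' @export
choice_params <- function(log_k, alpha, epsilon = 0) {
  if (!is.numeric(log_k) || length(log_k) != 1L || !is.finite(log_k)) {
    stop("`log_k` must be a single finite number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be strictly positive (degenerate acuity rejected)")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 ||
      epsilon >= 0.5) {
    stop("`epsilon` must lie in [0, 0.5)")
  }
  structure(list(log_k = log_k, alpha = alpha, epsilon = epsilon),
            class = "dd_choice_params")
}

#' @export
print.dd_choice_params <- function(x, ...) {
  cat(sprintf("Choice parameters: log_k = %.3f (half-life %.2f days), ",
              x$log_k, 1 / exp(x$log_k)))
  cat(sprintf("alpha = %.3f, epsilon = %.4f\n", x$alpha, x$epsilon))
  invisible(x)
}

#' Validate a trial table
#'
#' Checks the invariants of a table of binary inter-temporal choice trials:
#' immediate option delivered now (`DA = 0`), delayed option strictly later
#' (`DB > 0`), positive magnitudes with the immediate amount no larger than
#' the delayed one (`0 < A <= B`), and binary responses (1 = chose delayed).
#'
#' @param trials Data frame with at least columns `A`, `DA`, `B`, `DB`
#'   (and `R` unless `require_response = FALSE`).
#' @param require_response Whether the `R` column must be present.
#' @return The validated data frame, invisibly.
#' @export
validate_trials <- function(trials, require_response = TRUE) {
  need <- c("A", "DA", "B", "DB", if (require_response) "R")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0L) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(trials) == 0L) stop("trial table is empty")
  with(trials, {
    if (any(DA != 0)) stop("immediate delay DA must be 0 for every trial")
    if (any(DB <= 0)) stop("delayed delay DB must be > 0 (days)")
    if (any(A <= 0) || any(B <= 0)) stop("amounts A, B must be positive")
    if (any(A > B)) stop("immediate amount A must not exceed delayed amount B")
  })
  if (require_response && !all(trials$R %in% c(0, 1))) {
    stop("responses R must be 0 (chose immediate) or 1 (chose delayed)")
  }
  invisible(trials)
}

#' Probability of choosing the delayed reward
#'
#' The lapse-contaminated probit choice rule: with subjective values
#' `VA = A` (immediate, delay 0) and `VB` the discounted value of the
#' delayed reward,
#' `P = epsilon + (1 - 2 * epsilon) * pnorm((VB - VA) / alpha)`.
#' The probability equals 0.5 exactly at value indifference and is bounded
#' in `[epsilon, 1 - epsilon]`.
#'
#' @param trials Trial table (responses not required).
#' @param params A [choice_params()].
#' @param fun A [discount_function()]; defaults to hyperbolic with
#'   `k = exp(log_k)`.
#' @return Vector of probabilities, one per trial.
#' @export
choice_probability <- function(trials, params, fun = NULL) {
  stopifnot(inherits(params, "dd_choice_params"))
  validate_trials(trials, require_response = FALSE)
  if (is.null(fun)) fun <- discount_function("hyperbolic", k = exp(params$log_k))
  va <- present_value(fun, trials$A, trials$DA)
  vb <- present_value(fun, trials$B, trials$DB)
  eps <- params$epsilon
  eps + (1 - 2 * eps) * stats::pnorm((vb - va) / params$alpha)
}

#' Simulate binary responses to inter-temporal choice trials
#'
#' Draws `R ~ Bernoulli(P)` with `P` from [choice_probability()].
#' Reproducible for a fixed seed.
#'
#' @inheritParams choice_probability
#' @param rng_seed Integer seed.
#' @return Integer vector of 0/1 responses, one per trial.
#' @export
simulate_response <- function(trials, params, fun = NULL, rng_seed = 1L) {
  p <- choice_probability(trials, params, fun)
  withr_seed(rng_seed, as.integer(stats::rbinom(length(p), 1L, p)))
}

#' Bernoulli log-likelihood of a session
#'
#' @inheritParams choice_probability
#' @return The summed log-likelihood of the observed responses.
#' @export
choice_loglik <- function(trials, params, fun = NULL) {
  validate_trials(trials, require_response = TRUE)
  p <- choice_probability(trials, params, fun)
  sum(stats::dbinom(trials$R, 1L, p, log = TRUE))
}

# Evaluate an expression under a local RNG seed, restoring global RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Read / write trial tables
#'
#' Trial tables are exchanged as UTF-8 comma-separated files with the exact
#' header `participant, condition, commodity, trial_index, A, DA, B, DB, R`.
#' Comment lines starting `#` carry run metadata and are ignored on read.
#'
#' @param path File path.
#' @param trials Trial table to write.
#' @param meta Optional named character vector written as `# key: value`
#'   header lines.
#' @return `read_trials` returns the trial data frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("trial CSV schema error; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_trials(df)
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path, meta = NULL) {
  validate_trials(trials)
  write_csv_with_meta(trials[TRIAL_COLUMNS], path, meta)
  invisible(path)
}

write_csv_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}
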