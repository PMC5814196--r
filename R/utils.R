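#' Round half away from zero
#'
#' Rounding convention used for all rendered report values: ties go away
#' from zero (2.025 -> 2.03), unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(2.025, -2.025, 0.275), 2)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Fold change from group means, as rendered in reports
#'
#' Ratio of tumor to normal mean expression, rounded half-away-from-zero to
#' the requested number of decimals. This is the single code path used for
#' every fold-change cell in generated report tables, so printed values can
#' be reproduced from printed means.
#'
#' @param tumor_mean,normal_mean nonnegative means on a common scale.
#' @param digits decimals to render (default 2); `NA` for no rounding.
#' @param pseudocount value added to both means before taking the ratio
#'   (default 0).
#' @return numeric fold change(s).
#' @export
#' @examples
#' fold_change_from_means(46.72, 23.14)  # 2.02
fold_change_from_means <- function(tumor_mean, normal_mean, digits = 2,
                                   pseudocount = 0) {
  fc <- (tumor_mean + pseudocount) / (normal_mean + pseudocount)
  if (is.na(digits)) fc else round_half_up(fc, digits)
}

#' Percentage of a total, rendered to one decimal
#'
#' @param n count in the category.
#' @param total total count.
#' @param digits decimals (default 1, the convention of cohort summaries).
#' @return numeric percentage.
#' @export
#' @examples
#' percent_of(169, 217)  # 77.9
percent_of <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, digits)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls stay side-effect free.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent condition class so callers can distinguish
# configuration/structural errors from R-level failures.
pm_stop <- function(msg, class = "pairmir_error", call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
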