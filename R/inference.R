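#' Plug-in t-test for a correlation-scale value
#'
#' Converts a dependence measure's value m at sample size T into a p-value
#' through the Pearson-style statistic \eqn{t = m\sqrt{T-2}/\sqrt{1-m^2}}
#' with T - 2 degrees of freedom. Every measure in the simulation tables
#' (including Kendall's tau and dCor) is plugged into this same rule: it is
#' the unique rule that reproduces all of the independently printed table
#' p-values (0.61 at T = 18 gives 0.004; 0.43 gives 0.04; 0.65 gives
#' 0.002), whereas, e.g., the normal approximation for tau does not.
#'
#' @param m Measure value, \eqn{|m| \le 1}.
#' @param n Sample size T (number of time points), \eqn{\ge 3}.
#' @param alternative `"greater"` (one-sided upper, the default used for
#'   the per-replicate significance calls), `"two.sided"`, or `"less"`.
#' @return A p-value in \eqn{[0, 1]}. `m = 1` gives 0 under `"greater"`;
#'   `m = 0` gives 0.5 one-sided.
#' @examples
#' plugin_cor_test(0.61, 18) # ~0.004
#' @export
plugin_cor_test <- function(m, n,
                            alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || abs(m) > 1) {
    stop("'m' must be a single number with |m| <= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 3L) stop("'n' must be >= 3 (the test needs df = n - 2 >= 1)",
                   call. = FALSE)
  df <- n - 2L
  tstat <- if (abs(m) == 1) sign(m) * Inf else m * sqrt(df) / sqrt(1 - m^2)
  switch(alternative,
         greater   = stats::pt(tstat, df, lower.tail = FALSE),
         less      = stats::pt(tstat, df),
         two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

#' Per-replicate significance call
#'
#' TRUE when the one-sided plug-in p-value falls below the
#' Bonferroni-corrected threshold. The default threshold 5e-4 is
#' alpha = 0.05 divided by the 100 simulation replicates.
#'
#' @inheritParams plugin_cor_test
#' @param threshold Significance threshold in (0, 1); default `5e-4`.
#' @return Logical.
#' @export
plugin_significant <- function(m, n, threshold = 5e-4) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  plugin_cor_test(m, n, "greater") < threshold
}

#' One-sample t-test over per-replicate measure values
#'
#' Summarizes R replicate values of a correlation measure by their mean,
#' standard error, and the two-sided one-sample t-test against zero with
#' R - 1 degrees of freedom. Identical replicate values give a zero
#' standard error; the p-value is then reported as 0 with a degeneracy
#' warning.
#'
#' @param values Numeric vector of per-replicate measure values, length
#'   \eqn{R \ge 2}.
#' @return An object of class `"replicate_summary"`: list with `values`,
#'   `mean`, `se`, `df`, `statistic`, `p_value`.
#' @examples
#' replicate_ttest(c(0.8, 0.9)) # mean 0.85, se 0.05, p ~ 0.037
#' @export
replicate_ttest <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    stop("'values' must be a numeric vector of length >= 2 without NA",
         call. = FALSE)
  }
  R <- length(values)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(R)
  if (se == 0) {
    warning("identical replicate values: zero standard error, p reported as 0")
    tstat <- if (m == 0) NaN else sign(m) * Inf
    p <- 0
  } else {
    tstat <- m / se
    p <- 2 * stats::pt(abs(tstat), df = R - 1, lower.tail = FALSE)
  }
  structure(list(values = values, mean = m, se = se, df = R - 1L,
                 statistic = tstat, p_value = p),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("mean %.3f (se %.3f), t = %.2f on %d df, p = %.3g  [R = %d]\n",
              x$mean, x$se, x$statistic, x$df, x$p_value, length(x$values)))
  invisible(x)
}

#' Kernelized correlation averaged over replicates
#'
#' Computes the kernelized correlation on each replicate of a paired time
#' course and summarizes the values with [replicate_ttest()].
#'
#' @param reps List of \eqn{R \ge 2} replicates; each element is a list (or
#'   data frame) with numeric components `x` and `y` of a common length T.
#' @param spec A [kernel_spec()].
#' @return A `"replicate_summary"`.
#' @export
kc_replicates <- function(reps, spec = kernel_spec()) {
  reps <- check_replicates(reps)
  vals <- vapply(reps, function(r) kernel_cor(r$x, r$y, spec), numeric(1))
  out <- replicate_ttest(vals)
  out$gamma_used <- spec$gamma
  out
}

check_replicates <- function(reps) {
  if (!is.list(reps) || length(reps) < 2L) {
    stop("'reps' must be a list of >= 2 replicates", call. = FALSE)
  }
  reps <- lapply(reps, function(r) {
    if (is.null(r$x) || is.null(r$y)) {
      stop("each replicate needs components 'x' and 'y'", call. = FALSE)
    }
    list(x = as.numeric(r$x), y = as.numeric(r$y))
  })
  T0 <- length(reps[[1L]]$x)
  ok <- vapply(reps, function(r) length(r$x) == T0 && length(r$y) == T0,
               logical(1))
  if (!all(ok)) stop("all replicates must share the same number of time points",
                     call. = FALSE)
  reps
}

#' Condition self-correlation screen
#'
#' Flags variables whose time course is essentially identical across two
#' experimental conditions (e.g., a gene expressed the same in stimulated
#' and control cells), and which are therefore irrelevant to the contrast
#' under study. For each replicate the kernelized correlation between the
#' variable's condition-A series and its condition-B series is computed;
#' the variable is flagged when the replicate mean exceeds
#' `value_threshold` and the one-sample t-test p-value falls below
#' `p_threshold`.
#'
#' @param cond_a,cond_b Lists of \eqn{R \ge 2} numeric series (one per
#'   replicate) for the same variable in conditions A and B, matched time
#'   points.
#' @param spec A [kernel_spec()]; self-correlation is similar-patterned, so
#'   the untrained default `gamma = 0.5` is appropriate.
#' @param value_threshold Minimum mean self-correlation to flag
#'   (default 0.95).
#' @param p_threshold Maximum p-value to flag (default 0.001).
#' @return A list with `self_correlation` (the replicate mean), `se`,
#'   `p_value`, `values`, and logical `flagged`.
#' @export
self_cor_screen <- function(cond_a, cond_b, spec = kernel_spec(),
                            value_threshold = 0.95, p_threshold = 0.001) {
  if (!is.list(cond_a) || !is.list(cond_b) ||
      length(cond_a) != length(cond_b) || length(cond_a) < 2L) {
    stop("'cond_a' and 'cond_b' must be lists of >= 2 matched replicates",
         call. = FALSE)
  }
  reps <- Map(function(a, b) list(x = a, y = b), cond_a, cond_b)
  s <- kc_replicates(reps, spec)
  flagged <- (s$mean > value_threshold) && (s$p_value < p_threshold)
  list(self_correlation = s$mean, se = s$se, p_value = s$p_value,
       values = s$values, flagged = flagged)
}
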