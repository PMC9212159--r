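#' Pearson product-moment correlation
#'
#' Thin validated wrapper over [stats::cor()], the linear baseline the
#' kernelized measure is compared against.
#'
#' @param x,y Numeric series of equal length \eqn{\ge 3}.
#' @return A number in \eqn{[-1, 1]}.
#' @export
pearson_cor <- function(x, y) {
  check_pair(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant series: Pearson correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall's tau, via [stats::cor()] with
#' `method = "kendall"`. Tie correction matters here: noiseless sinusoid
#' grids contain exactly repeated values.
#'
#' @inheritParams pearson_cor
#' @return A number in \eqn{[-1, 1]}.
#' @export
kendall_cor <- function(x, y) {
  check_pair(x, y)
  v <- suppressWarnings(stats::cor(x, y, method = "kendall"))
  if (is.na(v)) stop("all-tied input: Kendall correlation undefined",
                     call. = FALSE)
  v
}

#' Sample distance correlation (biased V-statistic)
#'
#' The nonnegative dependence measure of energy statistics:
#' \eqn{dCor = dCov / \sqrt{dVar_x\, dVar_y}} built from double-centered
#' pairwise-distance matrices. Zero characterizes independence in
#' population; `dcor(x, x) = 1` for any non-constant `x`. Unlike the
#' kernelized correlation it carries no sign.
#'
#' @inheritParams pearson_cor
#' @return A number in \eqn{[0, 1]}.
#' @export
dcor <- function(x, y) {
  check_pair(x, y)
  A <- double_center(as.matrix(stats::dist(x)))
  B <- double_center(as.matrix(stats::dist(y)))
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) {
    stop("constant series: zero distance variance", call. = FALSE)
  }
  v <- sqrt(max(mean(A * B), 0)) / (dvx * dvy)^(1 / 4)
  min(v, 1)
}
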