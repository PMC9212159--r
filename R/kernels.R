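#' Kernel specification
#'
#' Describes the kernel used to lift paired observations \eqn{u_i = (x_i,
#' y_i)} from the plane into a high-dimensional feature space: either a
#' polynomial kernel \eqn{k(u, v) = (1 + \langle u, v\rangle)^d} or a
#' Gaussian (radial basis function) kernel \eqn{k(u, v) = \exp(-\gamma\,
#' \lVert u - v\rVert^2)}, where \eqn{\gamma > 0} is the inverse kernel
#' width.
#'
#' @param family Kernel family, `"rbf"` or `"polynomial"`.
#' @param gamma Inverse kernel width (RBF only), a single positive number.
#'   The default 0.5 is the recommended setting for similar-patterned
#'   (positively correlated) pairs; for complementary-patterned pairs train
#'   it with [train_gamma()].
#' @param degree Polynomial degree (polynomial only), an integer \eqn{\ge 2}.
#' @param standardize Logical; z-score each series across time points before
#'   building the Gram matrix. Standardization is part of the canonical
#'   algorithm and the default; the simulation runner exposes the raw-scale
#'   alternative (see [run_scenario()]).
#'
#' @return An object of class `"kernel_spec"`.
#' @examples
#' kernel_spec("rbf", gamma = 0.5)
#' kernel_spec("polynomial", degree = 2)
#' @export
kernel_spec <- function(family = c("rbf", "polynomial"), gamma = 0.5,
                        degree = 2L, standardize = TRUE) {
  family <- match.arg(family)
  if (family == "rbf") {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
        gamma <= 0) {
      stop("'gamma' must be a single positive number", call. = FALSE)
    }
    spec <- list(family = "rbf", gamma = gamma, degree = NULL,
                 standardize = isTRUE(standardize))
  } else {
    degree <- as.integer(degree)
    if (length(degree) != 1L || is.na(degree) || degree < 2L) {
      stop("'degree' must be a single integer >= 2", call. = FALSE)
    }
    spec <- list(family = "polynomial", gamma = NULL, degree = degree,
                 standardize = isTRUE(standardize))
  }
  class(spec) <- "kernel_spec"
  spec
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$family == "rbf") {
    cat(sprintf("RBF kernel (gamma = %g), standardize = %s\n",
                x$gamma, x$standardize))
  } else {
    cat(sprintf("Polynomial kernel (degree = %d), standardize = %s\n",
                x$degree, x$standardize))
  }
  invisible(x)
}

#' Short label for a kernel spec, used in result tables
#' @noRd
kernel_label <- function(spec) {
  if (spec$family == "rbf") sprintf("kc_rbf(gamma=%g)", spec$gamma)
  else sprintf("kc_poly%d", spec$degree)
}

#' Z-score a series across time points
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (divisor
#' T - 1). A constant series has no scale and is rejected.
#'
#' @param x Numeric vector, length \eqn{\ge 3}, all values finite.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @examples
#' standardize_series(c(1, 2, 3))
#' @export
standardize_series <- function(x) {
  check_series(x)
  s <- stats::sd(x)
  if (s == 0) stop("constant series: zero variance, cannot standardize",
                   call. = FALSE)
  (x - mean(x)) / s
}

check_series <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  if (length(x) < 3L) {
    stop(sprintf("'%s' must have length >= 3", name), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

check_pair <- function(x, y) {
  check_series(x, "x")
  check_series(y, "y")
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  invisible(NULL)
}

#' Polynomial kernel between two points
#'
#' \eqn{k(u, v) = (1 + \langle u, v\rangle)^d}.
#'
#' @param u,v Numeric vectors of equal length (typically 2-D plane points).
#' @param degree Integer degree \eqn{\ge 2}.
#' @return A single number.
#' @examples
#' polynomial_kernel(c(1, 1), c(1, 1), 2) # (1 + 2)^2 = 9
#' @export
polynomial_kernel <- function(u, v, degree) {
  stopifnot(length(u) == length(v), all(is.finite(u)), all(is.finite(v)))
  degree <- as.integer(degree)
  if (degree < 2L) stop("'degree' must be >= 2", call. = FALSE)
  (1 + sum(u * v))^degree
}

#' Gaussian (RBF) kernel between two points
#'
#' \eqn{k(u, v) = \exp(-\gamma \lVert u - v\rVert^2)}, in \eqn{(0, 1]};
#' equals 1 iff \eqn{u = v}. Far-apart points underflow safely to 0.
#'
#' @param u,v Numeric vectors of equal length.
#' @param gamma Inverse kernel width, \eqn{> 0}.
#' @return A single number in \eqn{[0, 1]}.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), gamma = 0.5) # exp(-1)
#' @export
rbf_kernel <- function(u, v, gamma) {
  stopifnot(length(u) == length(v), all(is.finite(u)), all(is.finite(v)))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("'gamma' must be a single positive number", call. = FALSE)
  }
  exp(-gamma * sum((u - v)^2))
}

#' Gram matrix of a paired series under a kernel
#'
#' Forms the T plane points \eqn{u_i = (\tilde x_i, \tilde y_i)} (tilde
#' denotes the optional z-scoring controlled by `spec$standardize`) and the
#' T-by-T symmetric Gram matrix \eqn{K_{ij} = k(u_i, u_j)}.
#'
#' @param x,y Numeric series of equal length T \eqn{\ge 3}.
#' @param spec A [kernel_spec()].
#' @return A list with components `u` (T-by-2 matrix of plane points) and
#'   `K` (T-by-T Gram matrix; unit diagonal for RBF).
#' @export
gram_matrix <- function(x, y, spec = kernel_spec()) {
  check_pair(x, y)
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$standardize) {
    x <- standardize_series(x)
    y <- standardize_series(y)
  }
  u <- cbind(x = x, y = y)
  if (spec$family == "rbf") {
    d2 <- as.matrix(stats::dist(u))^2
    K <- exp(-spec$gamma * d2)
  } else {
    K <- (1 + tcrossprod(u))^spec$degree
  }
  # dist() guarantees an exact-zero diagonal; symmetrize against rounding
  K <- (K + t(K)) / 2
  list(u = u, K = K)
}

#' Double-center a square matrix
#'
#' Applies the centering projection \eqn{K_c = H K H} with
#' \eqn{H = I - \frac{1}{T}\mathbf{1}\mathbf{1}'}, computed entrywise as
#' \eqn{K_{ij} - \bar K_{i\cdot} - \bar K_{\cdot j} + \bar K_{\cdot\cdot}}.
#' Every row and column of the result sums to zero.
#'
#' @param K A square numeric matrix.
#' @return The double-centered matrix, same dimensions as `K`.
#' @examples
#' K <- matrix(c(1, 0, 0, 0, 1, 0.988, 0, 0.988, 1), 3, 3)
#' round(double_center(K), 3)
#' @export
double_center <- function(K) {
  if (!is.matrix(K) || !is.numeric(K) || nrow(K) != ncol(K)) {
    stop("'K' must be a square numeric matrix", call. = FALSE)
  }
  rm <- rowMeans(K)
  cm <- colMeans(K)
  K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm) + mean(K)
}

#' Kernelize a paired series
#'
#' Runs the full transformation: optional z-scoring, Gram matrix
#' \eqn{K}, double-centering to \eqn{K_c}, then the kernelized vectors
#' \eqn{K_c\tilde x} and \eqn{K_c\tilde y}. Both kernelized vectors sum to
#' zero because \eqn{\mathbf{1}'K_c = 0}.
#'
#' @inheritParams gram_matrix
#' @return An object of class `"kernelized_pair"`: a list with `u`, `K`,
#'   `Kc`, `xk`, `yk` and the `spec` used.
#' @export
kernelize_pair <- function(x, y, spec = kernel_spec()) {
  g <- gram_matrix(x, y, spec)
  Kc <- double_center(g$K)
  out <- list(u = g$u, K = g$K, Kc = Kc,
              xk = drop(Kc %*% g$u[, "x"]),
              yk = drop(Kc %*% g$u[, "y"]),
              spec = spec)
  class(out) <- "kernelized_pair"
  out
}

#' Kernelized correlation coefficient
#'
#' The nonlinear, sign-preserving dependence measure: Pearson's r of the
#' kernelized vectors \eqn{K_c\tilde x} and \eqn{K_c\tilde y}. Bounded in
#' \eqn{[-1, 1]}, symmetric in its arguments, invariant to adding a
#' constant to either series, and (for the RBF kernel) antisymmetric under
#' a sign flip of one series. As \eqn{\gamma \to \infty} the RBF version
#' converges to the plain Pearson correlation of `x` and `y`.
#'
#' @inheritParams gram_matrix
#' @param base Base correlation plugged into the kernelized vectors. Only
#'   `"pearson"` is implemented; the argument exists for extension.
#' @return A single number in \eqn{[-1, 1]}.
#' @examples
#' t_i <- seq(0, 119, by = 7)
#' x <- 2 * sin(t_i * pi / 42) - 0.5
#' y <- 2 * sin((t_i - 7) * pi / 42) - 0.5
#' kernel_cor(x, y, kernel_spec("rbf", gamma = 0.5, standardize = FALSE))
#' @export
kernel_cor <- function(x, y, spec = kernel_spec(), base = "pearson") {
  base <- match.arg(base, "pearson")
  kp <- kernelize_pair(x, y, spec)
  if (stats::var(kp$xk) < 1e-14 || stats::var(kp$yk) < 1e-14) {
    stop("degenerate kernelization: a kernelized vector has (near-)zero ",
         "variance; try a different kernel parameter", call. = FALSE)
  }
  v <- stats::cor(kp$xk, kp$yk)
  # clamp rounding spill just outside [-1, 1]
  max(-1, min(1, v))
}
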