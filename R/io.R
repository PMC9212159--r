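#' Construct an expression dataset
#'
#' Container for a replicated expression time course: an n-variable by
#' T-time-point by R-replicate numeric array plus identifiers, time labels
#' and an optional per-replicate condition tag.
#'
#' @param values Numeric array `n x T x R` (a matrix is accepted for
#'   `R = 1`), no missing values.
#' @param variables Character vector of n unique identifiers.
#' @param times Vector of T ordered time labels (metadata only; the
#'   measures use order, not spacing).
#' @param condition Optional character vector of length R tagging each
#'   replicate with an experimental condition.
#' @return An object of class `"expression_dataset"`.
#' @export
expression_dataset <- function(values, variables, times, condition = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  n <- dim(values)[1L]; T0 <- dim(values)[2L]; R <- dim(values)[3L]
  if (T0 < 3L) stop("need at least 3 time points", call. = FALSE)
  if (!is.numeric(values) || anyNA(values) || !all(is.finite(values))) {
    stop("'values' must be finite numeric with no missing entries",
         call. = FALSE)
  }
  variables <- as.character(variables)
  if (length(variables) != n) stop("length(variables) must match dim 1",
                                   call. = FALSE)
  if (anyDuplicated(variables)) {
    stop("duplicate variable identifier: ",
         variables[duplicated(variables)][1L], call. = FALSE)
  }
  if (length(times) != T0) stop("length(times) must match dim 2",
                                call. = FALSE)
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (length(condition) != R) stop("length(condition) must match dim 3",
                                     call. = FALSE)
  }
  dimnames(values) <- list(variables, NULL, NULL)
  structure(list(values = values, variables = variables, times = times,
                 n_replicates = R, condition = condition),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d variables x %d time points x %d replicate(s)\n",
              length(x$variables), length(x$times), x$n_replicates))
  if (!is.null(x$condition)) {
    cat("conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a delimited expression table
#'
#' Reads a TSV/CSV matrix with variable identifiers in the first column and
#' time points in the remaining columns. Replicates are either stacked as
#' wide column blocks in one file (time within replicate: columns
#' `T*R` wide, declared via `n_replicates`) or supplied as one file per
#' replicate (pass a vector of paths). Duplicate identifiers, non-numeric
#' cells and missing values are hard errors naming the offending cell; no
#' imputation is attempted.
#'
#' @param path One path, or a vector of per-replicate paths.
#' @param sep Field separator; defaults to `","` for `.csv`, tab otherwise.
#' @param n_replicates Number of wide replicate blocks in a single file.
#' @param times Optional time labels (length T); defaults to the column
#'   names of the first block.
#' @param condition Optional per-replicate condition tags.
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, sep = NULL, n_replicates = 1L,
                                  times = NULL, condition = NULL) {
  if (length(path) > 1L) {
    mats <- lapply(path, read_expr_matrix, sep = sep)
    ids <- rownames(mats[[1L]])
    for (m in mats[-1L]) {
      if (!identical(rownames(m), ids) || ncol(m) != ncol(mats[[1L]])) {
        stop("replicate files must share identifiers and time points",
             call. = FALSE)
      }
    }
    values <- array(unlist(mats), dim = c(nrow(mats[[1L]]), ncol(mats[[1L]]),
                                          length(mats)))
    if (is.null(times)) times <- colnames(mats[[1L]])
    return(expression_dataset(values, ids, times, condition))
  }
  m <- read_expr_matrix(path, sep = sep)
  R <- as.integer(n_replicates)
  if (ncol(m) %% R != 0L) {
    stop(sprintf("column count %d is not divisible by n_replicates = %d",
                 ncol(m), R), call. = FALSE)
  }
  T0 <- ncol(m) %/% R
  values <- array(NA_real_, dim = c(nrow(m), T0, R))
  for (r in seq_len(R)) {
    values[, , r] <- m[, ((r - 1L) * T0 + 1L):(r * T0)]
  }
  if (is.null(times)) times <- colnames(m)[seq_len(T0)]
  expression_dataset(values, rownames(m), times, condition)
}

read_expr_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate variable identifier '", ids[duplicated(ids)][1L],
         "' in ", path, call. = FALSE)
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(raw, 2, as.numeric))
  num <- matrix(num, nrow = nrow(raw), dimnames = dimnames(raw))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric or missing value at row '%s', column '%s' in %s",
      ids[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]], path), call. = FALSE)
  }
  rownames(num) <- ids
  num
}

#' Write an expression dataset as a delimited table
#'
#' Inverse of [read_expression_table()] for the single-file wide layout:
#' replicate blocks side by side, time within replicate, identifiers in the
#' first column.
#'
#' @param ds An [expression_dataset()].
#' @param path Output path; `.csv` extension selects comma separation.
#' @param sep Optional explicit separator.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path, sep = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  T0 <- length(ds$times); R <- ds$n_replicates
  wide <- matrix(NA_real_, nrow = length(ds$variables), ncol = T0 * R)
  cn <- character(T0 * R)
  for (r in seq_len(R)) {
    idx <- ((r - 1L) * T0 + 1L):(r * T0)
    wide[, idx] <- ds$values[, , r]
    cn[idx] <- if (R == 1L) as.character(ds$times)
               else paste0(ds$times, "_rep", r)
  }
  df <- data.frame(id = ds$variables, wide, check.names = FALSE)
  colnames(df) <- c("id", cn)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a variable pair as a list of replicates
#'
#' @param ds An [expression_dataset()].
#' @param var_a,var_b Variable identifiers.
#' @param replicates Indices of replicates to use (default all).
#' @return A list of `list(x=, y=)` replicates, suitable for
#'   [kc_replicates()] and [train_gamma()].
#' @export
dataset_pair_replicates <- function(ds, var_a, var_b,
                                    replicates = seq_len(ds$n_replicates)) {
  stopifnot(inherits(ds, "expression_dataset"))
  ia <- match(var_a, ds$variables); ib <- match(var_b, ds$variables)
  if (is.na(ia) || is.na(ib)) stop("unknown variable identifier",
                                   call. = FALSE)
  lapply(replicates, function(r)
    list(x = ds$values[ia, , r], y = ds$values[ib, , r]))
}

#' Split a single long series pair into cycle replicates
#'
#' Treats consecutive segments of one long periodic time course (e.g., two
#' cell cycles) as biological repeats, the device used to obtain replicates
#' from a single synchronized experiment.
#'
#' @param x,y Numeric series of equal length divisible by `n_parts`.
#' @param n_parts Number of equal segments (default 2).
#' @return A list of `n_parts` replicates, each `list(x=, y=)`.
#' @export
split_series_replicates <- function(x, y, n_parts = 2L) {
  check_pair(x, y)
  n_parts <- as.integer(n_parts)
  if (length(x) %% n_parts != 0L) {
    stop("series length must be divisible by 'n_parts'", call. = FALSE)
  }
  len <- length(x) %/% n_parts
  lapply(seq_len(n_parts), function(k) {
    idx <- ((k - 1L) * len + 1L):(k * len)
    list(x = x[idx], y = y[idx])
  })
}

#' All-pairs kernelized correlation
#'
#' Computes the kernelized correlation for every unordered pair of
#' variables in a dataset: n(n-1)/2 rows. With \eqn{R \ge 2} replicates
#' the value is the replicate mean and the p-value comes from the
#' one-sample t-test across replicates; with a single replicate the
#' plug-in t-test at sample size T is used. P-values are adjusted over the
#' whole family. A constant variable fails its pairs (NA value and
#' p-value) with a warning; the run continues.
#'
#' @param ds An [expression_dataset()].
#' @param spec A [kernel_spec()].
#' @param adjust Multiple-testing correction: `"bonferroni"` (default,
#'   matching the study's own correction style), `"BH"`, or `"none"`.
#' @return A data frame with columns `variable_a`, `variable_b`,
#'   `measure`, `value`, `p_value`, `p_adjusted`, `gamma_used`.
#' @export
all_pairs_kc <- function(ds, spec = kernel_spec(),
                         adjust = c("bonferroni", "BH", "none")) {
  stopifnot(inherits(ds, "expression_dataset"))
  adjust <- match.arg(adjust)
  vars <- ds$variables
  n <- length(vars)
  if (n < 2L) stop("need at least 2 variables", call. = FALSE)
  idx <- utils::combn(n, 2L)
  T0 <- length(ds$times)
  one_pair <- function(ia, ib) {
    reps <- dataset_pair_replicates(ds, vars[ia], vars[ib])
    tryCatch({
      if (length(reps) >= 2L) {
        s <- kc_replicates(reps, spec)
        c(value = s$mean, p = s$p_value)
      } else {
        v <- kernel_cor(reps[[1L]]$x, reps[[1L]]$y, spec)
        c(value = v, p = plugin_cor_test(v, T0, "greater"))
      }
    }, error = function(e) {
      warning(sprintf("pair %s-%s failed: %s", vars[ia], vars[ib],
                      conditionMessage(e)), call. = FALSE)
      c(value = NA_real_, p = NA_real_)
    })
  }
  res <- apply(idx, 2L, function(ij) one_pair(ij[1L], ij[2L]))
  out <- data.frame(
    variable_a = vars[idx[1L, ]],
    variable_b = vars[idx[2L, ]],
    measure = kernel_label(spec),
    value = res["value", ],
    p_value = res["p", ],
    p_adjusted = stats::p.adjust(res["p", ],
                                 method = if (adjust == "none") "none"
                                          else adjust),
    gamma_used = if (spec$family == "rbf") spec$gamma else NA_real_,
    row.names = NULL
  )
  out
}
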