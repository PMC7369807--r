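#' Pairwise-comparison (judgment) matrices
#'
#' A judgment matrix is an n-by-n positive matrix on the Saaty 1-9 scale in
#' which entry (i, j) records how much more important indicator i is than
#' indicator j. Diagonal entries must be 1 and off-diagonal pairs must be
#' (approximately) reciprocal. Published matrices are typically printed with
#' two decimals (0.33 for 1/3, 1.67 for 5/3), so reciprocity is accepted
#' within `recip_tol`: |a_ij * a_ji - 1| <= 0.05 by default. Set
#' `rationalize = TRUE` to replace each lower-triangle entry with the exact
#' reciprocal of its upper-triangle partner.
#'
#' @param x Square numeric matrix (or object coercible to one).
#' @param labels Optional indicator ids for rows/columns.
#' @param rationalize Replace lower-triangle entries by exact reciprocals of
#'   the upper triangle (default `FALSE`: the matrix is validated as given,
#'   never silently symmetrized).
#' @param recip_tol Reciprocity tolerance on |a_ij * a_ji - 1|.
#' @return A validated `judgment_matrix`.
#' @examples
#' judgment_matrix(rbind(c(1, 3), c(0.33, 1)))
#' @export
judgment_matrix <- function(x, labels = NULL, rationalize = FALSE,
                            recip_tol = 0.05) {
  m <- as.matrix(x)
  if (!is.numeric(m) || nrow(m) != ncol(m)) {
    stop_input("a judgment matrix must be a square numeric matrix")
  }
  n <- nrow(m)
  if (any(!is.finite(m))) stop_input("judgment matrix entries must be finite")
  if (any(m <= 0)) stop_input("judgment matrix entries must be positive")
  if (any(abs(diag(m) - 1) > 1e-12)) {
    stop_input("judgment matrix diagonal entries must equal 1")
  }
  if (rationalize && n > 1) {
    m[lower.tri(m)] <- t(1 / m)[lower.tri(m)]
  }
  recip <- abs(m * t(m) - 1)
  if (any(recip > recip_tol)) {
    bad <- which(recip == max(recip), arr.ind = TRUE)[1, ]
    stop_input("reciprocity violated at (", bad[1], ",", bad[2], "): ",
               "a_ij * a_ji = ", format(m[bad[1], bad[2]] * m[bad[2], bad[1]]),
               " (tolerance ", recip_tol, ")")
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    dimnames(m) <- list(labels, labels)
  }
  structure(m, class = c("judgment_matrix", "matrix", "array"))
}

#' Read a judgment matrix from delimited text
#'
#' Accepts a plain numeric CSV or one whose first column (and header row)
#' carries indicator labels.
#'
#' @param path CSV file path.
#' @inheritParams judgment_matrix
#' @return A `judgment_matrix`.
#' @export
read_judgment_matrix <- function(path, rationalize = FALSE,
                                 recip_tol = 0.05) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if (!is.numeric(df[[1]])) {
    labels <- as.character(df[[1]])
    df <- df[-1]
  }
  judgment_matrix(as.matrix(df), labels = labels,
                  rationalize = rationalize, recip_tol = recip_tol)
}

#' AHP priority weights by the row geometric-mean method
#'
#' The canonical weight rule: the unnormalized priority of indicator i is
#' the geometric mean of row i of the judgment matrix,
#' \eqn{\bar w_i = (\prod_j a_{ij})^{1/n}}, and weights are
#' \eqn{w_i = \bar w_i / \sum_k \bar w_k}. The eigenvector-scale vector
#' `n * w` is also returned: it is the "feature vector" scale conventional
#' in published AHP tables.
#'
#' @param j A `judgment_matrix`.
#' @return A tibble with columns `indicator`, `geom_mean` (the unnormalized
#'   row geometric means), `weight` (summing to 1), and `feature` (= n *
#'   weight).
#' @examples
#' geometric_mean_weights(judgment_matrix(rbind(c(1, 3), c(1 / 3, 1))))
#' @export
geometric_mean_weights <- function(j) {
  j <- as_judgment(j)
  n <- nrow(j)
  gm <- exp(rowMeans(log(unclass(j))))
  w <- gm / sum(gm)
  tibble::tibble(
    indicator = matrix_labels(j),
    geom_mean = unname(gm),
    weight = unname(w),
    feature = unname(w * n)
  )
}

#' AHP priority weights by the principal eigenvector
#'
#' Power iteration on the judgment matrix; the normalized dominant
#' eigenvector is the classical eigenvector priority rule and serves as an
#' independent cross-check of [geometric_mean_weights()] (the two agree
#' exactly on consistent matrices).
#'
#' @param j A `judgment_matrix`.
#' @param tol Convergence tolerance on the max absolute change of the
#'   normalized iterate.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A tibble with `indicator` and `weight` (summing to 1).
#' @export
principal_eigen_weights <- function(j, tol = 1e-12, max_iter = 1000L) {
  j <- as_judgment(j)
  a <- unclass(j)
  w <- rep(1 / nrow(a), nrow(a))
  for (it in seq_len(max_iter)) {
    w_new <- as.numeric(a %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) {
      return(tibble::tibble(indicator = matrix_labels(j), weight = w_new))
    }
    w <- w_new
  }
  stop("power iteration did not converge in ", max_iter, " iterations",
       call. = FALSE)
}

#' Largest-eigenvalue estimate from a weight vector
#'
#' The averaging estimator \eqn{\lambda_{max} = \sum_i (A w)_i / (n w_i)},
#' exact when `w` is the principal eigenvector. For positive reciprocal
#' matrices \eqn{\lambda_{max} \ge n}, with equality iff the matrix is
#' perfectly consistent.
#'
#' @param j A `judgment_matrix`.
#' @param w Numeric weight vector (strictly positive), or a tibble with a
#'   `weight` column as returned by the weighting functions.
#' @return The scalar eigenvalue estimate.
#' @export
lambda_max <- function(j, w) {
  j <- as_judgment(j)
  w <- weight_values(w, nrow(j))
  if (any(w <= 0)) stop_input("lambda_max needs strictly positive weights")
  aw <- as.numeric(unclass(j) %*% w)
  sum(aw / (nrow(j) * w))
}

# Random consistency index for matrix orders 1..9 (Saaty's simulated table).
RI_TABLE <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)

#' Consistency check of a judgment matrix
#'
#' Computes the consistency index CI = (lambda_max - n)/(n - 1), looks up
#' the random index RI for the matrix order (tabulated for n = 1..9), and
#' forms the consistency ratio CR = CI/RI. The matrix passes when CR < 0.1.
#' For n <= 2 a reciprocal matrix is always consistent, so CI and CR are
#' defined as 0. Orders above 9 have no tabulated RI and are an error.
#'
#' @inheritParams lambda_max
#' @return A one-row tibble: `n`, `lambda_max`, `ci`, `ri`, `cr`,
#'   `consistent`.
#' @export
consistency_check <- function(j, w) {
  j <- as_judgment(j)
  n <- nrow(j)
  if (n > length(RI_TABLE)) {
    stop_input("no random consistency index tabulated for n = ", n,
               " (supported orders: 1-", length(RI_TABLE), ")")
  }
  lm <- lambda_max(j, w)
  if (n <= 2) {
    ci <- 0
    cr <- 0
  } else {
    ci <- (lm - n) / (n - 1)
    cr <- ci / RI_TABLE[n]
  }
  tibble::tibble(n = n, lambda_max = lm, ci = ci, ri = RI_TABLE[n], cr = cr,
                 consistent = cr < 0.1)
}

#' Fit AHP weights with a consistency guarantee
#'
#' Convenience composition of the geometric-mean weight rule and the
#' consistency test. When the consistency ratio is 0.1 or more the fit
#' refuses to return weights unless `force = TRUE`, mirroring standard AHP
#' practice that an inconsistent matrix must be revised before its weights
#' are used.
#'
#' @inheritParams geometric_mean_weights
#' @param force Return weights even when the matrix fails the consistency
#'   test.
#' @return An `ahp_fit` object; use [generics::tidy()] for the per-indicator
#'   weight table and [generics::glance()] for the consistency summary.
#' @examples
#' fit <- ahp_weights(macao_judgment())
#' tidy(fit)
#' glance(fit)
#' @export
ahp_weights <- function(j, force = FALSE) {
  j <- as_judgment(j)
  tab <- geometric_mean_weights(j)
  rep <- consistency_check(j, tab$weight)
  if (!rep$consistent && !force) {
    stop(errorCondition(
      sprintf(paste0("judgment matrix fails the consistency test ",
                     "(CR = %.3f >= 0.1); revise it or pass force = TRUE"),
              rep$cr),
      class = c("healstreet_consistency_error", "error", "condition")))
  }
  structure(
    list(matrix = j, table = tab, weights = tab$weight, consistency = rep),
    class = "ahp_fit"
  )
}

#' @export
print.ahp_fit <- function(x, ...) {
  cat("<ahp_fit> n =", x$consistency$n, "\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-6s feature %.3f  weight %6.3f%%\n", tab$indicator[i],
                tab$feature[i], 100 * tab$weight[i]))
  }
  with(x$consistency, cat(sprintf(
    "  lambda_max %.3f  CI %.3f  RI %.3f  CR %.3f  %s\n",
    lambda_max, ci, ri, cr, if (consistent) "Pass" else "FAIL")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ahp_weights
#' @param x An `ahp_fit`.
#' @param ... Unused.
#' @export
tidy.ahp_fit <- function(x, ...) x$table

#' @rdname ahp_weights
#' @export
glance.ahp_fit <- function(x, ...) x$consistency

#' @rdname ahp_weights
#' @param object An `ahp_fit`.
#' @export
autoplot.ahp_fit <- function(object, ...) {
  tab <- dplyr::mutate(object$table,
                       indicator = factor(.data$indicator, .data$indicator))
  ggplot2::ggplot(tab, ggplot2::aes(.data$indicator, .data$weight)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "AHP weight",
                  title = "Priority weights (row geometric-mean method)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

as_judgment <- function(j) {
  if (inherits(j, "judgment_matrix")) j else judgment_matrix(j)
}

matrix_labels <- function(m) {
  rownames(m) %||% paste0("i", seq_len(nrow(m)))
}

weight_values <- function(w, n) {
  if (is.data.frame(w)) w <- w$weight
  w <- as.numeric(w)
  if (length(w) != n) {
    stop_input("weight vector length ", length(w),
               " does not match matrix order ", n)
  }
  w
}
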