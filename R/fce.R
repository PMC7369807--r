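#' Membership matrices over an ordinal evaluation set
#'
#' A membership matrix has one row per second-level indicator and one column
#' per evaluation level; row i is the membership distribution of indicator i
#' over the levels. Published matrices carry two-decimal entries whose rows
#' sum to 1 within about 0.01, so the default row-sum tolerance is 0.02;
#' `strict = TRUE` tightens it to 1e-9 for freshly computed rows.
#'
#' @param x Numeric matrix (rows = indicators, columns = levels) or a data
#'   frame of the same shape.
#' @param indicator_ids Optional row ids (defaults to existing rownames).
#' @param levels Evaluation set or level labels (defaults to existing
#'   colnames, else the standard five-level set).
#' @param strict Require rows to sum to 1 within 1e-9 instead of `row_tol`.
#' @param row_tol Row-sum tolerance when `strict = FALSE`.
#' @return A `membership_matrix`.
#' @examples
#' membership_matrix(rbind(c(0.5, 0.3, 0.1, 0.1, 0.0),
#'                         c(0.2, 0.2, 0.2, 0.2, 0.2)))
#' @export
membership_matrix <- function(x, indicator_ids = NULL, levels = NULL,
                              strict = FALSE, row_tol = 0.02) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    stop_input("membership degrees must lie in [0, 1]")
  }
  es <- if (is.null(levels) && !is.null(colnames(m))) {
    evaluation_set(colnames(m))
  } else {
    as_evaluation_set(levels)
  }
  if (ncol(m) != length(es)) {
    stop_input("matrix has ", ncol(m), " columns but the evaluation set has ",
               length(es), " levels")
  }
  tol <- if (strict) 1e-9 else row_tol
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    bad <- which.max(abs(rs - 1))
    stop_input("row ", bad, " sums to ", format(rs[bad]),
               ", outside 1 ± ", format(tol))
  }
  rownames(m) <- indicator_ids %||% rownames(m) %||%
    paste0("r", seq_len(nrow(m)))
  colnames(m) <- unclass(es)
  structure(m, evaluation_set = es,
            class = c("membership_matrix", "matrix", "array"))
}

#' Convert survey rating counts to a membership matrix
#'
#' Each indicator's membership distribution is the row proportion of its
#' rating counts: row i of the result is `counts[i, ] / sum(counts[i, ])`,
#' so rows sum to 1 exactly. This is the standard frequency construction of
#' single-factor evaluation vectors from questionnaire data.
#'
#' @param counts Non-negative integer matrix or data frame, rows =
#'   indicators, columns = evaluation levels in severity order (worst
#'   first).
#' @inheritParams membership_matrix
#' @return A `membership_matrix` (strict rows).
#' @examples
#' membership_from_counts(rbind(c(57, 36, 7, 0, 1)))
#' @export
membership_from_counts <- function(counts, indicator_ids = NULL,
                                   levels = NULL) {
  m <- as.matrix(counts)
  if (any(!is.finite(m)) || any(m < 0)) {
    stop_input("survey counts must be non-negative")
  }
  n <- rowSums(m)
  if (any(n == 0)) {
    stop_input("indicator ", which(n == 0)[1], " has zero respondents")
  }
  membership_matrix(m / n, indicator_ids = indicator_ids, levels = levels,
                    strict = TRUE)
}

#' Read a membership matrix from delimited text
#'
#' Expects a header row naming the evaluation levels (severity order, worst
#' first) and a first column of indicator ids.
#'
#' @param path CSV file path.
#' @inheritParams membership_matrix
#' @return A `membership_matrix`.
#' @export
read_membership_matrix <- function(path, strict = FALSE, row_tol = 0.02) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  membership_matrix(as.matrix(df[-1]), indicator_ids = ids,
                    levels = colnames(df)[-1], strict = strict,
                    row_tol = row_tol)
}

#' Fuzzy synthesis with the weighted-average operator
#'
#' Combines indicator weights with a membership matrix using the
#' weighted-average operator M(., +): component j of the result is
#' \eqn{c_j = \sum_i a_i r_{ij}}, a plain vector-matrix product with no
#' min/max clipping. The result is returned un-normalized; apply
#' [fce_normalize()] to rescale to unit sum.
#'
#' @param w Numeric weight vector (or tibble with a `weight` column), one
#'   weight per matrix row. Weights must be non-negative; they are used as
#'   given, not renormalized.
#' @param r A `membership_matrix` (or plain matrix).
#' @return A `fuzzy_vector`: numeric of length p with attributes
#'   `evaluation_set` and `normalized` (here `FALSE`).
#' @examples
#' st <- macao_study()
#' fce_synthesize(st$hierarchy$criteria[[3]]$leaves$weight,
#'                st$memberships$u3)
#' @export
fce_synthesize <- function(w, r) {
  if (is.data.frame(w)) w <- w$weight
  w <- as.numeric(w)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_input("synthesis weights must be finite and non-negative")
  }
  m <- unclass(as.matrix(r))
  if (length(w) != nrow(m)) {
    stop_input("length(w) = ", length(w), " but the membership matrix has ",
               nrow(m), " rows")
  }
  es <- attr(r, "evaluation_set") %||%
    (if (!is.null(colnames(m))) evaluation_set(colnames(m)) else
       as_evaluation_set(if (ncol(m) == 5) NULL else paste0("V", seq_len(ncol(m)))))
  fuzzy_vector(as.numeric(w %*% m), es, normalized = FALSE)
}

fuzzy_vector <- function(values, es, normalized) {
  structure(as.numeric(values), names = unclass(es),
            evaluation_set = es, normalized = normalized,
            class = "fuzzy_vector")
}

#' @export
print.fuzzy_vector <- function(x, ...) {
  cat("<fuzzy_vector>", if (attr(x, "normalized")) "(normalized)" else
    "(un-normalized)", "\n")
  print(round(stats::setNames(as.numeric(x), names(x)), 3))
  invisible(x)
}

#' Normalize a fuzzy evaluation vector to unit sum
#'
#' Rescales each component by the component sum, \eqn{c_j / \sum_i c_i}.
#' Idempotent; order-preserving.
#'
#' @param c A `fuzzy_vector` or plain non-negative numeric vector with at
#'   least one positive component.
#' @return A normalized `fuzzy_vector` summing to 1.
#' @export
fce_normalize <- function(c) {
  v <- as.numeric(c)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop_input("fuzzy vector components must be finite and non-negative")
  }
  s <- sum(v)
  if (s <= 0) stop_input("cannot normalize an all-zero fuzzy vector")
  es <- attr(c, "evaluation_set") %||%
    (if (!is.null(names(c))) evaluation_set(names(c)) else
       as_evaluation_set(if (length(v) == 5) NULL else paste0("V", seq_along(v))))
  fuzzy_vector(v / s, es, normalized = TRUE)
}

#' Maximum-membership classification
#'
#' The verdict of a fuzzy comprehensive evaluation is the evaluation level
#' with the largest membership. Ties are resolved conservatively toward the
#' more severe (lower-index) level and flagged, a deliberate choice for
#' health-related assessment where the worst plausible rating should not be
#' hidden by a tie.
#'
#' @param c A `fuzzy_vector` or numeric vector of memberships.
#' @param levels Evaluation set; defaults to the vector's own set.
#' @return A one-row tibble: `level` (label), `index` (1-based, 1 = worst),
#'   `value` (the winning membership), `tie` (logical).
#' @examples
#' max_membership(c(0.125, 0.263, 0.265, 0.210, 0.137))
#' @export
max_membership <- function(c, levels = NULL) {
  v <- as.numeric(c)
  es <- if (!is.null(levels)) as_evaluation_set(levels) else
    attr(c, "evaluation_set") %||%
      (if (!is.null(names(c))) evaluation_set(names(c)) else
         as_evaluation_set(if (length(v) == 5) NULL else paste0("V", seq_along(v))))
  if (length(v) != length(es)) {
    stop_input("vector length ", length(v), " does not match the ",
               length(es), "-level evaluation set")
  }
  idx <- which.max(v)  # which.max returns the first (most severe) maximum
  tibble::tibble(level = unclass(es)[idx], index = idx, value = v[idx],
                 tie = sum(v == v[idx]) > 1)
}

#' Two-level fuzzy comprehensive evaluation of a hierarchy
#'
#' Runs the full two-stage pipeline: for each first-level criterion the
#' leaf weights are combined with that criterion's membership matrix by the
#' weighted-average operator (first-level vectors, kept un-normalized);
#' the first-level vectors are stacked into the second-stage matrix; the
#' criterion weights are applied to that matrix; and the overall vector is
#' normalized once and classified by maximum membership. All intermediates
#' are retained for audit.
#'
#' @param h A `street_hierarchy` whose criteria and leaves carry weights.
#' @param memberships Named list of membership matrices keyed by criterion
#'   id (one per criterion, row count = leaf count).
#' @param normalize_weights Rescale each sibling weight group to unit sum
#'   before synthesis (default `TRUE`). The weighted-average operator is a
#'   convex combination only when weights sum to 1; published weight tables
#'   are printed with two decimals and sibling sums of 0.99-1.01, and
#'   recomputation of the packaged worked example shows its printed
#'   synthesis results are reproduced (within rounding) by the rescaled
#'   weights, not the raw ones. Stored hierarchy weights are never mutated.
#' @return An `fce_report`: list with `criterion_vectors` (tibble, long),
#'   `stacked` (criteria x levels matrix), `overall_raw`, `overall`
#'   (normalized `fuzzy_vector`), `verdict` (tibble from
#'   [max_membership()]), `validation`, and the input `hierarchy`.
#' @examples
#' st <- macao_study()
#' rep <- hierarchical_fce(st$hierarchy, st$memberships)
#' glance(rep)
#' @export
hierarchical_fce <- function(h, memberships, normalize_weights = TRUE) {
  stopifnot(inherits(h, "street_hierarchy"))
  chk <- validate_against_memberships(h, memberships)
  if (!all(chk$ok)) {
    stop_input("membership matrices incompatible with hierarchy: ",
               paste(chk$criterion[!chk$ok], collapse = ", "))
  }
  es <- h$evaluation_set
  firsts <- purrr::map(h$criteria, function(cr) {
    w <- cr$leaves$weight
    if (normalize_weights) w <- w / sum(w)
    fce_synthesize(w, memberships[[cr$id]])
  })
  names(firsts) <- purrr::map_chr(h$criteria, "id")
  stacked <- do.call(rbind, purrr::map(firsts, as.numeric))
  dimnames(stacked) <- list(names(firsts), unclass(es))
  cw <- purrr::map_dbl(h$criteria, "weight")
  if (normalize_weights) cw <- cw / sum(cw)
  overall_raw <- fuzzy_vector(as.numeric(cw %*% stacked), es,
                              normalized = FALSE)
  overall <- fce_normalize(overall_raw)
  verdict <- max_membership(overall)

  criterion_vectors <- purrr::imap_dfr(firsts, function(v, id) {
    tibble::tibble(criterion = id, level = names(v),
                   index = seq_along(v), membership = as.numeric(v))
  })
  structure(
    list(hierarchy = h, criterion_vectors = criterion_vectors,
         first_level = firsts, stacked = stacked,
         criterion_weights = stats::setNames(cw, names(firsts)),
         overall_raw = overall_raw, overall = overall,
         verdict = verdict, validation = chk),
    class = "fce_report"
  )
}

#' @export
print.fce_report <- function(x, ...) {
  cat("<fce_report> ", x$hierarchy$objective, "\n", sep = "")
  cat("  first-level vectors (un-normalized):\n")
  for (id in rownames(x$stacked)) {
    cat("    ", id, ": (", paste(sprintf("%.3f", x$stacked[id, ]),
                                 collapse = ", "), ")\n", sep = "")
  }
  cat("  overall (normalized): (",
      paste(sprintf("%.3f", as.numeric(x$overall)), collapse = ", "),
      ")\n", sep = "")
  cat(sprintf("  verdict: \"%s\" (level %d, membership %.3f%s)\n",
              x$verdict$level, x$verdict$index, x$verdict$value,
              if (x$verdict$tie) ", tie" else ""))
  invisible(x)
}

#' @rdname hierarchical_fce
#' @param x,object An `fce_report`.
#' @param ... Unused.
#' @export
tidy.fce_report <- function(x, ...) {
  dplyr::bind_rows(
    x$criterion_vectors,
    tibble::tibble(criterion = "overall", level = names(x$overall),
                   index = seq_along(x$overall),
                   membership = as.numeric(x$overall))
  )
}

#' @rdname hierarchical_fce
#' @export
glance.fce_report <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict$level, index = x$verdict$index,
    membership = x$verdict$value, tie = x$verdict$tie,
    raw_sum = sum(as.numeric(x$overall_raw)),
    n_criteria = nrow(x$stacked)
  )
}

#' @rdname hierarchical_fce
#' @export
autoplot.fce_report <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(level = factor(.data$level,
                                 unclass(object$hierarchy$evaluation_set)),
                  where = ifelse(.data$criterion == "overall",
                                 "overall", "criterion"))
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$membership,
                                   fill = .data$where)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~criterion) +
    ggplot2::scale_fill_manual(values = c(criterion = "#74a9cf",
                                          overall = "#045a8d")) +
    ggplot2::labs(x = NULL, y = "membership",
                  title = "Fuzzy comprehensive evaluation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
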