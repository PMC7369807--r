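#' Indicator hierarchies for street-space evaluation
#'
#' A hierarchy has exactly three tiers: one objective, a set of first-level
#' criteria, and second-level leaf indicators under each criterion. Every
#' internal node carries either explicit child weights or a pairwise
#' judgment matrix from which weights can be derived with [ahp_weights()].
#'
#' Printed study weights are stored verbatim: field studies commonly report
#' rounded weights whose sums drift from 1 by up to 0.01, and renormalizing
#' them would change the arithmetic of a published worked example. Weight
#' sums are therefore only required to lie within `weight_tol` (default
#' 0.02) of 1; pass `normalize = TRUE` to rescale to exact unit sums for a
#' new study.
#'
#' @name street_hierarchy
NULL

new_hierarchy <- function(objective, criteria, eval_set) {
  structure(
    list(objective = objective, criteria = criteria,
         evaluation_set = eval_set),
    class = "street_hierarchy"
  )
}

#' Load an indicator hierarchy from a configuration file or list
#'
#' Reads a three-tier indicator hierarchy (objective, criteria, leaves) from
#' a YAML or JSON document, or from an already-parsed list with the same
#' shape. Each criterion needs either a `weight` (plus `weight`s on its
#' leaves) or a `judgment` matrix; a criterion-level judgment matrix may also
#' be given at the top level as `judgment` to derive the criterion weights.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @param normalize If `TRUE`, rescale each sibling weight group to sum to
#'   exactly 1. Default `FALSE`: printed weights are preserved verbatim.
#' @param weight_tol Allowed absolute deviation of sibling weight sums
#'   from 1 (default 0.02, admitting rounded published weights).
#'
#' @return A `street_hierarchy` object.
#' @seealso [hierarchy_nodes()], [write_hierarchy()], [hierarchical_fce()]
#' @examples
#' h <- load_hierarchy(macao_fixture_path("macao_hierarchy.yaml"))
#' h
#' @export
load_hierarchy <- function(config, normalize = FALSE, weight_tol = 0.02) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config_document(config)
  }
  if (!is.list(config)) {
    stop("`config` must be a file path or a list", call. = FALSE)
  }
  objective <- config$objective %||% stop_input("config lacks an `objective`")
  eval_set <- as_evaluation_set(config$evaluation_set)
  raw_criteria <- config$criteria %||% stop_input("config lacks `criteria`")
  if (length(raw_criteria) == 0) stop_input("`criteria` is empty")

  criteria <- purrr::map(raw_criteria, parse_criterion,
                         p = length(eval_set), weight_tol = weight_tol)
  ids <- purrr::map_chr(criteria, "id")
  all_ids <- c(ids, purrr::map(criteria, ~ .x$leaves$id) |> unlist())
  if (anyDuplicated(all_ids)) {
    stop_input("duplicate indicator ids: ",
               paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }

  # Criterion weights: explicit, or derived from a top-level judgment matrix.
  w <- purrr::map(criteria, "weight")
  have_w <- !purrr::map_lgl(w, is.null)
  if (!all(have_w)) {
    if (is.null(config$judgment)) {
      stop_input("criteria without weights and no top-level judgment matrix")
    }
    jm <- judgment_matrix(config_matrix(config$judgment), labels = ids)
    fit <- ahp_weights(jm)
    for (i in seq_along(criteria)) criteria[[i]]$weight <- fit$weights[i]
  }
  check_weight_sum(purrr::map_dbl(criteria, "weight"), "criterion", weight_tol)

  if (normalize) {
    cw <- purrr::map_dbl(criteria, "weight")
    cw <- cw / sum(cw)
    for (i in seq_along(criteria)) {
      criteria[[i]]$weight <- cw[i]
      criteria[[i]]$leaves$weight <-
        criteria[[i]]$leaves$weight / sum(criteria[[i]]$leaves$weight)
    }
  }
  new_hierarchy(objective, criteria, eval_set)
}

parse_criterion <- function(node, p, weight_tol) {
  id <- node$id %||% stop_input("criterion without `id`")
  label <- node$label %||% id
  leaves_raw <- node$leaves %||% node$children
  if (is.null(leaves_raw) || length(leaves_raw) == 0) {
    stop_input("criterion `", id, "` has no leaves (deeper or flat trees ",
               "are not supported: the model is objective + two levels)")
  }
  for (lf in leaves_raw) {
    if (!is.null(lf$leaves) || !is.null(lf$children)) {
      stop_input("indicator `", lf$id %||% "?",
                 "` has children: hierarchies deeper than two levels below ",
                 "the objective are not supported")
    }
  }
  leaves <- tibble::tibble(
    id = purrr::map_chr(leaves_raw, ~ .x$id %||% stop_input("leaf without id")),
    label = purrr::map_chr(leaves_raw, ~ .x$label %||% .x$id),
    weight = purrr::map_dbl(leaves_raw, ~ .x$weight %||% NA_real_)
  )
  judgment <- NULL
  if (anyNA(leaves$weight)) {
    if (is.null(node$judgment)) {
      stop_input("criterion `", id, "` has neither complete leaf weights ",
                 "nor a judgment matrix")
    }
    judgment <- judgment_matrix(config_matrix(node$judgment),
                                labels = leaves$id)
    leaves$weight <- ahp_weights(judgment)$weights
  } else if (!is.null(node$judgment)) {
    judgment <- judgment_matrix(config_matrix(node$judgment),
                                labels = leaves$id)
  }
  check_weight_sum(leaves$weight, paste0("leaf (criterion `", id, "`)"),
                   weight_tol)
  list(id = id, label = label, weight = node$weight, leaves = leaves,
       judgment = judgment)
}

config_matrix <- function(x) {
  m <- do.call(rbind, purrr::map(x, as.numeric))
  if (is.null(m)) stop_input("empty judgment matrix in config")
  m
}

check_weight_sum <- function(w, what, tol) {
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_input(what, " weights must be finite and non-negative")
  }
  if (abs(sum(w) - 1) > tol) {
    stop_input(what, " weights sum to ", format(sum(w)),
               ", outside 1 ± ", format(tol))
  }
  invisible(w)
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("healstreet_input_error",
                                             "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config_document <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Flatten a hierarchy to a node table
#'
#' @param h A `street_hierarchy`.
#' @return A tibble with one row per node (criteria and leaves): `id`,
#'   `label`, `level` (1 = criterion, 2 = leaf), `parent`, `weight`, and
#'   `global_weight` (criterion weight times leaf weight; equal to `weight`
#'   for criteria).
#' @export
hierarchy_nodes <- function(h) {
  stopifnot(inherits(h, "street_hierarchy"))
  purrr::map_dfr(h$criteria, function(cr) {
    dplyr::bind_rows(
      tibble::tibble(id = cr$id, label = cr$label, level = 1L,
                     parent = NA_character_, weight = cr$weight,
                     global_weight = cr$weight),
      dplyr::mutate(cr$leaves, level = 2L, parent = cr$id,
                    global_weight = cr$weight * .data$weight)
    )
  })
}

#' Serialize a hierarchy back to a configuration list or file
#'
#' The written document round-trips: `load_hierarchy(write_hierarchy(h, f))`
#' reproduces `h` (judgment matrices attached to nodes are preserved).
#'
#' @param h A `street_hierarchy`.
#' @param path Optional file path (`.yaml` or `.json`); when `NULL` the
#'   configuration list is returned instead.
#' @return `path` (invisibly) when writing, else the configuration list.
#' @export
write_hierarchy <- function(h, path = NULL) {
  stopifnot(inherits(h, "street_hierarchy"))
  cfg <- list(
    objective = h$objective,
    evaluation_set = as.character(unclass(h$evaluation_set)),
    criteria = purrr::map(h$criteria, function(cr) {
      out <- list(
        id = cr$id, label = cr$label, weight = cr$weight,
        leaves = purrr::pmap(cr$leaves, function(id, label, weight, ...) {
          list(id = id, label = label, weight = weight)
        })
      )
      if (!is.null(cr$judgment)) {
        out$judgment <- apply(unclass(cr$judgment), 1, as.numeric,
                              simplify = FALSE)
      }
      out
    })
  )
  if (is.null(path)) return(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @export
print.street_hierarchy <- function(x, ...) {
  cat("<street_hierarchy> ", x$objective, "\n", sep = "")
  cat("  evaluation set: ", paste(unclass(x$evaluation_set), collapse = ", "),
      "\n", sep = "")
  for (cr in x$criteria) {
    cat(sprintf("  %-4s %-45s w = %.3f  (%d leaves)\n", cr$id,
                substr(cr$label, 1, 45), cr$weight, nrow(cr$leaves)))
  }
  invisible(x)
}

#' Check membership matrices against a hierarchy
#'
#' Verifies, criterion by criterion, that a set of membership matrices is
#' compatible with a hierarchy: one matrix per criterion, row count equal to
#' the criterion's leaf count, and column count equal to the number of
#' evaluation levels. Nothing is mutated; failures are reported, not raised.
#'
#' @param h A `street_hierarchy`.
#' @param memberships Named list of matrices (or `membership_matrix`
#'   objects), keyed by criterion id.
#' @return A tibble with one row per criterion: `criterion`, `present`,
#'   `rows_ok`, `levels_ok`, `ok`, and a human-readable `detail`.
#' @examples
#' st <- macao_study()
#' validate_against_memberships(st$hierarchy, st$memberships)
#' @export
validate_against_memberships <- function(h, memberships) {
  stopifnot(inherits(h, "street_hierarchy"))
  p <- length(h$evaluation_set)
  purrr::map_dfr(h$criteria, function(cr) {
    m <- memberships[[cr$id]]
    if (is.null(m)) {
      return(tibble::tibble(criterion = cr$id, present = FALSE,
                            rows_ok = NA, levels_ok = NA, ok = FALSE,
                            detail = "membership matrix missing"))
    }
    rows_ok <- nrow(m) == nrow(cr$leaves)
    levels_ok <- ncol(m) == p
    tibble::tibble(
      criterion = cr$id, present = TRUE,
      rows_ok = rows_ok, levels_ok = levels_ok,
      ok = rows_ok && levels_ok,
      detail = if (rows_ok && levels_ok) "ok" else paste0(
        nrow(m), "x", ncol(m), " matrix vs ", nrow(cr$leaves),
        " leaves and ", p, " levels")
    )
  })
}
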