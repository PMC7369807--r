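#' End-to-end street-space evaluation pipeline
#'
#' Strings the stages together: load the hierarchy, (optionally) derive
#' criterion weights from a judgment matrix with a consistency gate, load
#' the membership matrices, run the two-level fuzzy comprehensive
#' evaluation, and return the audited report. A config is a list (or a
#' YAML/JSON file) with fields:
#'
#' * `fixture`: `"macao"` to run the packaged worked example, or
#' * `hierarchy`: hierarchy config path, and
#' * `memberships`: path to a membership CSV in the packaged layout
#'   (columns `criterion`, `indicator`, then one column per level);
#' * optional `judgment`: path to a criterion-level judgment matrix CSV
#'   whose AHP weights replace the hierarchy's criterion weights;
#' * optional `force`: proceed despite a failing consistency ratio.
#'
#' Errors are classed for scriptability: `healstreet_input_error` for
#' missing/invalid inputs, `healstreet_consistency_error` when a judgment
#' matrix fails the CR < 0.1 test without `force`.
#'
#' @param config List or path to a YAML/JSON config document.
#' @param force Override a failing consistency test (also settable in the
#'   config).
#' @return An `fce_report` (see [hierarchical_fce()]); when a judgment
#'   matrix was used, the `ahp` element carries the [ahp_weights()] fit.
#' @examples
#' rep <- run_pipeline(list(fixture = "macao"))
#' rep$verdict
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config_document(config)
  }
  force <- isTRUE(config$force) || force
  fit <- NULL
  if (identical(config$fixture, "macao")) {
    h <- macao_hierarchy()
    ms <- macao_memberships()
  } else {
    if (is.null(config$hierarchy) || is.null(config$memberships)) {
      stop_input("config needs `fixture: macao` or both `hierarchy` and ",
                 "`memberships`")
    }
    h <- load_hierarchy(config$hierarchy)
    ms <- read_membership_map(config$memberships)
    if (!is.null(config$judgment)) {
      jm <- read_judgment_matrix(config$judgment)
      fit <- ahp_weights(jm, force = force)
      if (nrow(jm) != length(h$criteria)) {
        stop_input("judgment matrix order ", nrow(jm),
                   " does not match the ", length(h$criteria),
                   " criteria")
      }
      for (i in seq_along(h$criteria)) {
        h$criteria[[i]]$weight <- fit$weights[i]
      }
    }
  }
  rep <- hierarchical_fce(h, ms)
  rep$ahp <- fit
  rep
}

read_membership_map <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("criterion", "indicator") %in% names(df))) {
    stop_input("membership file needs `criterion` and `indicator` columns")
  }
  split(df, factor(df$criterion, unique(df$criterion))) |>
    lapply(function(d) {
      membership_matrix(as.matrix(d[, -(1:2)]), indicator_ids = d$indicator,
                        levels = colnames(d)[-(1:2)])
    })
}

#' Write an evaluation report to JSON
#'
#' Serializes every intermediate of an `fce_report` (weights, first-level
#' vectors, stacked matrix, raw and normalized overall vectors, verdict) at
#' full precision. The file round-trips through [jsonlite::read_json()] and
#' feeding the recorded intermediates back through [fce_normalize()] and
#' [max_membership()] reproduces the verdict.
#'
#' @param report An `fce_report`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fce_report"))
  nodes <- hierarchy_nodes(report$hierarchy)
  out <- list(
    objective = report$hierarchy$objective,
    evaluation_set = as.character(unclass(report$hierarchy$evaluation_set)),
    weights = purrr::pmap(nodes, function(id, level, parent, weight,
                                          global_weight, ...) {
      list(id = id, level = level, parent = parent, weight = weight,
           global_weight = global_weight)
    }),
    first_level = lapply(report$first_level, as.numeric),
    criterion_weights = as.list(report$criterion_weights),
    overall_raw = as.numeric(report$overall_raw),
    overall = as.numeric(report$overall),
    verdict = as.list(report$verdict),
    version = as.character(utils::packageVersion("healstreet"))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
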