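#' Packaged Macao old-town worked example
#'
#' The complete published worked example for Macao's old city area ships as
#' plain-text fixtures: the three-tier indicator hierarchy with its printed
#' weights, the 5x5 criterion-level judgment matrix, the five second-level
#' membership matrices, and the posture-by-activity frequency table from
#' the field observation campaign. Printed values are stored verbatim (two
#' decimals, sums 0.99-1.01), never renormalized, so package output can be
#' compared digit-for-digit with the published tables.
#'
#' @name macao_fixtures
NULL

#' Path to a packaged fixture file
#'
#' @param file Fixture file name; with no argument, lists available
#'   fixtures.
#' @return A file path (or a character vector of names).
#' @examples
#' macao_fixture_path()
#' @export
macao_fixture_path <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "healstreet")))
  }
  path <- system.file("extdata", file, package = "healstreet")
  if (!nzchar(path)) stop_input("no packaged fixture named `", file, "`")
  path
}

#' @describeIn macao_fixtures The indicator hierarchy with printed weights.
#' @export
macao_hierarchy <- function() {
  load_hierarchy(macao_fixture_path("macao_hierarchy.yaml"))
}

#' @describeIn macao_fixtures The 5x5 criterion-level judgment matrix
#'   (printed two-decimal entries).
#' @export
macao_judgment <- function() {
  read_judgment_matrix(macao_fixture_path("macao_judgment.csv"))
}

#' @describeIn macao_fixtures Named list of the five second-level
#'   membership matrices, keyed by criterion id (u1..u5).
#' @export
macao_memberships <- function() {
  df <- utils::read.csv(macao_fixture_path("macao_memberships.csv"),
                        check.names = FALSE)
  split(df, factor(df$criterion, unique(df$criterion))) |>
    lapply(function(d) {
      membership_matrix(as.matrix(d[, -(1:2)]), indicator_ids = d$indicator,
                        levels = colnames(d)[-(1:2)])
    })
}

#' @describeIn macao_fixtures The posture-by-activity frequency table from
#'   the observation campaign.
#' @export
macao_activity_table <- function() {
  readr::read_csv(macao_fixture_path("macao_activities.csv"),
                  show_col_types = FALSE)
}

#' @describeIn macao_fixtures Hierarchy plus memberships bundled for
#'   [hierarchical_fce()].
#' @export
macao_study <- function() {
  list(hierarchy = macao_hierarchy(), memberships = macao_memberships())
}
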