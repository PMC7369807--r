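#' Ordinal evaluation set
#'
#' An evaluation set is the ordered list of judgment levels a fuzzy
#' comprehensive evaluation classifies into, ordered from the most severe
#' (worst) level to the best. The default set is the five-level scale used
#' for street-space healing-environment assessment: Poor, Relatively Poor,
#' General, Good, Very Good.
#'
#' @param labels Character vector of unique level names, worst first.
#'   At least two levels are required.
#'
#' @return An object of class `evaluation_set`: a character vector of labels
#'   with the number of levels available via `length()`.
#' @examples
#' evaluation_set()
#' evaluation_set(c("Fail", "Pass"))
#' @export
evaluation_set <- function(labels = c("Poor", "Relatively Poor", "General",
                                      "Good", "Very Good")) {
  labels <- as.character(labels)
  if (length(labels) < 2) {
    stop("an evaluation set needs at least two levels", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("evaluation set labels must be unique", call. = FALSE)
  }
  structure(labels, class = "evaluation_set")
}

#' @export
print.evaluation_set <- function(x, ...) {
  cat("<evaluation_set> ", length(x), " levels (worst first): ",
      paste(unclass(x), collapse = " < "), "\n", sep = "")
  invisible(x)
}

is_evaluation_set <- function(x) inherits(x, "evaluation_set")

# Coerce labels-or-set to an evaluation_set, defaulting when NULL.
as_evaluation_set <- function(x) {
  if (is.null(x)) return(evaluation_set())
  if (is_evaluation_set(x)) return(x)
  evaluation_set(x)
}
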