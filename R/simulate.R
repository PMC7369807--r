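#' Synthetic inputs for every pipeline stage
#'
#' Seeded generators emulating the statistical structure of the field data:
#' expert pairwise comparisons with controllable inconsistency, multinomial
#' questionnaire responses over the five-level evaluation set, behavioral
#' observation logs with the protocol's age-group/posture/activity
#' structure, and named street-graph topologies. All generators take an
#' explicit seed and never touch the global random state beyond a local,
#' restored RNG scope.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, code) {
  if (is.null(seed)) stop_input("a seed is required for stochastic generation")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate an expert judgment matrix from true weights
#'
#' Builds the consistent ratio matrix w_i/w_j and perturbs each
#' upper-triangle entry multiplicatively by exp(e_ij) with
#' e_ij ~ Normal(0, noise_level^2), mirroring the error antisymmetrically
#' (e_ji = -e_ij) so the result is exactly reciprocal by construction.
#' Log-normal multiplicative noise keeps entries positive and makes
#' `noise_level` directly interpretable as the log-scale size of expert
#' error; at `noise_level = 0` the matrix is perfectly consistent and AHP
#' recovers `true_weights` exactly.
#'
#' @param true_weights Positive weights summing to 1 (tolerance 1e-6).
#' @param noise_level Non-negative log-scale perturbation SD.
#' @param seed Integer seed (required when `noise_level > 0`).
#' @return A `judgment_matrix`.
#' @examples
#' simulate_judgment_matrix(c(0.5, 0.3, 0.2), noise_level = 0)
#' @export
simulate_judgment_matrix <- function(true_weights, noise_level = 0,
                                     seed = NULL) {
  w <- as.numeric(true_weights)
  if (any(w <= 0)) stop_input("true weights must be strictly positive")
  if (abs(sum(w) - 1) > 1e-6) stop_input("true weights must sum to 1")
  if (noise_level < 0) stop_input("noise_level must be non-negative")
  n <- length(w)
  a <- outer(w, w, "/")
  if (noise_level > 0) {
    eps <- with_seed(seed, {
      e <- matrix(0, n, n)
      e[upper.tri(e)] <- stats::rnorm(n * (n - 1) / 2, 0, noise_level)
      e - t(e)
    })
    a <- a * exp(eps)
  }
  diag(a) <- 1
  judgment_matrix(a, recip_tol = 1e-9)
}

#' Simulate questionnaire rating counts
#'
#' Independent multinomial draws per indicator over the evaluation levels.
#'
#' @param true_memberships Matrix (indicators x levels) or list of
#'   probability vectors, each summing to 1 within 1e-9.
#' @param respondents Respondents per indicator (scalar or one per
#'   indicator), each >= 1.
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix) and `respondents`.
#' @examples
#' simulate_survey(rbind(c(0.1, 0.2, 0.4, 0.2, 0.1)), 100, seed = 1)
#' @export
simulate_survey <- function(true_memberships, respondents, seed) {
  p <- if (is.list(true_memberships)) {
    do.call(rbind, true_memberships)
  } else {
    as.matrix(true_memberships)
  }
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9)) {
    stop_input("each true membership row must be a probability vector")
  }
  m <- nrow(p)
  n <- rep_len(as.integer(respondents), m)
  if (any(n < 1)) stop_input("each indicator needs at least one respondent")
  counts <- with_seed(seed, {
    t(vapply(seq_len(m), function(i) {
      as.integer(stats::rmultinom(1, n[i], p[i, ]))
    }, integer(ncol(p))))
  })
  rownames(counts) <- rownames(p)
  list(counts = counts, respondents = n)
}

default_streets <- function() {
  tibble::tibble(
    street = c("rua_a", "rua_b"),
    age_mixture = list(c(child = 0.1, youth = 0.3, middle_aged = 0.3,
                         aged = 0.3),
                       c(child = 0.05, youth = 0.45, middle_aged = 0.3,
                         aged = 0.2))
  )
}

# (posture, activity) category space of the field frequency table.
activity_space <- function() {
  tibble::tribble(
    ~posture,   ~activity,
    "standing", "watch",
    "standing", "taking pictures",
    "standing", "conversation",
    "standing", "waiting for the bus",
    "standing", "shopping",
    "sitting",  "rest",
    "sitting",  "conversation",
    "sitting",  "sale of goods",
    "exercise", "running",
    "relax",    "look around",
    "relax",    "eat",
    "relax",    "drink",
    "rely_on",  "waiting for bus",
    "rely_on",  "rest"
  )
}

# Age sampled uniformly within the sampled group's bin (aged capped at 90).
sample_age <- function(group) {
  lo <- c(child = 0, youth = 15, middle_aged = 45, aged = 65)[group]
  hi <- c(child = 14, youth = 44, middle_aged = 64, aged = 90)[group]
  as.integer(floor(stats::runif(length(group), lo, hi + 1)))
}

#' Simulate a behavioral observation log
#'
#' Draws records street by street: the observation interval uniformly over
#' the three daily windows, the age group from each street's mixture (age
#' in years uniform within the group's bin), the (posture, activity) pair
#' uniformly over the field category space, group sizes from the observed
#' regimes (scattered individuals, groups of 3-5, groups of 5-8), and stay
#' durations from a two-part mixture with probability `short_stay_prob` of
#' a sub-5-minute stay (exercising the by-passer exclusion filter).
#'
#' @param streets Tibble with `street` and `age_mixture` (named probability
#'   vector over the four age groups) columns; default two synthetic
#'   streets.
#' @param records_per_street Records to draw per street.
#' @param short_stay_prob Probability a stay is shorter than 5 minutes.
#' @param seed Integer seed.
#' @return Tibble of observation records with the standard log columns.
#' @examples
#' simulate_observations(records_per_street = 5, seed = 1)
#' @export
simulate_observations <- function(streets = default_streets(),
                                  records_per_street = 100,
                                  short_stay_prob = 0.2, seed) {
  if (nrow(streets) == 0) stop_input("street list is empty")
  cats <- activity_space()
  with_seed(seed, {
    purrr::pmap_dfr(streets, function(street, age_mixture, ...) {
      n <- records_per_street
      grp <- sample(names(age_mixture), n, replace = TRUE,
                    prob = age_mixture)
      short <- stats::runif(n) < short_stay_prob
      dur <- ifelse(short, stats::runif(n, 0, 5),
                    5 + stats::rexp(n, rate = 1 / 20))
      ci <- sample(nrow(cats), n, replace = TRUE)
      size_regime <- sample(c("single", "small", "large"), n, replace = TRUE,
                            prob = c(0.5, 0.35, 0.15))
      gs <- ifelse(size_regime == "single", 1L,
                   ifelse(size_regime == "small",
                          sample(3:5, n, replace = TRUE),
                          sample(5:8, n, replace = TRUE)))
      tibble::tibble(
        street = street,
        interval = sample(INTERVALS, n, replace = TRUE),
        age_years = sample_age(grp),
        age_group = grp,
        group_size = as.integer(gs),
        duration_min = round(dur, 1),
        posture = cats$posture[ci],
        activity = cats$activity[ci]
      )
    })
  })
}

#' Reconstruct an observation log matching a frequency table
#'
#' Emits one record per count of a (posture, activity) frequency table, so
#' that [aggregate_activities()] on the result reproduces the table's
#' marginals exactly. Durations are set above the short-stay threshold;
#' street, interval and age fields are drawn with the given seed.
#'
#' @param table Tibble with `posture`, `activity`, `frequency`.
#' @param street Street id to assign (single synthetic street).
#' @param seed Integer seed for the auxiliary fields.
#' @return Observation-log tibble with `sum(table$frequency)` rows.
#' @examples
#' tab <- macao_activity_table()
#' logd <- observations_from_activity_table(tab, seed = 1)
#' @export
observations_from_activity_table <- function(table, street = "synthetic",
                                             seed) {
  n <- sum(table$frequency)
  idx <- rep(seq_len(nrow(table)), table$frequency)
  with_seed(seed, {
    grp <- sample(AGE_GROUPS, n, replace = TRUE)
    tibble::tibble(
      street = street,
      interval = sample(INTERVALS, n, replace = TRUE),
      age_years = sample_age(grp),
      age_group = grp,
      group_size = 1L,
      duration_min = round(5 + stats::rexp(n, 1 / 20), 1),
      posture = table$posture[idx],
      activity = table$activity[idx]
    )
  })
}

#' Simulate a street graph of a named topology
#'
#' @param kind One of `"path"`, `"star"`, `"cycle"`, `"grid"`, `"random"`.
#'   `"random"` draws a seeded Erdős–Rényi G(n, p) graph conditioned on
#'   being connected (p = 0.4).
#' @param size Node count (for `"grid"`, the side length; >= 2, cycles
#'   >= 3).
#' @param seed Integer seed (required for `"random"`).
#' @return A `street_graph` with node ids `"v1"`, `"v2"`, ...
#' @examples
#' connectivity(simulate_street_graph("star", 7))
#' @export
simulate_street_graph <- function(kind = c("path", "star", "cycle", "grid",
                                           "random"),
                                  size, seed = NULL) {
  kind <- match.arg(kind)
  if (size < 2) stop_input("size must be at least 2")
  if (kind == "cycle" && size < 3) stop_input("a cycle needs >= 3 nodes")
  g <- switch(kind,
    path = igraph::make_ring(size, circular = FALSE),
    cycle = igraph::make_ring(size, circular = TRUE),
    star = igraph::make_star(size, mode = "undirected", center = 1),
    grid = igraph::make_lattice(c(size, size)),
    random = with_seed(seed, {
      repeat {
        gr <- igraph::sample_gnp(size, 0.4)
        if (igraph::is_connected(gr)) break
      }
      gr
    })
  )
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  class(g) <- c("street_graph", class(g))
  g
}
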