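paper_overall <- c(0.125, 0.263, 0.265, 0.210, 0.137)

test_that("survey counts convert to exact row-proportion memberships", {
  m <- membership_from_counts(rbind(c(57, 36, 7, 0, 1)))
  expect_equal(unname(unclass(m)[1, ]), c(0.57, 0.36, 0.07, 0, 0.01) / 1.01,
               tolerance = 1e-12)
  expect_equal(sum(unclass(m)[1, ]), 1, tolerance = 1e-12)

  u <- membership_from_counts(rbind(c(10, 10, 10, 10, 10)))
  expect_equal(unname(unclass(u)[1, ]), rep(0.2, 5))

  expect_error(membership_from_counts(rbind(c(0, 0, 0, 0, 0))),
               "zero respondents")
})

test_that("membership matrix validation enforces row sums and shape", {
  # printed two-decimal rows (sums 0.99-1.01) pass at the default tolerance
  expect_s3_class(macao_memberships()$u1, "membership_matrix")
  # but fail strict mode
  expect_error(membership_matrix(unclass(macao_memberships()$u2),
                                 strict = TRUE),
               class = "healstreet_input_error")
  expect_error(membership_matrix(rbind(c(0.5, 0.3))), "levels")
  expect_error(membership_matrix(rbind(c(0.9, 0.4, 0, 0, 0))), "sums")
})

test_that("weighted-average synthesis is the plain vector-matrix product", {
  ms <- macao_memberships()

  # identical rows: output is the common row scaled by the weight sum
  rho <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  r_same <- membership_matrix(rbind(rho, rho, rho))
  w <- c(0.5, 0.3, 0.1)
  expect_equal(as.numeric(fce_synthesize(w, r_same)), rho * sum(w),
               tolerance = 1e-12)

  # one-hot weights select a row
  expect_equal(as.numeric(fce_synthesize(c(0, 1, 0), r_same)), rho,
               tolerance = 1e-12)

  # dimension mismatch and negative weights are rejected
  expect_error(fce_synthesize(c(0.5, 0.5), r_same), "rows")
  expect_error(fce_synthesize(c(-0.1, 0.6, 0.5), r_same), "non-negative")

  # linearity in the matrix argument
  r1 <- unclass(ms$u4)
  r2 <- matrix(rep(rho, each = 3), 3)
  a <- 0.3
  blend <- membership_matrix(a * r1 + (1 - a) * r2)
  w4 <- c(0.47, 0.47, 0.05)
  expect_equal(as.numeric(fce_synthesize(w4, blend)),
               a * as.numeric(fce_synthesize(w4, r1)) +
                 (1 - a) * as.numeric(fce_synthesize(w4, r2)),
               tolerance = 1e-12)

  # output bounds: each component within [min, max] column value x sum(w)
  out <- as.numeric(fce_synthesize(w4, ms$u4))
  for (jcol in 1:5) {
    expect_gte(out[jcol], min(unclass(ms$u4)[, jcol]) * sum(w4) - 1e-12)
    expect_lte(out[jcol], max(unclass(ms$u4)[, jcol]) * sum(w4) + 1e-12)
  }
})

test_that("normalization rescales to unit sum, preserves order and is idempotent", {
  expect_equal(as.numeric(fce_normalize(c(3, 1, 0, 0, 0))),
               c(0.75, 0.25, 0, 0, 0))
  expect_equal(as.numeric(fce_normalize(rep(0.2, 5))), rep(0.2, 5))

  v <- fce_synthesize(c(0.49, 0.3, 0.21), macao_memberships()$u5)
  n1 <- fce_normalize(v)
  expect_equal(as.numeric(fce_normalize(n1)), as.numeric(n1),
               tolerance = 1e-14)
  expect_equal(order(as.numeric(n1)), order(as.numeric(v)))

  expect_error(fce_normalize(c(0, 0, 0)), "all-zero")
})

test_that("maximum membership picks the right level and breaks ties severely", {
  res <- max_membership(paper_overall)
  expect_equal(res$level, "General")
  expect_equal(res$index, 3L)
  expect_equal(res$value, 0.265)
  expect_false(res$tie)

  expect_equal(max_membership(c(0, 0, 0, 0, 1))$level, "Very Good")

  tie <- max_membership(c(0.3, 0.3, 0.2, 0.1, 0.1))
  expect_equal(tie$level, "Poor")
  expect_true(tie$tie)

  expect_error(max_membership(c(0.5, 0.5), evaluation_set()), "levels|match")
})

test_that("two-level evaluation composes correctly on degenerate hierarchies", {
  # single criterion with weight 1: overall equals that criterion's
  # normalized first-level vector
  cfg <- list(
    objective = "toy", criteria = list(list(
      id = "c1", label = "only", weight = 1,
      leaves = list(list(id = "l1", weight = 0.6),
                    list(id = "l2", weight = 0.4))
    ))
  )
  h <- load_hierarchy(cfg)
  m <- membership_matrix(rbind(c(0.5, 0.2, 0.1, 0.1, 0.1),
                               c(0.1, 0.1, 0.2, 0.2, 0.4)))
  rep <- hierarchical_fce(h, list(c1 = m))
  expect_equal(as.numeric(rep$overall),
               as.numeric(fce_normalize(fce_synthesize(c(0.6, 0.4), m))),
               tolerance = 1e-12)

  # constant membership rows: overall equals the common row whatever the
  # weights (convexity)
  rho <- c(0.05, 0.15, 0.4, 0.3, 0.1)
  st <- macao_study()
  ms_const <- lapply(st$memberships, function(mm) {
    membership_matrix(matrix(rep(rho, each = nrow(mm)), nrow(mm)))
  })
  rep2 <- hierarchical_fce(st$hierarchy, ms_const)
  expect_equal(as.numeric(rep2$overall), rho, tolerance = 1e-12)
})

test_that("the packaged study evaluates to 'General' with audited intermediates", {
  st <- macao_study()
  rep <- hierarchical_fce(st$hierarchy, st$memberships)
  expect_equal(rep$verdict$level, "General")
  expect_equal(rep$verdict$index, 3L)
  expect_equal(as.numeric(rep$overall), paper_overall, tolerance = 0.005)
  expect_equal(sum(as.numeric(rep$overall)), 1, tolerance = 1e-12)

  # intermediates re-validate: normalize + classify reproduces the verdict
  again <- max_membership(fce_normalize(rep$overall_raw))
  expect_equal(again, rep$verdict)

  # tidy/glance surfaces
  td <- tidy(rep)
  expect_setequal(unique(td$criterion), c(paste0("u", 1:5), "overall"))
  expect_equal(glance(rep)$verdict, "General")

  # incompatible membership map is refused
  expect_error(hierarchical_fce(st$hierarchy, st$memberships[-1]),
               class = "healstreet_input_error")
})
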