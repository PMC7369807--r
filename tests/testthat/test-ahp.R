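test_that("judgment matrix validation accepts printed matrices and rejects malformed input", {
  jm <- macao_judgment()
  expect_s3_class(jm, "judgment_matrix")
  expect_equal(unname(unclass(jm)[1, ]), c(1, 3, 5, 3, 1))

  expect_s3_class(judgment_matrix(matrix(1, 3, 3)), "judgment_matrix")

  expect_error(judgment_matrix(rbind(c(1, 0), c(2, 1))),
               class = "healstreet_input_error")          # zero entry
  expect_error(judgment_matrix(matrix(1, 2, 3)), "square")
  expect_error(judgment_matrix(rbind(c(2, 1), c(1, 1))), "diagonal")
  expect_error(judgment_matrix(rbind(c(1, 3), c(0.5, 1))), "reciprocity")

  # rationalize restores exact reciprocals without touching the upper triangle
  jr <- judgment_matrix(unclass(jm), rationalize = TRUE)
  expect_equal(unclass(jr)[2, 1], 1 / 3)
  expect_equal(unclass(jr)[1, 2], 3)
  expect_true(all(abs(unclass(jr) * t(unclass(jr)) - 1) < 1e-12))
})

test_that("geometric-mean weights match closed forms and the eigenvector oracle", {
  # perfect indifference: uniform weights
  for (n in c(3, 5)) {
    w <- geometric_mean_weights(judgment_matrix(matrix(1, n, n)))
    expect_equal(w$weight, rep(1 / n, n))
  }

  # consistent 2x2: closed form (0.75, 0.25), eigenvector agrees
  j2 <- judgment_matrix(rbind(c(1, 3), c(1 / 3, 1)))
  expect_equal(geometric_mean_weights(j2)$weight, c(0.75, 0.25),
               tolerance = 1e-12)
  expect_equal(principal_eigen_weights(j2)$weight, c(0.75, 0.25),
               tolerance = 1e-9)

  # consistent matrix built from known weights: both rules recover them
  truth <- c(0.5, 0.3, 0.2)
  jc <- simulate_judgment_matrix(truth, noise_level = 0)
  expect_equal(geometric_mean_weights(jc)$weight, truth, tolerance = 1e-12)
  expect_equal(principal_eigen_weights(jc)$weight, truth, tolerance = 1e-9)

  # near-consistent printed matrix: the two rules agree to 1e-3 per component
  jm <- macao_judgment()
  expect_lt(max(abs(geometric_mean_weights(jm)$weight -
                    principal_eigen_weights(jm)$weight)), 1e-3)

  # weights always sum to one
  expect_equal(sum(geometric_mean_weights(jm)$weight), 1, tolerance = 1e-12)
})

test_that("lambda_max matches a dense eigen-solver and is bounded below by n", {
  j3 <- judgment_matrix(rbind(c(1, 2, 6), c(1 / 2, 1, 2), c(1 / 6, 1 / 2, 1)))
  ew <- principal_eigen_weights(j3, tol = 1e-14)
  expect_equal(lambda_max(j3, ew),
               max(Re(eigen(unclass(j3))$values)), tolerance = 1e-6)

  # exactly consistent matrices have lambda_max = n
  jc <- simulate_judgment_matrix(c(0.4, 0.35, 0.25), noise_level = 0)
  expect_equal(lambda_max(jc, geometric_mean_weights(jc)), 3,
               tolerance = 1e-12)

  # lambda_max >= n over random reciprocal matrices, equality iff consistent
  for (n in 3:7) {
    j <- simulate_judgment_matrix(rep(1 / n, n), noise_level = 0.4,
                                  seed = 100 + n)
    lm <- lambda_max(j, principal_eigen_weights(j))
    expect_gte(lm, n - 1e-9)
  }

  expect_error(lambda_max(j3, c(0, 0.5, 0.5)), "positive")
})

test_that("consistency check reproduces the RI table contract and classifies matrices", {
  # printed criterion matrix with exact reciprocals restored: CR 0, pass
  jr <- judgment_matrix(unclass(macao_judgment()), rationalize = TRUE)
  rep <- consistency_check(jr, geometric_mean_weights(jr))
  expect_equal(rep$ri, 1.12)
  expect_equal(round(rep$lambda_max, 3), 5)
  expect_equal(round(rep$ci, 3), 0)
  expect_equal(round(rep$cr, 3), 0)
  expect_true(rep$consistent)

  # n = 2 is always consistent by definition
  rep2 <- consistency_check(judgment_matrix(rbind(c(1, 7), c(1 / 7, 1))),
                            c(0.875, 0.125))
  expect_equal(rep2$cr, 0)
  expect_true(rep2$consistent)

  # maximally cyclic 3x3 fails, and the Eq-style estimate agrees with eigen()
  jc <- judgment_matrix(rbind(c(1, 9, 1 / 9), c(1 / 9, 1, 9),
                              c(9, 1 / 9, 1)))
  wc <- principal_eigen_weights(jc, tol = 1e-14)
  repc <- consistency_check(jc, wc)
  expect_false(repc$consistent)
  expect_gt(repc$cr, 0.1)
  expect_equal(repc$lambda_max, max(Re(eigen(unclass(jc))$values)),
               tolerance = 1e-6)

  # RI table domain is n = 1..9
  big <- simulate_judgment_matrix(rep(0.1, 10), noise_level = 0)
  expect_error(consistency_check(big, geometric_mean_weights(big)),
               class = "healstreet_input_error")
})

test_that("ahp_weights gates on consistency and honors force", {
  fit <- ahp_weights(macao_judgment())
  expect_lt(max(abs(fit$weights -
                    c(0.34991, 0.11593, 0.06967, 0.11598, 0.34850))),
            0.0015)
  expect_true(glance(fit)$consistent)
  expect_named(tidy(fit), c("indicator", "geom_mean", "weight", "feature"))

  bad <- simulate_judgment_matrix(rep(0.2, 5), noise_level = 1.2, seed = 42)
  expect_error(ahp_weights(bad), class = "healstreet_consistency_error")
  forced <- ahp_weights(bad, force = TRUE)
  expect_false(forced$consistency$consistent)
  expect_equal(sum(forced$weights), 1, tolerance = 1e-12)
})

test_that("weights are equivariant under indicator permutation", {
  j <- simulate_judgment_matrix(c(0.4, 0.25, 0.2, 0.15), noise_level = 0.1,
                                seed = 7)
  perm <- c(3, 1, 4, 2)
  jp <- judgment_matrix(unclass(j)[perm, perm], recip_tol = 1e-9)
  expect_equal(geometric_mean_weights(jp)$weight,
               geometric_mean_weights(j)$weight[perm], tolerance = 1e-12)
  expect_equal(principal_eigen_weights(jp)$weight,
               principal_eigen_weights(j)$weight[perm], tolerance = 1e-9)
})

test_that("geometric-mean and eigenvector rules agree within 0.01 on consistent-enough matrices", {
  for (s in 1:20) {
    n <- 3 + (s %% 4)
    j <- simulate_judgment_matrix(rep(1 / n, n), noise_level = 0.15,
                                  seed = 2000 + s)
    rep <- consistency_check(j, geometric_mean_weights(j))
    if (!rep$consistent) next
    expect_lt(max(abs(geometric_mean_weights(j)$weight -
                      principal_eigen_weights(j)$weight)), 0.01)
  }
})
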