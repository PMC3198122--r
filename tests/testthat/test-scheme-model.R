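test_that("probability triples are validated", {
  expect_equal(unname(prob_triple(c(0.2, 0.3, 0.5))), c(0.2, 0.3, 0.5))
  expect_error(prob_triple(c(0.2, 0.3)), "3 components")
  expect_error(prob_triple(c(0.5, 0.6, -0.1)), "\\[0, 1\\]")
  expect_error(prob_triple(c(0.2, 0.3, 0.4)), "sum to 1")
})

test_that("degenerate sampling regions force the unique point", {
  xm <- sample_x_marginals(1, region = list(ich = c(0.06, 0.06),
                                            mni = c(0.26, 0.26)))
  expect_equal(drop(xm), c(ICH = 0.06, NEI = 0.68, MNI = 0.26))
  ym <- sample_y_marginal(region = list(poor = c(0.40, 0.40),
                                        good = c(0.35, 0.35)))
  expect_equal(drop(ym), c(poor = 0.40, neither = 0.25, good = 0.35))
})

test_that("marginal draws respect region bounds and sum to one", {
  set.seed(101)
  xm <- sample_x_marginals(10)
  expect_true(all(xm[, "ICH"] >= 0.01 & xm[, "ICH"] <= 0.12))
  expect_true(all(xm[, "MNI"] >= 0.05 & xm[, "MNI"] <= 0.45))
  expect_equal(rowSums(xm), rep(1, 10))
  ym <- sample_y_marginal(count = 10)
  expect_true(all(ym[, "poor"] >= 0.20 & ym[, "poor"] <= 0.60))
  expect_true(all(ym[, "good"] >= 0.15 & ym[, "good"] <= 0.55))
  expect_equal(rowSums(ym), rep(1, 10))
})

test_that("region sampling is uniform over the admissible sub-simplex", {
  # compare against an independently coded rejection sampler on a region
  # where the simplex constraint binds (so the box marginal is not uniform)
  b1 <- c(0.10, 0.90)
  b3 <- c(0.30, 0.95)
  set.seed(202)
  mine <- sample_x_marginals(10000, region = list(ich = b1, mni = b3))
  orac <- oracle_region(10000, b1, b3)
  for (k in 1:3) {
    se <- sqrt(stats::var(mine[, k]) / 10000 + stats::var(orac[, k]) / 10000)
    expect_lt(abs(mean(mine[, k]) - mean(orac[, k])), 4 * se)
  }
  # default region: box unconstrained, so the ICH marginal is uniform with
  # known midpoint
  set.seed(203)
  xm <- sample_x_marginals(10000)
  expect_lt(abs(mean(xm[, "ICH"]) - (0.01 + 0.12) / 2),
            4 * sqrt(0.11^2 / 12 / 10000))
})

test_that("empty regions error out after the rejection cap", {
  expect_error(
    sample_x_marginals(1, region = list(ich = c(0.7, 0.8), mni = c(0.5, 0.9)),
                       max_tries = 5000),
    "admissible area")
})

test_that("independence conditional is admissible and exact", {
  x <- c(0.06, 0.64, 0.30)
  y <- c(0.40, 0.25, 0.35)
  sc <- make_scheme(x, y) # independence conditional by default
  expect_true(validate_scheme(sc))
  expect_equal(drop(sc$x["A", ] %*% sc$cond$A), sc$y["A", ])
})

test_that("sampled conditionals satisfy marginalization and monotonicity", {
  set.seed(301)
  for (rep in 1:50) {
    x <- drop(sample_x_marginals(1))
    y <- drop(sample_y_marginal())
    cm <- sample_conditional(x, y)
    expect_lt(max(abs(drop(x %*% cm) - y)), 1e-10)
    expect_true(cm[1, 1] >= cm[2, 1] && cm[2, 1] >= cm[3, 1])
    expect_true(cm[1, 3] <= cm[2, 3] && cm[2, 3] <= cm[3, 3])
    expect_equal(unname(rowSums(cm)), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("conditional sampler matches an independent implementation of the
           acceptance region", {
  x <- c(0.05, 0.60, 0.35)
  y <- c(0.45, 0.25, 0.30)
  set.seed(302)
  mine <- t(replicate(1500, sample_conditional(x, y)[1, ]))
  orac <- oracle_cond_draws(x, y, 200000)
  expect_gt(nrow(orac$rI), 1000)
  for (k in c(1, 3)) {
    se <- sqrt(stats::var(mine[, k]) / nrow(mine) +
                 stats::var(orac$rI[, k]) / nrow(orac$rI))
    expect_lt(abs(mean(mine[, k]) - mean(orac$rI[, k])), 4 * se)
  }
})

test_that("infeasibility within the attempt cap raises a constraint-naming
           error", {
  expect_error(
    sample_conditional(c(0.45, 0.10, 0.45), c(0.55, 0.01, 0.44),
                       max_tries = 200),
    "violation")
})

test_that("conditional rows for zero-probability X categories default to the
           Y-marginal", {
  y <- c(0.4, 0.25, 0.35)
  set.seed(303)
  cm <- sample_conditional(c(0, 0.7, 0.3), y)
  expect_equal(unname(cm[1, ]), y)
  expect_lt(max(abs(drop(c(0, 0.7, 0.3) %*% cm) - y)), 1e-10)
  cm1 <- sample_conditional(c(0, 0, 1), y)
  expect_equal(unname(cm1[3, ]), y)
})

test_that("scheme ensembles have the requested size and pass all invariants", {
  ens <- build_scheme_ensemble(2, 2, 2, seed = 5)
  expect_length(ens, 8)
  for (sc in ens) {
    expect_true(validate_scheme(sc))
    expect_true(sc$is_null)
    # null: identical Y-marginal across arms
    expect_equal(max(abs(sweep(sc$y, 2, sc$y[1, ]))), 0)
  }
  expect_length(build_scheme_ensemble(1, 1, 1, seed = 5), 1)
})

test_that("ensembles are reproducible from the master seed", {
  e1 <- build_scheme_ensemble(2, 2, 1, seed = 77)
  e2 <- build_scheme_ensemble(2, 2, 1, seed = 77)
  expect_identical(e1, e2)
})

test_that("per-arm draws differ in the X-marginal when sharing is disabled", {
  ens <- build_scheme_ensemble(1, 1, 1, seed = 9, share_x = FALSE)
  expect_gt(max(abs(sweep(ens[[1]]$x, 2, ens[[1]]$x[1, ]))), 0)
  expect_true(validate_scheme(ens[[1]]))
})

test_that("sampled outcome pairs follow the scheme's joint distribution", {
  sc <- make_fixture_schemes()$monotone_cond
  set.seed(401)
  out <- sample_outcomes(sc, "A", 100000)
  # degenerate-marginal sanity: X = ICH forced
  forced <- make_scheme(c(1, 0, 0), c(0.4, 0.25, 0.35))
  expect_true(all(sample_outcomes(forced, "A", 200)$x == "ICH"))
  # joint frequencies vs the product P[X] * P[Y|X] by brute-force tabulation
  joint_hat <- table(out$x, out$y) / nrow(out)
  joint <- sweep(sc$cond$A, 1, sc$x["A", ], "*")
  chisq <- 100000 * sum((joint_hat - joint)^2 / joint)
  expect_gt(stats::pchisq(chisq, df = 8, lower.tail = FALSE), 0.001)
  # marginal within 3 standard errors
  for (k in 1:3) {
    p <- sc$x["A", k]
    expect_lt(abs(mean(as.integer(out$x) == k) - p),
              3 * sqrt(p * (1 - p) / 100000))
  }
})

test_that("least-favorable-configuration marginals are laid out best-first", {
  xm <- lfc_x_marginals(c(0.36, 0.06), c(0.16, 0.06), c(0.16, 0.06))
  expect_equal(xm["A", ], c(ICH = 0.06, NEI = 0.58, MNI = 0.36))
  expect_equal(xm["B", ], xm["C", ])
  all_eq <- lfc_x_marginals(c(0.26, 0.06))
  expect_equal(all_eq["A", ], all_eq["C", ])
  edge <- lfc_x_marginals(c(0.9, 0.1))
  expect_equal(unname(edge["A", "NEI"]), 0)
  expect_error(lfc_x_marginals(c(0.8, 0.4)))
})

test_that("scheme JSON serialization round-trips exactly", {
  ens <- build_scheme_ensemble(2, 1, 1, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_schemes(ens, path)
  back <- read_schemes(path)
  expect_equal(back, ens, tolerance = 1e-12)
})
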