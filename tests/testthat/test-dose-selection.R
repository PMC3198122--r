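test_that("rapid responses score 2 / 1 / 0 for MNI / NEI / ICH", {
  expect_equal(unname(score_response(c("MNI", "NEI", "ICH"))), c(2L, 1L, 0L))
  expect_error(score_response("mni"), "unknown")
  expect_error(selection_config(scores = c(ICH = 1L, NEI = 1L, MNI = 2L)),
               "increasing")
  expect_error(selection_config(lead = 0))
})

test_that("deterministic per-set scores (2,1,0) eliminate at sets 3 and 6", {
  src <- function(i, active) {
    stats::setNames(c(A = "MNI", B = "NEI", C = "ICH")[active], active)
  }
  res <- run_selection(src)
  expect_equal(res$selected, "A")
  expect_equal(res$n_first_elim, 3L)
  expect_equal(res$n_final, 6L)
  expect_false(res$truncated)
  expect_equal(res$tnk_patients, 15L) # 3 sets of 3 + 3 sets of 2
})

test_that("simultaneous elimination of two tied minima selects immediately", {
  src <- function(i, active) {
    stats::setNames(c(A = "MNI", B = "ICH", C = "ICH")[active], active)
  }
  res <- run_selection(src)
  expect_equal(res$selected, "A")
  expect_equal(res$n_first_elim, 3L)
  expect_equal(res$n_final, 3L)
  expect_equal(res$tnk_patients, 9L)
})

test_that("permanent ties never eliminate and the procedure truncates", {
  src <- function(i, active) stats::setNames(rep("MNI", length(active)), active)
  res <- run_selection(src)
  expect_true(res$truncated)
  expect_true(is.na(res$selected))
  expect_equal(res$sets_observed, 150L)
  expect_setequal(res$survivors_at_truncation, c("A", "B", "C"))
  expect_equal(res$tnk_patients, 450L)
})

test_that("cascade re-applies the elimination predicate within one set", {
  # per-set scores building sums (10, 4, 3) at set 5: the third arm is
  # eliminated at the minimum, after which the second trails by the full lead
  seq_scores <- rbind(c(2, 1, 1), c(2, 1, 1), c(2, 1, 0), c(2, 1, 1),
                      c(2, 0, 0), c(2, 0, 0))
  lab <- c("ICH", "NEI", "MNI")
  src <- function(i, active) {
    stats::setNames(lab[seq_scores[i, match(active, c("A", "B", "C"))] + 1L],
                    active)
  }
  res <- run_selection(src)
  expect_equal(res$selected, "A")
  expect_equal(res$n_first_elim, 5L)
  expect_equal(res$n_final, 5L)
  # without cascading only the minimum-attaining arm goes at set 5
  res2 <- run_selection(src, selection_config(cascade = FALSE))
  expect_equal(res2$n_first_elim, 5L)
  expect_equal(res2$n_final, 6L)
})

test_that("stepwise advance matches a brute-force simulator on random score
           sequences", {
  set.seed(11)
  lab <- c("ICH", "NEI", "MNI")
  for (cascade in c(TRUE, FALSE)) {
    cfg <- selection_config(truncation_m = 40L, cascade = cascade)
    for (rep in 1:100) {
      scores <- matrix(sample(0:2, 40 * 3, replace = TRUE), 40, 3)
      src <- function(i, active) {
        stats::setNames(lab[scores[i, match(active, c("A", "B", "C"))] + 1L],
                        active)
      }
      mine <- run_selection(src, cfg)
      orac <- oracle_selection(scores, lead = 6L, m = 40L, cascade = cascade)
      expect_equal(mine$n_first_elim, orac$n1)
      expect_equal(mine$n_final, orac$nfin)
      if (!mine$truncated) {
        expect_equal(match(mine$selected, c("A", "B", "C")), orac$selected)
      } else {
        expect_setequal(match(mine$survivors_at_truncation, c("A", "B", "C")),
                        orac$survivors)
      }
    }
  }
})

test_that("outcomes for inactive arms and finished procedures are rejected", {
  st <- new_selection_state()
  st <- advance_one_set(st, c(A = "MNI", B = "MNI", C = "ICH"))
  st <- advance_one_set(st, c(A = "MNI", B = "MNI", C = "ICH"))
  st <- advance_one_set(st, c(A = "MNI", B = "MNI", C = "ICH"))
  expect_equal(st$active, c("A", "B"))
  expect_error(advance_one_set(st, c(A = "MNI", B = "MNI", C = "ICH")),
               "active arm")
})

test_that("patient accounting identity holds exactly for every replication", {
  xm <- lfc_x_marginals(c(0.31, 0.06), c(0.21, 0.06), c(0.21, 0.06))
  o <- estimate_selection_ocs(xm, 5000, seed = 21, return_reps = TRUE)
  d <- o$reps_detail
  m <- 150L
  min_n1 <- ifelse(d[, "n1"] == 0L, m, pmin(d[, "n1"], m))
  min_n <- ifelse(d[, "n"] == 0L, m, pmin(d[, "n"], m))
  expect_identical(d[, "t"], 2L * min_n + min_n1)
  # first elimination never later than final selection
  both <- d[, "n1"] > 0L & d[, "n"] > 0L
  expect_true(all(d[both, "n1"] <= d[both, "n"]))
  # cumulative-sum increments are bounded by the maximum score per set
  expect_true(all(d[, "t"] <= 3L * m))
})

test_that("R and C++ selection routes agree on one least favorable
           configuration", {
  xm <- lfc_x_marginals(c(0.36, 0.06), c(0.16, 0.06), c(0.16, 0.06))
  big <- estimate_selection_ocs(xm, 100000, seed = 31)
  set.seed(32)
  lab <- c("ICH", "NEI", "MNI")
  n_r <- 400
  res_r <- replicate(n_r, {
    src <- function(i, active) {
      x <- vapply(active, function(a) {
        findInterval(runif(1), cumsum(xm[a, ])[1:2]) + 1L
      }, integer(1))
      stats::setNames(lab[x], active)
    }
    r <- run_selection(src)
    c(cs = identical(r$selected, "A") && !r$truncated,
      n = if (is.na(r$n_final)) 150L else min(r$n_final, 150L))
  })
  p_hat <- mean(res_r["cs", ])
  se <- sqrt(p_hat * (1 - p_hat) / n_r)
  expect_lt(abs(p_hat - big$table[["p_cs"]]), 4 * se + 0.005)
  expect_lt(abs(mean(res_r["n", ]) - big$table[["e_min_n_m"]]),
            4 * stats::sd(res_r["n", ]) / sqrt(n_r))
})

test_that("selection probability of the best arm is monotone in its MNI
           probability", {
  p_cs <- vapply(c(0.28, 0.32, 0.36), function(p_mni) {
    xm <- lfc_x_marginals(c(p_mni, 0.06), c(0.16, 0.06), c(0.16, 0.06))
    estimate_selection_ocs(xm, 20000, seed = 41)$table[["p_cs"]]
  }, numeric(1))
  se <- sqrt(0.25 / 20000)
  expect_true(all(diff(p_cs) > -3 * sqrt(2) * se))
})
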