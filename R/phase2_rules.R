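#' Per-arm outcome summary at the end of phase II
#'
#' @param n_rapid Number of rapid responses observed on the arm.
#' @param ich_count Number of symptomatic ICHs among them.
#' @param n_rankin Number of clinical (trichotomized Rankin) outcomes.
#' @param poor_count,neither_count,good_count Counts per clinical category;
#'   must sum to `n_rankin`.
#' @return An object of class `arm_summary`.
#' @export
arm_summary <- function(n_rapid, ich_count, n_rankin, poor_count,
                        neither_count, good_count) {
  stopifnot(ich_count >= 0, ich_count <= n_rapid,
            poor_count + neither_count + good_count == n_rankin,
            n_rankin >= 0)
  structure(list(n_rapid = n_rapid, ich_count = ich_count,
                 n_rankin = n_rankin, poor_count = poor_count,
                 neither_count = neither_count, good_count = good_count),
            class = "arm_summary")
}

# Summarize sampled outcome pairs (as from sample_outcomes) into an arm_summary.
#' @rdname arm_summary
#' @param outcomes A data.frame with columns `x`, `y` as from
#'   [sample_outcomes()].
#' @export
summarize_arm <- function(outcomes) {
  arm_summary(
    n_rapid = nrow(outcomes),
    ich_count = sum(outcomes$x == "ICH"),
    n_rankin = nrow(outcomes),
    poor_count = sum(outcomes$y == "poor"),
    neither_count = sum(outcomes$y == "neither"),
    good_count = sum(outcomes$y == "good")
  )
}

#' Classify the relative safety scenario
#'
#' Partitions the difference in symptomatic ICH counts
#' `d = candidate - comparator` into the three safety scenarios: `d <= -2`
#' (candidate clearly safer) is Scenario 1, `|d| <= 1` (effectively the same)
#' is Scenario 2, and `d >= 2` (candidate clearly less safe) is Scenario 3.
#'
#' @param tnk,rtpa `arm_summary` objects for the candidate and comparator arm.
#' @param ich_threshold ICH-count difference defining "clearly" (default 2).
#' @return Integer scenario 1, 2 or 3.
#' @export
#' @examples
#' a <- arm_summary(100, 1, 100, 40, 25, 35)
#' b <- arm_summary(100, 3, 100, 40, 25, 35)
#' classify_scenario(a, b) # 1
classify_scenario <- function(tnk, rtpa, ich_threshold = 2L) {
  d <- tnk$ich_count - rtpa$ich_count
  if (d <= -ich_threshold) 1L else if (d >= ich_threshold) 3L else 2L
}

#' Assess clinical promise or futility of the candidate arm
#'
#' Applies the end-of-phase-II decision rules. Both co-primary endpoints
#' (poor and good clinical outcome) are first tested with the
#' continuity-corrected pooled z-test at the two-tailed interim level; a
#' significant *deficit* in good outcomes for the candidate makes further
#' study unpromising regardless of scenario, and any rejection in any
#' direction is recorded in `significant_endpoints` (used by the trial
#' simulator for type I error accounting). Otherwise the scenario rule on the
#' poor-outcome proportions decides: under Scenario 1 the candidate is
#' promising iff its poor proportion is less than or equal to the
#' comparator's; under Scenario 2 iff it is at least `poor_margin` (an
#' arithmetic difference, default 0.08) lower; under Scenario 3 further study
#' is always unpromising.
#'
#' @inheritParams classify_scenario
#' @param alpha_interim Two-tailed interim significance level (default 0.001).
#' @param poor_margin Required poor-outcome advantage under Scenario 2.
#' @return An object of class `phase2_decision`: `status` (`"promising"` or
#'   `"unpromising"`), `scenario`, `significant_endpoints` (character subset
#'   of `c("poor", "good")`), and the two `pooled_z_test` results.
#' @export
assess_promise <- function(tnk, rtpa, alpha_interim = 0.001,
                           poor_margin = 0.08, ich_threshold = 2L) {
  stopifnot(tnk$n_rankin > 0, rtpa$n_rankin > 0)
  test_poor <- pooled_z_cc(tnk$poor_count, tnk$n_rankin,
                           rtpa$poor_count, rtpa$n_rankin)
  test_good <- pooled_z_cc(tnk$good_count, tnk$n_rankin,
                           rtpa$good_count, rtpa$n_rankin)
  sig <- c("poor", "good")[c(test_poor$p_two_sided <= alpha_interim,
                             test_good$p_two_sided <= alpha_interim)]
  scenario <- classify_scenario(tnk, rtpa, ich_threshold)
  p_poor_tnk <- tnk$poor_count / tnk$n_rankin
  p_poor_rtpa <- rtpa$poor_count / rtpa$n_rankin
  good_deficit_sig <- test_good$p_two_sided <= alpha_interim &&
    test_good$direction < 0
  promising <- !good_deficit_sig && switch(scenario,
    p_poor_tnk <= p_poor_rtpa,                          # Scenario 1
    p_poor_rtpa - p_poor_tnk >= poor_margin - 1e-12,    # Scenario 2
    FALSE                                               # Scenario 3
  )
  structure(list(
    status = if (promising) "promising" else "unpromising",
    scenario = scenario,
    significant_endpoints = sig,
    test_poor = test_poor,
    test_good = test_good
  ), class = "phase2_decision")
}

#' Select a dose at truncation by the clinical decision criteria
#'
#' When the elimination procedure reaches the truncation point with two or
#' three surviving candidate arms, Criterion 1 keeps the survivors that are
#' promising by [assess_promise()]; if none survive, further study with any
#' dose is unpromising. Residual ties are broken successively by lowest ICH
#' rate (Criterion 2, on the rapid-response denominator), lowest poor-outcome
#' proportion (Criterion 3), highest good-outcome proportion (Criterion 4),
#' and finally a seeded uniform random choice.
#'
#' @param survivors Named list of `arm_summary` objects (names are arm
#'   labels).
#' @inheritParams assess_promise
#' @return A list with `selected` (arm label or `NA_character_`) and
#'   `decision` (the selected arm's `phase2_decision`, or an unpromising
#'   decision with `scenario = NA` when Criterion 1 eliminates every
#'   survivor).
#' @export
truncation_select <- function(survivors, rtpa, alpha_interim = 0.001,
                              poor_margin = 0.08, ich_threshold = 2L) {
  stopifnot(length(survivors) >= 1, !is.null(names(survivors)))
  decisions <- lapply(survivors, assess_promise, rtpa = rtpa,
                      alpha_interim = alpha_interim,
                      poor_margin = poor_margin, ich_threshold = ich_threshold)
  promising <- names(survivors)[vapply(decisions, function(d)
    d$status == "promising", logical(1))]
  if (length(promising) == 0L) {
    return(list(selected = NA_character_,
                decision = structure(list(status = "unpromising",
                                          scenario = NA_integer_,
                                          significant_endpoints = character()),
                                     class = "phase2_decision")))
  }
  pool <- promising
  keep_min <- function(pool, value) {
    v <- vapply(pool, value, numeric(1))
    pool[abs(v - min(v)) < 1e-12]
  }
  pool <- keep_min(pool, function(a)
    survivors[[a]]$ich_count / survivors[[a]]$n_rapid)            # Criterion 2
  if (length(pool) > 1L) {
    pool <- keep_min(pool, function(a)
      survivors[[a]]$poor_count / survivors[[a]]$n_rankin)        # Criterion 3
  }
  if (length(pool) > 1L) {
    pool <- keep_min(pool, function(a)
      -survivors[[a]]$good_count / survivors[[a]]$n_rankin)       # Criterion 4
  }
  selected <- if (length(pool) > 1L) pool[sample.int(length(pool), 1L)]
              else pool[1L]
  list(selected = selected, decision = decisions[[selected]])
}
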