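STAGE_LEVELS <- c("phase2_futility", "phase2_no_winner", "interim1",
                  "interim2", "interim3", "interim4", "terminal")

#' Estimate operating characteristics of the selection procedure
#'
#' Monte-Carlo estimation of the sequential elimination procedure's operating
#' characteristics for a given set of per-arm rapid-response marginals:
#' `P[cs]` (probability that the best dose -- by convention the first row --
#' is the sole survivor at or before the truncation point; correct selections
#' that a clinical rule might make at truncation time are *not* counted),
#' `E[min(N(1), m)]` and `E[min(N, m)]` (expected set index of first and
#' final elimination, truncated at `m`), the median and mode of the number of
#' matched sets, `E[T]` (expected candidate-arm patients randomized during
#' selection) and `P[no winner]` (probability of truncation).
#'
#' @param x_marginals 3 x 3 matrix of rapid-response marginals, one row per
#'   candidate arm (best dose first), as from [lfc_x_marginals()].
#' @param reps Number of replications.
#' @param config A [selection_config()].
#' @param seed Optional seed (reseeds the RNG via [derive_seed()]).
#' @param return_reps If `TRUE`, attach the per-replication matrix.
#' @return An object of class `selection_ocs`: `table` (named numeric of the
#'   operating characteristics plus `p_incorrect`), `per_arm` (selection
#'   probability per arm), `se` (Monte-Carlo standard errors for the
#'   probability rows), `reps`, and optionally `reps_detail`.
#' @export
#' @examples
#' xm <- lfc_x_marginals(c(0.36, 0.06), c(0.16, 0.06), c(0.16, 0.06))
#' estimate_selection_ocs(xm, reps = 2000, seed = 1)$table
estimate_selection_ocs <- function(x_marginals, reps,
                                   config = selection_config(), seed = NULL,
                                   return_reps = FALSE) {
  stopifnot(reps >= 1, is.matrix(x_marginals), nrow(x_marginals) == 3L)
  for (i in 1:3) prob_triple(x_marginals[i, ], X_LEVELS)
  if (!is.null(seed)) set.seed(derive_seed(seed, 0L, "selection"))
  m <- config$truncation_m
  sim <- cpp_selection_sim(unname(x_marginals), as.integer(reps), config$lead,
                           m, config$scores, config$cascade)
  colnames(sim) <- c("selected", "n1", "n", "truncated", "t")
  min_n1 <- ifelse(sim[, "n1"] == 0L, m, pmin(sim[, "n1"], m))
  min_n <- ifelse(sim[, "n"] == 0L, m, pmin(sim[, "n"], m))
  p_cs <- mean(sim[, "selected"] == 1L)
  p_nw <- mean(sim[, "truncated"] == 1L)
  non_trunc_n <- sim[sim[, "truncated"] == 0L, "n"]
  mode_n <- if (length(non_trunc_n)) {
    tab <- tabulate(non_trunc_n, nbins = m)
    which.max(tab)
  } else NA_integer_
  tab <- c(
    p_cs = p_cs,
    e_min_n1_m = mean(min_n1),
    e_min_n_m = mean(min_n),
    median_n = median(min_n),
    mode_n = as.numeric(mode_n),
    e_t = mean(sim[, "t"]),
    p_no_winner = p_nw,
    p_incorrect = 1 - p_cs - p_nw
  )
  per_arm <- vapply(1:3, function(a) mean(sim[, "selected"] == a), numeric(1))
  names(per_arm) <- c("A", "B", "C")
  out <- structure(list(
    table = tab,
    per_arm = per_arm,
    se = c(p_cs = sqrt(p_cs * (1 - p_cs) / reps),
           p_no_winner = sqrt(p_nw * (1 - p_nw) / reps)),
    reps = reps
  ), class = "selection_ocs")
  if (return_reps) out$reps_detail <- sim
  out
}

#' @export
print.selection_ocs <- function(x, ...) {
  cat("Selection operating characteristics (", x$reps, " replications)\n",
      sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' Group-sequential design configuration
#'
#' @param assessment_min_per_arm Minimum patients per continuing arm at the
#'   end-of-phase-II assessment (default 100; with the truncation point of 150
#'   sets the assessment happens at 100--150 per arm as dictated by selection
#'   timing).
#' @param interim_totals Cumulative two-arm totals (selected dose + comparator,
#'   including their phase II patients) triggering the later interim looks.
#' @param terminal_total Two-arm total at the terminal analysis (must be
#'   even; 1:1 allocation).
#' @param alpha_interim Two-tailed level of each per-endpoint interim test.
#' @param alpha_terminal Two-tailed per-endpoint level at the terminal
#'   analysis (Holm's first stage).
#' @param holm_overall Overall two-tailed level of the Holm step-down.
#' @return An object of class `gs_config`.
#' @export
gs_config <- function(assessment_min_per_arm = 100L,
                      interim_totals = c(500L, 1000L, 1500L),
                      terminal_total = 1908L, alpha_interim = 0.001,
                      alpha_terminal = 0.025, holm_overall = 0.05) {
  interim_totals <- as.integer(interim_totals)
  terminal_total <- as.integer(terminal_total)
  stopifnot(assessment_min_per_arm >= 1,
            all(diff(interim_totals) > 0),
            all(interim_totals < terminal_total),
            terminal_total %% 2L == 0L,
            alpha_interim > 0, alpha_interim < 1,
            alpha_terminal > 0, alpha_terminal < 1,
            holm_overall > 0, holm_overall < 1)
  structure(list(assessment_min_per_arm = as.integer(assessment_min_per_arm),
                 interim_totals = interim_totals,
                 terminal_total = terminal_total,
                 alpha_interim = alpha_interim,
                 alpha_terminal = alpha_terminal,
                 holm_overall = holm_overall),
            class = "gs_config")
}

# Build an arm_summary from a count row (n, ich, poor, neither, good).
.counts_to_summary <- function(cnt) {
  arm_summary(cnt[["n"]], cnt[["ich"]], cnt[["n"]], cnt[["poor"]],
              cnt[["neither"]], cnt[["good"]])
}

#' Simulate one complete trial (reference implementation)
#'
#' Runs a single replication of the whole design in pure R, built from the
#' module-level primitives ([run_selection()], [assess_promise()],
#' [truncation_select()], [pooled_z_cc()]): phase II sequential selection on
#' matched sets (the comparator arm enrolls one patient per set), top-up
#' enrollment to the assessment minimum, the end-of-phase-II assessment
#' (interim significance screen at `alpha_interim`, then the clinical
#' promise/futility rules), group-sequential phase III looks, and the
#' terminal analysis with per-endpoint tests at `alpha_terminal` plus the
#' Holm step-down for reporting. The vectorized counterpart used for
#' Monte-Carlo studies is [simulate_trials()]; the two are cross-checked in
#' the package tests.
#'
#' @param scheme A `tnk_scheme` (see [make_scheme()]).
#' @param sel_cfg A [selection_config()].
#' @param gs_cfg A [gs_config()].
#' @param design `"gs"` (full group-sequential design) or `"fss"`
#'   (fixed-sample-size variant: selection, then a single terminal analysis
#'   with no promise/futility examination and no interim looks; at truncation
#'   a surviving arm is chosen uniformly at random).
#' @param poor_margin,ich_threshold Clinical decision-rule parameters (see
#'   [assess_promise()]).
#' @return An object of class `trial_result`: `stop_stage` (factor),
#'   `selection` (the `selection_result`), `decision` (a `phase2_decision` or
#'   `NULL`), `rejections` (named integer, sign of the observed difference
#'   for each rejected endpoint, 0 otherwise), `holm_rejected` (endpoints
#'   rejected by the Holm procedure at the terminal analysis),
#'   `any_type1` (valid under null schemes), and the final per-arm counts.
#' @export
simulate_trial <- function(scheme, sel_cfg = selection_config(),
                           gs_cfg = gs_config(), design = c("gs", "fss"),
                           poor_margin = 0.08, ich_threshold = 2L) {
  design <- match.arg(design)
  stopifnot(inherits(scheme, "tnk_scheme"))
  counts <- matrix(0L, 4L, 5L,
                   dimnames = list(ARM_LEVELS,
                                   c("n", "ich", "poor", "neither", "good")))
  draw <- function(arm, k) {
    if (k <= 0) return(invisible(NULL))
    out <- sample_outcomes(scheme, arm, k)
    counts[arm, ] <<- counts[arm, ] +
      c(k, sum(out$x == "ICH"), sum(out$y == "poor"),
        sum(out$y == "neither"), sum(out$y == "good"))
    out
  }
  summ <- function(arm) .counts_to_summary(as.list(counts[arm, ]))
  test_pair <- function(sel) {
    list(poor = pooled_z_cc(counts[sel, "poor"], counts[sel, "n"],
                            counts["D", "poor"], counts["D", "n"]),
         good = pooled_z_cc(counts[sel, "good"], counts[sel, "n"],
                            counts["D", "good"], counts["D", "n"]))
  }

  # --- phase II selection ---
  src <- function(i, active) {
    xs <- vapply(active, function(a) as.character(draw(a, 1L)$x[1L]),
                 character(1))
    draw("D", 1L)
    stats::setNames(xs, active)
  }
  selres <- run_selection(src, sel_cfg)

  rej <- c(poor = 0L, good = 0L)
  stage <- NULL
  decision <- NULL
  holm_rejected <- character()
  sel <- selres$selected
  record <- function(tt, alpha) {
    if (tt$poor$p_two_sided <= alpha) rej["poor"] <<- as.integer(tt$poor$direction)
    if (tt$good$p_two_sided <= alpha) rej["good"] <<- as.integer(tt$good$direction)
  }

  if (design == "fss") {
    if (selres$truncated) {
      surv <- selres$survivors_at_truncation
      sel <- surv[sample.int(length(surv), 1L)]
    }
    half <- gs_cfg$terminal_total %/% 2L
    draw(sel, half - counts[sel, "n"])
    draw("D", half - counts["D", "n"])
    tt <- test_pair(sel)
    record(tt, gs_cfg$alpha_terminal)
    holm_idx <- holm_step_down(c(tt$poor$p_two_sided, tt$good$p_two_sided),
                               gs_cfg$holm_overall)
    holm_rejected <- c("poor", "good")[holm_idx]
    stage <- "terminal"
  } else {
    if (!selres$truncated) {
      draw(sel, gs_cfg$assessment_min_per_arm - counts[sel, "n"])
      draw("D", gs_cfg$assessment_min_per_arm - counts["D", "n"])
    } else {
      surv <- selres$survivors_at_truncation
      ts <- truncation_select(stats::setNames(lapply(surv, summ), surv),
                              summ("D"), gs_cfg$alpha_interim, poor_margin,
                              ich_threshold)
      decision <- ts$decision
      if (is.na(ts$selected)) {
        # no survivor promising: random dose tested once at the interim
        # level, then the trial stops
        sel <- surv[sample.int(length(surv), 1L)]
        record(test_pair(sel), gs_cfg$alpha_interim)
        stage <- "phase2_no_winner"
      } else {
        sel <- ts$selected
      }
    }
    if (is.null(stage)) {
      # --- first interim: significance screen, then promise/futility ---
      tt <- test_pair(sel)
      dec <- assess_promise(summ(sel), summ("D"), gs_cfg$alpha_interim,
                            poor_margin, ich_threshold)
      decision <- dec
      if (length(dec$significant_endpoints) > 0L) {
        record(tt, gs_cfg$alpha_interim)
        decision$status <- "stop_significant"
        stage <- "interim1"
      } else if (dec$status == "unpromising") {
        stage <- "phase2_futility"
      }
    }
    if (is.null(stage)) {
      for (k in seq_along(gs_cfg$interim_totals)) {
        half <- gs_cfg$interim_totals[k] %/% 2L
        draw(sel, half - counts[sel, "n"])
        draw("D", half - counts["D", "n"])
        tt <- test_pair(sel)
        if (tt$poor$p_two_sided <= gs_cfg$alpha_interim ||
            tt$good$p_two_sided <= gs_cfg$alpha_interim) {
          record(tt, gs_cfg$alpha_interim)
          stage <- paste0("interim", k + 1L)
          break
        }
      }
    }
    if (is.null(stage)) {
      half <- gs_cfg$terminal_total %/% 2L
      draw(sel, half - counts[sel, "n"])
      draw("D", half - counts["D", "n"])
      tt <- test_pair(sel)
      record(tt, gs_cfg$alpha_terminal)
      holm_idx <- holm_step_down(c(tt$poor$p_two_sided, tt$good$p_two_sided),
                                 gs_cfg$holm_overall)
      holm_rejected <- c("poor", "good")[holm_idx]
      stage <- "terminal"
    }
  }

  structure(list(
    stop_stage = factor(stage, levels = STAGE_LEVELS),
    selection = selres,
    selected = sel,
    decision = decision,
    rejections = rej,
    holm_rejected = holm_rejected,
    any_type1 = any(rej != 0L),
    counts = counts
  ), class = "trial_result")
}

#' Fixed-sample-size trial variant
#'
#' Convenience wrapper for [simulate_trial()] with `design = "fss"`: dose
#' selection as in the full design, a forced uniform random selection among
#' survivors at truncation, direct enrollment to the terminal sample size and
#' a single per-endpoint analysis at `alpha_terminal` -- no promise/futility
#' examination and no interim looks. Isolates the combined effect of dose
#' selection and the continuity correction.
#'
#' @inheritParams simulate_trial
#' @export
simulate_fss_trial <- function(scheme, sel_cfg = selection_config(),
                               gs_cfg = gs_config()) {
  simulate_trial(scheme, sel_cfg, gs_cfg, design = "fss")
}

#' Simulate many trial replications (vectorized)
#'
#' Batch counterpart of [simulate_trial()] with the inner loop in C++.
#'
#' @inheritParams simulate_trial
#' @param reps Number of replications.
#' @param seed Optional seed (reseeds the RNG via [derive_seed()]).
#' @return A `data.frame` with one row per replication: `stage` (factor),
#'   `rej_poor`, `rej_good` (sign of the observed difference when the
#'   endpoint rejected, else 0), `selected` (arm label), `truncated`,
#'   `n_per_arm` (per-arm sample size at stopping) and `any_type1`.
#' @export
simulate_trials <- function(scheme, reps, sel_cfg = selection_config(),
                            gs_cfg = gs_config(), design = c("gs", "fss"),
                            poor_margin = 0.08, ich_threshold = 2L,
                            seed = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(scheme, "tnk_scheme"), reps >= 1)
  if (!is.null(seed)) set.seed(derive_seed(seed, 0L, "trial"))
  cond <- do.call(rbind, scheme$cond[ARM_LEVELS])
  sim <- cpp_trial_sim(unname(scheme$x), unname(cond), as.integer(reps),
                       sel_cfg$lead, sel_cfg$truncation_m, sel_cfg$scores,
                       sel_cfg$cascade, gs_cfg$assessment_min_per_arm,
                       gs_cfg$interim_totals, gs_cfg$terminal_total,
                       gs_cfg$alpha_interim, gs_cfg$alpha_terminal,
                       poor_margin, as.integer(ich_threshold),
                       design == "fss")
  data.frame(
    stage = factor(STAGE_LEVELS[sim[, 1] + 1L], levels = STAGE_LEVELS),
    rej_poor = sim[, 2],
    rej_good = sim[, 3],
    selected = c("A", "B", "C")[sim[, 4]],
    truncated = sim[, 5] == 1L,
    n_per_arm = sim[, 6],
    any_type1 = sim[, 2] != 0L | sim[, 3] != 0L
  )
}

#' Estimate experiment-wise type I error rates over a scheme ensemble
#'
#' For each null distribution scheme, simulates `reps_per_scheme` complete
#' trials and records the fraction with a poor-endpoint rejection, a
#' good-endpoint rejection, either (the experiment-wise error), and each
#' signed tail (candidate observed better vs. worse). Rejection at any
#' interim look (at `alpha_interim`) or at the terminal analysis (at
#' `alpha_terminal`, the Holm first stage) counts as a type I error; futility
#' stops without significance contribute none. Descriptive statistics across
#' schemes are reported in the standard eight-column layout.
#'
#' Per-scheme replication blocks are independently seeded from the master
#' seed via [derive_seed()], so results are invariant to scheme order and
#' subsetting.
#'
#' @param schemes List of null `tnk_scheme` objects.
#' @param reps_per_scheme Replications per scheme.
#' @inheritParams simulate_trials
#' @param seed Master seed.
#' @return An object of class `type1_summary`: `per_scheme` (data frame of
#'   per-scheme rates), `summary` (3 x 8 matrix: rows poor/good/either,
#'   columns mean/median/maximum/minimum/lower quartile/upper quartile/
#'   range/std dev), `tails` (mean signed-tail rates), `design`, `reps` and
#'   `seed`.
#' @export
estimate_type1_errors <- function(schemes, reps_per_scheme,
                                  design = c("gs", "fss"),
                                  sel_cfg = selection_config(),
                                  gs_cfg = gs_config(), poor_margin = 0.08,
                                  ich_threshold = 2L, seed = 1L) {
  design <- match.arg(design)
  stopifnot(length(schemes) >= 1, reps_per_scheme >= 1)
  for (s in schemes) {
    if (!inherits(s, "tnk_scheme") || !isTRUE(s$is_null)) {
      stop("type I error estimation requires null schemes ",
           "(identical Y-marginal across arms)")
    }
  }
  rows <- lapply(seq_along(schemes), function(i) {
    set.seed(derive_seed(seed, i, "trial"))
    cond <- do.call(rbind, schemes[[i]]$cond[ARM_LEVELS])
    sim <- cpp_trial_sim(unname(schemes[[i]]$x), unname(cond),
                         as.integer(reps_per_scheme), sel_cfg$lead,
                         sel_cfg$truncation_m, sel_cfg$scores,
                         sel_cfg$cascade, gs_cfg$assessment_min_per_arm,
                         gs_cfg$interim_totals, gs_cfg$terminal_total,
                         gs_cfg$alpha_interim, gs_cfg$alpha_terminal,
                         poor_margin, as.integer(ich_threshold),
                         design == "fss")
    rejp <- sim[, 2]
    rejg <- sim[, 3]
    data.frame(
      scheme = i,
      rate_poor = mean(rejp != 0L),
      rate_good = mean(rejg != 0L),
      rate_either = mean(rejp != 0L | rejg != 0L),
      poor_better = mean(rejp == -1L),  # candidate's poor rate observed lower
      poor_worse = mean(rejp == 1L),
      good_better = mean(rejg == 1L),   # candidate's good rate observed higher
      good_worse = mean(rejg == -1L),
      p_futility = mean(sim[, 1] == 0L),
      p_no_winner = mean(sim[, 1] == 1L)
    )
  })
  per_scheme <- do.call(rbind, rows)
  stat_row <- function(v) {
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    c(mean = mean(v), median = median(v), maximum = max(v), minimum = min(v),
      lower_quartile = q[1], upper_quartile = q[2], range = max(v) - min(v),
      std_dev = sd(v))
  }
  summary <- rbind(poor = stat_row(per_scheme$rate_poor),
                   good = stat_row(per_scheme$rate_good),
                   either = stat_row(per_scheme$rate_either))
  tails <- c(poor_better = mean(per_scheme$poor_better),
             poor_worse = mean(per_scheme$poor_worse),
             good_better = mean(per_scheme$good_better),
             good_worse = mean(per_scheme$good_worse))
  structure(list(per_scheme = per_scheme, summary = summary, tails = tails,
                 design = design, reps = reps_per_scheme, seed = seed),
            class = "type1_summary")
}

#' @export
print.type1_summary <- function(x, ...) {
  cat("Type I error study (", x$design, " design): ", nrow(x$per_scheme),
      " schemes x ", x$reps, " replications\n", sep = "")
  print(round(x$summary, 4))
  cat("Mean signed-tail rates:\n")
  print(round(x$tails, 4))
  invisible(x)
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Trial stopped at stage:", as.character(x$stop_stage), "\n")
  cat("Selected arm:", x$selected, "\n")
  if (x$any_type1) {
    cat("Rejections:",
        paste(names(x$rejections)[x$rejections != 0], collapse = ", "), "\n")
  }
  invisible(x)
}
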