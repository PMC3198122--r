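#' Selection procedure configuration
#'
#' Parameters of the truncated sequential elimination procedure: an arm whose
#' cumulative rapid-response score falls a *lead* of points behind the current
#' leader is eliminated; if no single arm survives after `truncation_m`
#' matched sets the procedure is truncated and selection passes to the
#' clinical decision criteria.
#'
#' @param lead Required lead in score points (default 6).
#' @param truncation_m Truncation point in matched sets (default 150).
#' @param scores Named integer scores per rapid-response category; must be
#'   non-negative and strictly increasing in the category order
#'   ICH < NEI < MNI (default 0/1/2).
#' @param cascade If `TRUE` (default), re-apply the elimination predicate
#'   within a set until no further arm qualifies (so a state like cumulative
#'   sums (10, 4, 3) with lead 6 eliminates both trailing arms in one set).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(lead = 6L, truncation_m = 150L,
                             scores = c(ICH = 0L, NEI = 1L, MNI = 2L),
                             cascade = TRUE) {
  lead <- as.integer(lead)
  truncation_m <- as.integer(truncation_m)
  stopifnot(lead >= 1L, truncation_m >= 1L)
  scores <- scores[X_LEVELS]
  if (any(is.na(scores)) || any(scores < 0) ||
      !(scores["ICH"] < scores["NEI"] && scores["NEI"] < scores["MNI"])) {
    stop("scores must be non-negative and strictly increasing ICH < NEI < MNI")
  }
  structure(list(lead = lead, truncation_m = truncation_m,
                 scores = as.integer(scores), cascade = isTRUE(cascade)),
            class = "selection_config")
}

#' Score a rapid response
#'
#' Maps a rapid-response outcome to its cumulative-sum increment: 2 points
#' for major neurological improvement (MNI), 1 for neither (NEI), 0 for
#' symptomatic intracranial hemorrhage (ICH) under the default scores.
#'
#' @param x Character vector of rapid-response categories.
#' @param config A [selection_config()].
#' @return Integer score(s).
#' @export
#' @examples
#' score_response(c("MNI", "NEI", "ICH"))
score_response <- function(x, config = selection_config()) {
  i <- match(x, X_LEVELS)
  if (anyNA(i)) stop("unknown rapid-response category")
  config$scores[i]
}

#' Fresh selection state
#'
#' @inheritParams score_response
#' @param arms Candidate arms (default `A`, `B`, `C`).
#' @return An object of class `selection_state` holding the cumulative sums
#'   (eliminated arms keep their frozen tallies), the active arm set, the
#'   number of complete matched sets observed, and an elimination log.
#' @export
new_selection_state <- function(config = selection_config(),
                                arms = c("A", "B", "C")) {
  structure(list(
    cumsum = stats::setNames(integer(length(arms)), arms),
    active = arms,
    sets_observed = 0L,
    selected = NA_character_,
    n_first_elim = NA_integer_,
    n_final = NA_integer_,
    elimination_log = list()
  ), class = "selection_state")
}

# Apply the elimination predicate to a state after sums were updated: while
# the leader is >= lead points ahead of the trailing arm(s), all arms
# attaining the minimum are eliminated (once if cascade = FALSE).
.apply_elimination <- function(state, config) {
  repeat {
    if (length(state$active) < 2L) break
    s <- state$cumsum[state$active]
    gap <- max(s) - min(s)
    if (gap < config$lead) break
    losers <- names(s)[s == min(s)]
    state$active <- setdiff(state$active, losers)
    state$elimination_log[[length(state$elimination_log) + 1L]] <-
      list(set = state$sets_observed, eliminated = losers)
    if (is.na(state$n_first_elim)) state$n_first_elim <- state$sets_observed
    if (length(state$active) == 1L) {
      state$selected <- state$active
      state$n_final <- state$sets_observed
      break
    }
    if (!config$cascade) break
  }
  state
}

#' Advance the selection procedure by one matched set
#'
#' Enters the rapid responses of one matched set (one response per active
#' arm), increments the cumulative sums, and applies the elimination rule.
#' Elimination is checked only after complete matched sets.
#'
#' @param state A `selection_state`.
#' @param outcomes Named character vector of rapid-response categories, one
#'   per *active* arm.
#' @inheritParams score_response
#' @return The updated `selection_state`.
#' @export
#' @examples
#' st <- new_selection_state()
#' st <- advance_one_set(st, c(A = "MNI", B = "NEI", C = "ICH"))
#' st$cumsum
advance_one_set <- function(state, outcomes, config = selection_config()) {
  stopifnot(inherits(state, "selection_state"))
  if (!is.na(state$selected)) stop("selection already complete")
  if (!setequal(names(outcomes), state$active)) {
    stop("outcomes must supply exactly one response per active arm (",
         paste(state$active, collapse = ", "), ")")
  }
  inc <- score_response(outcomes[state$active], config)
  state$cumsum[state$active] <- state$cumsum[state$active] + inc
  state$sets_observed <- state$sets_observed + 1L
  .apply_elimination(state, config)
}

#' Run the sequential elimination procedure to completion
#'
#' Iterates [advance_one_set()] until a single arm survives or the truncation
#' point is reached. `outcome_source(set_index, active_arms)` must return a
#' named character vector of rapid responses for the active arms of that set.
#'
#' @param outcome_source Generator function of per-set outcomes.
#' @inheritParams score_response
#' @return An object of class `selection_result` with fields `selected` (arm
#'   label or `NA`), `n_first_elim` (set index of first elimination, `NA` if
#'   none), `n_final` (set index of final selection, `NA` if truncated),
#'   `truncated`, `survivors_at_truncation`, `tnk_patients` (candidate-arm
#'   patients randomized during selection), `sets_observed` and `cumsum`.
#'   Patient accounting satisfies
#'   `tnk_patients = 2 * min(n_final*, m) + min(n_first_elim*, m)` where the
#'   starred values substitute `m` when the corresponding elimination never
#'   occurred.
#' @export
#' @examples
#' # deterministic per-set scores (2, 1, 0): first elimination at set 3,
#' # selection of arm A at set 6, 15 candidate-arm patients
#' src <- function(i, active) {
#'   stats::setNames(c("MNI", "NEI", "ICH")[match(active, c("A", "B", "C"))], active)
#' }
#' run_selection(src)
run_selection <- function(outcome_source, config = selection_config()) {
  state <- new_selection_state(config)
  while (is.na(state$selected) && state$sets_observed < config$truncation_m) {
    outs <- outcome_source(state$sets_observed + 1L, state$active)
    state <- advance_one_set(state, outs, config)
  }
  selection_result_from_state(state, config)
}

# Package a finished (selected or truncated) state as a selection_result.
selection_result_from_state <- function(state, config) {
  m <- config$truncation_m
  truncated <- is.na(state$selected)
  min_n1 <- if (is.na(state$n_first_elim)) m else min(state$n_first_elim, m)
  min_n <- if (is.na(state$n_final)) m else min(state$n_final, m)
  structure(list(
    selected = state$selected,
    n_first_elim = state$n_first_elim,
    n_final = state$n_final,
    truncated = truncated,
    survivors_at_truncation = if (truncated) state$active else character(),
    tnk_patients = 2L * min_n + min_n1,
    sets_observed = state$sets_observed,
    cumsum = state$cumsum
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (x$truncated) {
    cat("Selection truncated at", x$sets_observed, "matched sets; survivors:",
        paste(x$survivors_at_truncation, collapse = ", "), "\n")
  } else {
    cat("Selected arm", x$selected, "at set", x$n_final,
        "(first elimination at set", paste0(x$n_first_elim, ")\n"))
  }
  cat("Candidate-arm patients randomized:", x$tnk_patients, "\n")
  invisible(x)
}
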