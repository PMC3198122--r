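#' Pooled two-proportion z-test with 1/2-continuity correction
#'
#' Two-sided z-test for the equality of two proportions using the pooled
#' variance estimate and the half-integer continuity correction
#' `z = (|p1 - p2| - (1/n1 + 1/n2)/2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))`.
#' The correction is clamped at zero when it exceeds the observed absolute
#' difference (so the corrected statistic can never change sign), and a
#' pooled proportion of exactly 0 or 1 (zero variance) yields `z = 0`,
#' `p = 1`, flagged degenerate. All arguments are vectorized.
#'
#' @param events1,n1 Event count and sample size in arm 1.
#' @param events2,n2 Event count and sample size in arm 2.
#' @return A list of class `pooled_z_test` with components `z` (non-negative),
#'   `p_two_sided`, `direction` (sign of the uncorrected `p1 - p2`) and
#'   `degenerate`. For vector input each component is a vector.
#' @export
#' @examples
#' pooled_z_cc(10, 100, 20, 100) # z approximately 1.7823
pooled_z_cc <- function(events1, n1, events2, n2) {
  stopifnot(all(n1 >= 1), all(n2 >= 1),
            all(events1 >= 0), all(events1 <= n1),
            all(events2 >= 0), all(events2 <= n2))
  p1 <- events1 / n1
  p2 <- events2 / n2
  pbar <- (events1 + events2) / (n1 + n2)
  inv <- 1 / n1 + 1 / n2
  degenerate <- pbar <= 0 | pbar >= 1
  z <- pmax(0, abs(p1 - p2) - 0.5 * inv) /
    sqrt(pmax(pbar * (1 - pbar), .Machine$double.xmin) * inv)
  z[degenerate] <- 0
  p <- 2 * pnorm(z, lower.tail = FALSE)
  p[degenerate] <- 1
  structure(list(z = z, p_two_sided = p, direction = sign(p1 - p2),
                 degenerate = degenerate),
            class = "pooled_z_test")
}

#' Holm step-down procedure for two hypotheses
#'
#' Compares the smaller of two p-values to `overall_alpha / 2`; if it rejects,
#' the larger is compared to `overall_alpha`. Controls the family-wise error
#' rate at `overall_alpha`.
#'
#' @param p_values Numeric vector of exactly two p-values in (0, 1].
#' @param overall_alpha Overall two-tailed level (default 0.05).
#' @return Integer vector of rejected hypothesis indices (possibly empty).
#' @export
#' @examples
#' holm_step_down(c(0.01, 0.04))        # both rejected
#' holm_step_down(c(0.03, 0.04))        # none
#' holm_step_down(c(0.02, 0.06))        # first only
holm_step_down <- function(p_values, overall_alpha = 0.05) {
  stopifnot(length(p_values) == 2L, all(p_values > 0), all(p_values <= 1),
            overall_alpha > 0, overall_alpha < 1)
  ord <- order(p_values)
  rejected <- integer(0)
  if (p_values[ord[1]] <= overall_alpha / 2) {
    rejected <- ord[1]
    if (p_values[ord[2]] <= overall_alpha) rejected <- c(rejected, ord[2])
  }
  sort(rejected)
}
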