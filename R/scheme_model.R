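#' @section Distribution schemes:
#' A *distribution scheme* specifies, for each of the four arms, the joint
#' distribution of the rapid response `X` (ICH < NEI < MNI) and the
#' trichotomized clinical outcome `Y` (poor < neither < good), factored as the
#' marginal of `X` times the conditional of `Y` given `X`. Null schemes share
#' one `Y`-marginal across all four arms.
#' @name scheme_model
NULL

.EPS_SUM <- 1e-12   # tolerance on probability triples summing to 1
.EPS_MARG <- 1e-10  # tolerance on the marginalization identity

#' Construct and validate a probability triple
#'
#' @param p Numeric vector of length 3, non-negative, summing to 1 within
#'   `1e-12`.
#' @param labels Category labels (default the rapid-response levels).
#' @return Named numeric vector of length 3.
#' @export
#' @examples
#' prob_triple(c(0.06, 0.68, 0.26))
prob_triple <- function(p, labels = X_LEVELS) {
  p <- as.numeric(p)
  if (length(p) != 3L) stop("a probability triple has exactly 3 components")
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > .EPS_SUM) stop("probability triple must sum to 1 (got ",
                                       format(sum(p), digits = 15), ")")
  names(p) <- labels
  p
}

#' Default sampling regions for scheme generation
#'
#' Clinically anchored bounds on the extreme categories: symptomatic ICH rates
#' near 6% are typical with thrombolysis (bounded here to \[0.01, 0.12\]),
#' pilot data put major neurological improvement between 16% and 36% (bounded
#' to \[0.05, 0.45\]); poor and good 3-month outcomes are bounded to broad
#' plausible ranges. All are config-overridable.
#'
#' @return A list with components `x` (bounds `ich`, `mni`) and `y`
#'   (bounds `poor`, `good`), each bound a length-2 numeric `c(lo, hi)`.
#' @export
default_regions <- function() {
  list(
    x = list(ich = c(0.01, 0.12), mni = c(0.05, 0.45)),
    y = list(poor = c(0.20, 0.60), good = c(0.15, 0.55))
  )
}

# Uniform draws from the flat 2-simplex, as n x 3 matrix (order statistics of
# two uniforms give the three spacings).
.runif_simplex <- function(n) {
  u1 <- runif(n)
  u2 <- runif(n)
  lo <- pmin(u1, u2)
  hi <- pmax(u1, u2)
  cbind(lo, hi - lo, 1 - hi, deparse.level = 0)
}

# Rejection sampler: uniform over the sub-simplex with box bounds on the first
# and third components. Degenerate (zero-width) bounds are handled exactly by
# conditioning rather than rejection, which would almost surely never accept.
.sample_region <- function(n, b1, b3, labels, max_tries = 100000L) {
  stopifnot(length(b1) == 2L, length(b3) == 2L, b1[1] <= b1[2], b3[1] <= b3[2])
  w1 <- b1[2] - b1[1]
  w3 <- b3[2] - b3[1]
  if (w1 == 0 && w3 == 0) {
    p <- c(b1[1], 1 - b1[1] - b3[1], b3[1])
    if (p[2] < 0) stop("degenerate region lies outside the simplex")
    return(matrix(rep(p, each = n), nrow = n, dimnames = list(NULL, labels)))
  }
  if (w1 == 0 || w3 == 0) {
    # one coordinate fixed: draw the free one uniformly on its feasible range
    fixed <- if (w1 == 0) b1[1] else b3[1]
    free_b <- if (w1 == 0) b3 else b1
    lo <- free_b[1]
    hi <- min(free_b[2], 1 - fixed)
    if (hi < lo) stop("region has zero admissible area")
    free <- runif(n, lo, hi)
    out <- if (w1 == 0) cbind(fixed, 1 - fixed - free, free)
           else cbind(free, 1 - free - fixed, fixed)
    colnames(out) <- labels
    return(out)
  }
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, labels))
  got <- 0L
  tries <- 0
  cap <- as.double(max_tries) * n # the cap is per requested draw
  while (got < n) {
    batch <- max(2L * (n - got), 64L)
    tries <- tries + batch
    if (tries > cap) {
      stop("region appears to have zero (or negligible) admissible area: ",
           tries, " rejections without filling ", n, " draws")
    }
    cand <- .runif_simplex(batch)
    keep <- cand[, 1] >= b1[1] & cand[, 1] <= b1[2] &
            cand[, 3] >= b3[1] & cand[, 3] <= b3[2]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) > 0L) {
      take <- min(nrow(cand), n - got)
      out[(got + 1L):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

#' Sample rapid-response marginal distributions
#'
#' Draws `count` marginal distributions of the rapid response `X`, uniform
#' over the part of the simplex whose ICH and MNI probabilities fall inside
#' the region bounds.
#'
#' @param count Number of triples to draw.
#' @param region List with elements `ich` and `mni`, each `c(lo, hi)` bounds.
#' @param max_tries Rejection cap before declaring the region empty.
#' @return A `count` x 3 matrix with columns `ICH`, `NEI`, `MNI`.
#' @export
#' @examples
#' set.seed(1)
#' sample_x_marginals(3)
sample_x_marginals <- function(count, region = default_regions()$x,
                               max_tries = 100000L) {
  stopifnot(count >= 1)
  .sample_region(count, region$ich, region$mni, X_LEVELS, max_tries)
}

#' Sample a clinical-outcome marginal distribution
#'
#' Draws marginal distributions of the trichotomized clinical outcome `Y`
#' uniformly over the admissible region. Under null usage one draw is shared
#' by all four arms.
#'
#' @param region List with elements `poor` and `good`, each `c(lo, hi)`.
#' @param count Number of triples (default 1).
#' @inheritParams sample_x_marginals
#' @return A `count` x 3 matrix with columns `poor`, `neither`, `good`.
#' @export
sample_y_marginal <- function(region = default_regions()$y, count = 1L,
                              max_tries = 100000L) {
  .sample_region(count, region$poor, region$good, Y_LEVELS, max_tries)
}

#' Sample a conditional matrix P\[Y | X\] under marginalization and
#' monotonicity constraints
#'
#' Draws the conditional rows for the extreme rapid-response categories from
#' the flat simplex restricted to the monotone ordering, solves the middle
#' (NEI) row from the marginalization identity
#' `sum_x P[X = x] P[Y | X = x] = P[Y]`, and accepts iff the solved row is a
#' valid probability triple in the monotone middle position. Monotonicity is
#' non-strict: the worst rapid-response category must have the largest
#' conditional probability of a poor clinical outcome and the smallest of a
#' good one, with ties allowed (so the independence matrix is admissible).
#'
#' The rejection loop is vectorized in batches; the cap counts candidate
#' pairs, not batches. A high default cap is needed because admissible
#' `Y`-marginals with a nearly empty middle category squeeze the solved
#' middle row into a sliver of the simplex.
#'
#' @param x_marg Rapid-response marginal (length-3, ICH/NEI/MNI order).
#' @param y_marg Clinical-outcome marginal (length-3, poor/neither/good order).
#' @param max_tries Attempt cap before declaring infeasibility.
#' @return A 3 x 3 matrix, rows indexed by `X` category, columns by `Y`
#'   category; row `x` is `P[Y | X = x]`.
#' @export
#' @examples
#' y <- c(0.40, 0.25, 0.35)
#' m <- sample_conditional(c(0.06, 0.64, 0.30), y)
#' drop(c(0.06, 0.64, 0.30) %*% m) # recovers y
sample_conditional <- function(x_marg, y_marg, max_tries = 1000000L) {
  x_marg <- prob_triple(x_marg, X_LEVELS)
  y_marg <- prob_triple(y_marg, Y_LEVELS)
  empty <- matrix(NA_real_, 3, 3, dimnames = list(X_LEVELS, Y_LEVELS))

  pos <- x_marg > 0
  if (sum(pos) <= 1L) {
    # at most one X category ever occurs: its conditional must equal the
    # Y-marginal; unreachable rows are set to the Y-marginal by convention
    out <- empty
    out[1, ] <- out[2, ] <- out[3, ] <- y_marg
    return(out)
  }

  pI <- x_marg[1]; pN <- x_marg[2]; pM <- x_marg[3]

  if (pI > 0 && pM > 0 && pN > 0) {
    # vectorized rejection in growing batches
    n_viol <- c(order = 0L, range = 0L, middle = 0L)
    tried <- 0L
    batch <- 256L
    while (tried < max_tries) {
      batch <- min(batch, max_tries - tried)
      tried <- tried + batch
      rI <- .runif_simplex(batch)
      rM <- .runif_simplex(batch)
      # outer ordering: poor decreasing in X, good increasing in X
      ok_ord <- rI[, 1] >= rM[, 1] & rI[, 3] <= rM[, 3]
      n_viol["order"] <- n_viol["order"] + sum(!ok_ord)
      rN <- (matrix(y_marg, batch, 3, byrow = TRUE) - pI * rI - pM * rM) / pN
      ok_rng <- ok_ord & rN[, 1] >= -.EPS_MARG & rN[, 1] <= 1 + .EPS_MARG &
        rN[, 2] >= -.EPS_MARG & rN[, 2] <= 1 + .EPS_MARG &
        rN[, 3] >= -.EPS_MARG & rN[, 3] <= 1 + .EPS_MARG
      n_viol["range"] <- n_viol["range"] + sum(ok_ord & !ok_rng)
      ok <- ok_rng & rI[, 1] >= rN[, 1] - .EPS_MARG &
        rN[, 1] >= rM[, 1] - .EPS_MARG &
        rI[, 3] <= rN[, 3] + .EPS_MARG & rN[, 3] <= rM[, 3] + .EPS_MARG
      n_viol["middle"] <- n_viol["middle"] + sum(ok_rng & !ok)
      hit <- which(ok)
      if (length(hit) > 0L) {
        i <- hit[1L]
        out <- rbind(rI[i, ], pmin(pmax(rN[i, ], 0), 1), rM[i, ],
                     deparse.level = 0)
        dimnames(out) <- list(X_LEVELS, Y_LEVELS)
        return(out)
      }
      batch <- min(batch * 4L, 65536L)
    }
    worst <- names(which.max(n_viol))
    stop("no feasible conditional matrix within ", max_tries, " attempts; ",
         "most frequent violation: ",
         c(order = "monotone ordering of extreme rows",
           range = "solved middle row outside [0, 1]",
           middle = "middle-row monotonicity")[worst])
  }

  # a zero component in the X-marginal: scalar loop (cheap cases)
  n_viol <- c(order = 0L, range = 0L, middle = 0L)
  for (t in seq_len(max_tries)) {
    if (pI > 0 && pM > 0) {
      # both extremes positive, middle category unreachable: the drawn rows
      # must already satisfy marginalization; middle row set by convention
      rI <- drop(.runif_simplex(1L))
      rM <- drop(.runif_simplex(1L))
      if (rI[1] < rM[1] || rI[3] > rM[3]) {
        n_viol["order"] <- n_viol["order"] + 1L
        next
      }
      if (max(abs(y_marg - pI * rI - pM * rM)) > .EPS_MARG) {
        n_viol["range"] <- n_viol["range"] + 1L
        next
      }
      rN <- y_marg
      if (rI[1] < rN[1] - .EPS_MARG || rN[1] < rM[1] - .EPS_MARG ||
          rI[3] > rN[3] + .EPS_MARG || rN[3] > rM[3] + .EPS_MARG) {
        n_viol["middle"] <- n_viol["middle"] + 1L
        next
      }
    } else {
      # one extreme category has probability zero: its row is set to the
      # Y-marginal (never sampled) and excluded from the solve
      free <- if (pI > 0) 1L else 3L      # the reachable extreme
      pF <- x_marg[free]
      rF <- drop(.runif_simplex(1L))
      rN <- (y_marg - pF * rF) / pN
      if (any(rN < -.EPS_MARG) || any(rN > 1 + .EPS_MARG)) {
        n_viol["range"] <- n_viol["range"] + 1L
        next
      }
      rN <- pmin(pmax(rN, 0), 1)
      ok <- if (free == 1L) {
        rF[1] >= rN[1] - .EPS_MARG && rF[3] <= rN[3] + .EPS_MARG
      } else {
        rN[1] >= rF[1] - .EPS_MARG && rN[3] <= rF[3] + .EPS_MARG
      }
      if (!ok) {
        n_viol["middle"] <- n_viol["middle"] + 1L
        next
      }
      if (free == 1L) { rI <- rF; rM <- y_marg } else { rM <- rF; rI <- y_marg }
    }
    out <- rbind(rI, rN, rM, deparse.level = 0)
    dimnames(out) <- list(X_LEVELS, Y_LEVELS)
    return(out)
  }
  worst <- names(which.max(n_viol))
  stop("no feasible conditional matrix within ", max_tries, " attempts; ",
       "most frequent violation: ", c(order = "monotone ordering of extreme rows",
                                      range = "solved middle row outside [0, 1]",
                                      middle = "middle-row monotonicity")[worst])
}

#' Assemble a distribution scheme
#'
#' @param x_marginal Either a length-3 triple shared by all arms, or a 4 x 3
#'   matrix of per-arm rapid-response marginals (rows `A`, `B`, `C`, `D`).
#' @param y_marginal Either a length-3 triple shared by all arms (null
#'   scheme), or a 4 x 3 matrix of per-arm clinical-outcome marginals.
#' @param conditional Optional list of per-arm 3 x 3 conditional matrices
#'   (names `A`..`D`). Default `NULL` uses the independence conditional (every
#'   row equals the arm's `Y`-marginal), which satisfies both constraints.
#' @param is_null Flag; defaults to `TRUE` when all arms share one
#'   `Y`-marginal.
#' @return An object of class `tnk_scheme` with components `x` (4 x 3 matrix),
#'   `y` (4 x 3 matrix), `cond` (list of four 3 x 3 matrices) and `is_null`.
#' @export
#' @examples
#' sc <- make_scheme(c(0.06, 0.68, 0.26), c(0.40, 0.25, 0.35))
#' validate_scheme(sc)
make_scheme <- function(x_marginal, y_marginal, conditional = NULL,
                        is_null = NULL) {
  expand <- function(m, labels) {
    if (is.matrix(m)) {
      stopifnot(nrow(m) == 4L, ncol(m) == 3L)
      m <- t(apply(m, 1L, prob_triple, labels = labels))
    } else {
      m <- matrix(rep(prob_triple(m, labels), each = 4L), nrow = 4L)
    }
    dimnames(m) <- list(ARM_LEVELS, labels)
    m
  }
  x <- expand(x_marginal, X_LEVELS)
  y <- expand(y_marginal, Y_LEVELS)
  if (is.null(conditional)) {
    conditional <- lapply(ARM_LEVELS, function(a) {
      matrix(rep(y[a, ], each = 3L), nrow = 3L,
             dimnames = list(X_LEVELS, Y_LEVELS))
    })
    names(conditional) <- ARM_LEVELS
  }
  stopifnot(is.list(conditional), length(conditional) == 4L)
  if (is.null(names(conditional))) names(conditional) <- ARM_LEVELS
  conditional <- conditional[ARM_LEVELS]
  if (is.null(is_null)) {
    is_null <- max(abs(sweep(y, 2L, y[1, ]))) < .EPS_MARG
  }
  structure(list(x = x, y = y, cond = conditional, is_null = is_null),
            class = "tnk_scheme")
}

#' Validate a distribution scheme's invariants
#'
#' Checks that every probability triple sums to one, that the marginalization
#' identity `P[X | T] %*% P[Y | X, T] = P[Y | T]` holds component-wise within
#' `1e-10` for every arm, that every conditional matrix satisfies the
#' (non-strict) clinical monotonicity constraint, and that a scheme flagged
#' null shares one `Y`-marginal across arms.
#'
#' @param scheme A `tnk_scheme`.
#' @param tol Tolerance for the marginalization identity.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_scheme <- function(scheme, tol = .EPS_MARG) {
  stopifnot(inherits(scheme, "tnk_scheme"))
  for (a in ARM_LEVELS) {
    prob_triple(scheme$x[a, ], X_LEVELS)
    prob_triple(scheme$y[a, ], Y_LEVELS)
    cm <- scheme$cond[[a]]
    for (i in 1:3) prob_triple(cm[i, ], Y_LEVELS)
    marg <- drop(scheme$x[a, ] %*% cm)
    if (max(abs(marg - scheme$y[a, ])) > tol) {
      stop("marginalization identity violated for arm ", a, " (max abs dev ",
           format(max(abs(marg - scheme$y[a, ])), digits = 3), ")")
    }
    # poor (col 1) non-increasing in X, good (col 3) non-decreasing in X
    if (cm[1, 1] < cm[2, 1] - tol || cm[2, 1] < cm[3, 1] - tol ||
        cm[1, 3] > cm[2, 3] + tol || cm[2, 3] > cm[3, 3] + tol) {
      stop("clinical monotonicity constraint violated for arm ", a)
    }
  }
  if (isTRUE(scheme$is_null) &&
      max(abs(sweep(scheme$y, 2L, scheme$y[1, ]))) > tol) {
    stop("scheme flagged null but Y-marginals differ across arms")
  }
  invisible(TRUE)
}

#' Generate an ensemble of null distribution schemes
#'
#' Draws `n_x` rapid-response marginals, for each `n_y` clinical-outcome
#' marginals (shared by all four arms: the null condition), and for each of
#' those pairs `n_cond` sets of per-arm conditional matrices satisfying the
#' marginalization and monotonicity constraints, yielding
#' `n_x * n_y * n_cond` null schemes.
#'
#' @param n_x,n_y,n_cond Factor counts (the reference study uses 10 each).
#' @param regions Sampling regions as from [default_regions()].
#' @param seed Optional master seed; when supplied the ensemble is a
#'   deterministic function of it.
#' @param share_x If `TRUE` (default) the four arms of a scheme share one
#'   rapid-response marginal; if `FALSE` each arm gets its own draw.
#'   Conditional matrices are always drawn per arm.
#' @param max_tries Attempt cap passed to [sample_conditional()].
#' @return List of `tnk_scheme` objects, all passing [validate_scheme()].
#' @export
#' @examples
#' ens <- build_scheme_ensemble(2, 2, 2, seed = 1)
#' length(ens)
build_scheme_ensemble <- function(n_x, n_y, n_cond,
                                  regions = default_regions(), seed = NULL,
                                  share_x = TRUE, max_tries = 1000000L) {
  stopifnot(n_x >= 1, n_y >= 1, n_cond >= 1)
  if (!is.null(seed)) set.seed(derive_seed(seed, 0L, "scheme-gen"))
  schemes <- vector("list", n_x * n_y * n_cond)
  k <- 0L
  for (i in seq_len(n_x)) {
    x <- if (share_x) {
      matrix(rep(sample_x_marginals(1L, regions$x), each = 4L), nrow = 4L,
             dimnames = list(ARM_LEVELS, X_LEVELS))
    } else {
      m <- sample_x_marginals(4L, regions$x)
      dimnames(m) <- list(ARM_LEVELS, X_LEVELS)
      m
    }
    for (j in seq_len(n_y)) {
      y <- drop(sample_y_marginal(regions$y))
      for (l in seq_len(n_cond)) {
        cond <- lapply(ARM_LEVELS, function(a) {
          sample_conditional(x[a, ], y, max_tries = max_tries)
        })
        names(cond) <- ARM_LEVELS
        k <- k + 1L
        schemes[[k]] <- make_scheme(x, y, cond, is_null = TRUE)
      }
    }
  }
  schemes
}

#' Sample patient outcome pairs from a scheme
#'
#' Generates i.i.d. pairs `(X, Y)` for one arm: `X` trinomial from the arm's
#' rapid-response marginal, then `Y` trinomial from the conditional row of the
#' realized `X`.
#'
#' @param scheme A `tnk_scheme`.
#' @param arm Arm label (`"A"`, `"B"`, `"C"` or `"D"`).
#' @param n Number of pairs.
#' @return A `data.frame` with ordered factor columns `x` and `y`.
#' @export
sample_outcomes <- function(scheme, arm, n) {
  stopifnot(inherits(scheme, "tnk_scheme"), arm %in% ARM_LEVELS, n >= 1)
  px <- scheme$x[arm, ]
  cm <- scheme$cond[[arm]]
  x <- findInterval(runif(n), cumsum(px)[1:2]) + 1L
  u <- runif(n)
  cum1 <- cm[, 1][x]
  cum2 <- (cm[, 1] + cm[, 2])[x]
  y <- 1L + (u >= cum1) + (u >= cum2)
  data.frame(
    x = factor(X_LEVELS[x], levels = X_LEVELS, ordered = TRUE),
    y = factor(Y_LEVELS[y], levels = Y_LEVELS, ordered = TRUE)
  )
}

#' Least-favorable-configuration rapid-response marginals
#'
#' Builds the per-arm rapid-response marginals for a selection scheme in which
#' one dose is superior (first listed arm) and the other two doses are given
#' explicitly, each arm specified as `c(pMNI, pICH)` with
#' `P[NEI] = 1 - pMNI - pICH`.
#'
#' @param best `c(pMNI, pICH)` for the best dose (assigned to arm `A`).
#' @param inferior1,inferior2 Same for the two inferior doses (arms `B`, `C`).
#' @return A 3 x 3 matrix of rapid-response marginals, rows `A`, `B`, `C`.
#' @export
#' @examples
#' lfc_x_marginals(c(0.36, 0.06), c(0.16, 0.06), c(0.16, 0.06))
lfc_x_marginals <- function(best, inferior1 = best, inferior2 = inferior1) {
  one <- function(p) {
    stopifnot(length(p) == 2L, all(p >= 0), sum(p) <= 1 + 1e-12)
    nei <- 1 - p[1] - p[2]
    if (nei < 0) nei <- 0 # guard against floating-point residue at the edge
    prob_triple(c(p[2], nei, p[1]), X_LEVELS)
  }
  out <- rbind(A = one(best), B = one(inferior1), C = one(inferior2))
  colnames(out) <- X_LEVELS
  out
}

#' @export
print.tnk_scheme <- function(x, ...) {
  cat("Distribution scheme (", if (isTRUE(x$is_null)) "null" else "non-null",
      ")\n", sep = "")
  cat("Rapid-response marginals P[X | T]:\n")
  print(round(x$x, 4))
  cat("Clinical-outcome marginals P[Y | T]:\n")
  print(round(x$y, 4))
  invisible(x)
}

#' Write / read scheme ensembles as JSON
#'
#' Schemes serialize to nested lists keyed by arm label with probabilities as
#' decimals; round-tripping preserves every value to full double precision.
#'
#' @param schemes List of `tnk_scheme` objects.
#' @param path File path.
#' @return `read_schemes` returns the list of schemes; `write_schemes` returns
#'   `path` invisibly.
#' @export
write_schemes <- function(schemes, path) {
  if (inherits(schemes, "tnk_scheme")) schemes <- list(schemes)
  payload <- lapply(schemes, function(s) {
    list(
      x_marginal = apply(s$x, 1L, as.list, simplify = FALSE),
      y_marginal = apply(s$y, 1L, as.list, simplify = FALSE),
      conditional = lapply(s$cond, function(m) apply(m, 1L, as.list,
                                                     simplify = FALSE)),
      is_null = isTRUE(s$is_null)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schemes
#' @export
read_schemes <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(s) {
    x <- do.call(rbind, lapply(s$x_marginal[ARM_LEVELS], function(r)
      unlist(r[X_LEVELS])))
    y <- do.call(rbind, lapply(s$y_marginal[ARM_LEVELS], function(r)
      unlist(r[Y_LEVELS])))
    rownames(x) <- rownames(y) <- ARM_LEVELS
    cond <- lapply(s$conditional[ARM_LEVELS], function(m) {
      cm <- do.call(rbind, lapply(m[X_LEVELS], function(r) unlist(r[Y_LEVELS])))
      rownames(cm) <- X_LEVELS
      cm
    })
    make_scheme(x, y, cond, is_null = isTRUE(s$is_null))
  })
}
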