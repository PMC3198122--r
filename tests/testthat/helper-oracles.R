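# Independent oracle implementations used to cross-check the package.
# These deliberately use different algorithms from the package code paths.

# Uniform draw from the flat 2-simplex via normalized exponential spacings
# (the package uses sorted-uniform spacings instead).
oracle_simplex <- function(n) {
  g <- matrix(-log(runif(3 * n)), n, 3)
  g / rowSums(g)
}

# Rejection sampler over a box-bounded sub-simplex built on oracle_simplex.
oracle_region <- function(n, b1, b3) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    cand <- oracle_simplex(4L * n)
    keep <- cand[, 1] >= b1[1] & cand[, 1] <= b1[2] &
      cand[, 3] >= b3[1] & cand[, 3] <= b3[2]
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Independent coding of the conditional-matrix acceptance test: propose
# (row_ICH, row_MNI) from the flat simplex, solve the NEI row from the
# marginalization identity, accept iff all three rows are valid and monotone.
# Returns the accepted (row_ICH, row_NEI, row_MNI) triples.
oracle_cond_draws <- function(x, y, n_prop) {
  rI <- oracle_simplex(n_prop)
  rM <- oracle_simplex(n_prop)
  rN <- (matrix(y, n_prop, 3, byrow = TRUE) - x[1] * rI - x[3] * rM) / x[2]
  ok <- rI[, 1] >= rM[, 1] & rI[, 3] <= rM[, 3] &
    rN[, 1] >= 0 & rN[, 1] <= 1 & rN[, 2] >= 0 & rN[, 2] <= 1 &
    rN[, 3] >= 0 & rN[, 3] <= 1 &
    rI[, 1] >= rN[, 1] & rN[, 1] >= rM[, 1] &
    rI[, 3] <= rN[, 3] & rN[, 3] <= rM[, 3]
  list(rI = rI[ok, , drop = FALSE], rN = rN[ok, , drop = FALSE],
       rM = rM[ok, , drop = FALSE], rate = mean(ok))
}

# Brute-force fixpoint of the elimination predicate on a vector of cumulative
# sums: repeatedly remove all active minima while the lead criterion is met.
oracle_eliminate <- function(cs, active, lead, cascade = TRUE) {
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    s <- cs[idx]
    if (max(s) - min(s) < lead) break
    active[idx[s == min(s)]] <- FALSE
    if (sum(active) == 1L) break
    if (!cascade) break
  }
  active
}

# Independent step-by-step simulator of the selection procedure from a fixed
# matrix of per-set scores (rows = sets, cols = arms). Returns first/final
# elimination sets, the selected arm index and survivor flags.
oracle_selection <- function(score_mat, lead, m, cascade = TRUE) {
  cs <- c(0L, 0L, 0L)
  active <- rep(TRUE, 3L)
  n1 <- NA_integer_
  nfin <- NA_integer_
  for (s in seq_len(min(nrow(score_mat), m))) {
    cs[active] <- cs[active] + score_mat[s, active]
    prev <- active
    active <- oracle_eliminate(cs, active, lead, cascade)
    if (any(prev & !active) && is.na(n1)) n1 <- s
    if (sum(active) == 1L) {
      nfin <- s
      break
    }
  }
  list(n1 = n1, nfin = nfin,
       selected = if (sum(active) == 1L) which(active) else NA_integer_,
       survivors = which(active))
}

# A null scheme with independence conditionals, shared across all arms.
null_independence_scheme <- function(x = c(0.06, 0.68, 0.26),
                                     y = c(0.40, 0.25, 0.35)) {
  make_scheme(x, y)
}
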