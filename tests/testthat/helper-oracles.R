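# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration for Viterbi, closed forms for the
# 2x2 matrix logarithm, and direct sampling for distributional checks.

# exhaustive maximum-probability path over all K^T state sequences
brute_force_viterbi <- function(logB, logA, logpi) {
  T_ <- nrow(logB); K <- ncol(logB)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    p <- grid[r, ]
    lp <- logpi[p[1L]] + logB[1L, p[1L]]
    if (T_ > 1L) for (t in 2:T_)
      lp <- lp + logA[p[t - 1L], p[t]] + logB[t, p[t]]
    if (lp > best) { best <- lp; best_path <- p }
  }
  unname(best_path)
}

# closed-form principal logarithm of a 2x2 stochastic matrix:
# P has eigenvalues 1 and lambda = 1 - p12 - p21, and
# logm(P) = log(lambda) / (lambda - 1) * (P - I)
logm_2x2_stochastic <- function(P) {
  lambda <- 1 - P[1, 2] - P[2, 1]
  stopifnot(lambda > 0)
  if (abs(lambda - 1) < 1e-14) return(matrix(0, 2, 2))
  log(lambda) / (lambda - 1) * (P - diag(2))
}

# matrix exponential by scaling-and-squaring of a Taylor series, accurate
# to machine precision for the small generators used here; independent of
# the eigendecomposition route used by the package
expm_taylor <- function(A, s = 12L, terms = 24L) {
  B <- A / 2^s
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(terms)) {
    term <- term %*% B / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# reduced-size two-state benchmark used where the full 75-trace dataset
# would be wasteful; same kinetics and noise, fewer/shorter traces
small_two_state <- function(seed, n_traces = 20, max_length = 120) {
  two_state_archetype(n_traces = n_traces, max_length = max_length, seed = seed)
}
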