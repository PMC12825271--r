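# Independent brute-force oracles, deliberately naive: plain double loops
# over the formulas, no shared code with the package internals.

gscf_brute <- function(W, A) {
  W <- as.matrix(W); A <- as.matrix(A)
  n <- nrow(W)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        den <- den + W[i, j]
        if (A[i, j] == 1) num <- num + W[i, j]
      }
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

rscf_brute <- function(W, A) {
  W <- as.matrix(W); A <- as.matrix(A)
  n <- nrow(W)
  out <- numeric(n)
  for (k in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      if (j != k) {
        den <- den + W[k, j]
        if (A[k, j] == 1) num <- num + W[k, j]
      }
    }
    out[k] <- if (den == 0) NA_real_ else num / den
  }
  out
}

# direct evaluation of the BH step-up formula
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# random symmetric nonnegative strength matrix with zero diagonal and a
# random same-hemisphere chain-ish adjacency, n regions
random_scf_instance <- function(n, sparsity = 0.3) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  vals <- stats::rexp(length(up)) * (stats::runif(length(up)) > sparsity)
  W[up] <- vals
  W <- W + t(W)
  A <- matrix(0L, n, n)
  Aup <- which(upper.tri(A))
  A[Aup] <- as.integer(stats::runif(length(Aup)) < 0.4)
  A <- A + t(A)
  diag(A) <- 0L
  list(W = W, A = A)
}

# tiny default ribbon + two-pair tractogram used by several test files
fixture_ribbon <- function(n = 5L) make_ribbon_parcellation(n)

fixture_tractogram <- function(ribbon, n_short = 60L, n_long = 40L, seed = 7L) {
  make_tractogram(
    ribbon,
    short_pairs = data.frame(region_i = 1L, region_j = 2L, count = n_short),
    long_pairs = data.frame(region_i = 1L, region_j = 3L, count = n_long),
    seed = seed
  )
}
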