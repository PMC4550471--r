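# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: plain dbinom sums, dense grids, and
# hand-coded step-up adjustment.

# three-component mixture log-likelihood via dbinom, term by term
oracle_loglik <- function(N, X, e, p) {
  keep <- N > 0
  N <- N[keep]; X <- X[keep]
  if (!length(N)) return(0)
  sum(log(p^2 * dbinom(X, N, 1 - e) + 2 * p * (1 - p) * dbinom(X, N, 0.5) +
            (1 - p)^2 * dbinom(X, N, e)))
}

# eLRT by dense grid over p (default step 1e-4), error rate at its null MLE
oracle_elrt <- function(N, X, step = 1e-4) {
  e <- sum(X) / sum(N)
  keep <- N > 0
  Nk <- N[keep]; Xk <- X[keep]
  be <- dbinom(Xk, Nk, e); bh <- dbinom(Xk, Nk, 0.5); bv <- dbinom(Xk, Nk, 1 - e)
  pg <- seq(0, 1, by = step)
  ll <- log(outer((1 - pg)^2, be) + outer(2 * pg * (1 - pg), bh) +
              outer(pg^2, bv))
  tot <- rowSums(ll)
  list(statistic = 2 * (max(tot) - tot[1]), maf_hat = pg[which.max(tot)])
}

# full LRT by exhaustive 2-D grid; the grid carries the near-boundary point
# e = 0.5- explicitly because sup_e l(e, 0) can sit at the open boundary
oracle_full_lrt <- function(N, X, e_step = 1e-3, p_step = 1e-3) {
  eg <- c(seq(0, 0.499, by = e_step), 0.5 - 1e-9)
  pg <- seq(0, 1, by = p_step)
  num <- -Inf; den <- -Inf
  for (e in eg) {
    keep <- N > 0
    be <- dbinom(X[keep], N[keep], e)
    bh <- dbinom(X[keep], N[keep], 0.5)
    bv <- dbinom(X[keep], N[keep], 1 - e)
    ll <- rowSums(log(outer((1 - pg)^2, be) + outer(2 * pg * (1 - pg), bh) +
                        outer(pg^2, bv)))
    num <- max(num, max(ll))
    den <- max(den, ll[1])
  }
  max(2 * (num - den), 0)
}

# hand-coded Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# brute-force Fmax: every distinct p-value threshold
oracle_fmax <- function(p, truth) {
  best <- 0
  for (t in unique(p)) {
    called <- p <= t
    tp <- sum(called & truth)
    prec <- tp / sum(called)
    rec <- tp / sum(truth)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    best <- max(best, f1)
  }
  best
}

# random small locus for property tests
random_locus <- function(n_max = 20, cov_max = 10) {
  n <- sample(2:n_max, 1)
  N <- rbinom(n, cov_max, 0.7)
  if (sum(N) == 0) N[1] <- 1L
  mode <- sample(1:3, 1)
  q <- switch(mode, 0.02, 0.5, runif(1))
  X <- rbinom(n, N, q)
  list(N = as.integer(N), X = as.integer(X))
}
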