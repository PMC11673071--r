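# Independent oracles used to cross-check the package's statistical paths.
# Each takes a deliberately different computational route from the
# implementation it checks.

# Mann-Whitney p-value by brute-force enumeration of every group split,
# computing U by direct pair counting (never via rank sums).
oracle_ranksum_p <- function(x, y, alternative) {
  pool <- c(x, y)
  nx <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(pool), nx)
  us <- apply(splits, 2, function(ix) u_of(pool[ix], pool[-ix]))
  eps <- 1e-9
  pg <- mean(us >= u_obs - eps)
  pl <- mean(us <= u_obs + eps)
  switch(alternative,
         greater = pg, less = pl,
         two_sided = min(1, 2 * min(pg, pl)))
}

# Literal Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  cur <- Inf
  for (i in m:1) {
    cur <- min(cur, ps[i] * m / i)
    adj[i] <- min(1, cur)
  }
  adj[order(o)]
}

# Upper-tail hypergeometric probability by direct (non-log) enumeration;
# only safe for small populations.
oracle_hyper_ge <- function(x, m, n, k) {
  hi <- min(m, k)
  if (x > hi) return(0)
  i <- max(x, k - n):hi
  sum(choose(m, i) * choose(n, k - i)) / choose(m + n, k)
}

# Monte-Carlo permutation estimate of P(X >= x): draw k-subsets of a labelled
# universe and count successes.
oracle_hyper_mc <- function(x, m, n, k, draws = 200000L) {
  hits <- vapply(seq_len(draws),
                 function(i) sum(sample.int(m + n, k) <= m) >= x,
                 logical(1))
  est <- mean(hits)
  list(p = est, se = sqrt(est * (1 - est) / draws))
}

# Small dense gem builder for unit tests.
make_gem <- function(values, layer = "raw_counts",
                     genes = sprintf("G%02d", seq_len(nrow(values))),
                     obs = sprintf("c%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, obs)
  gem(values, layer)
}

# Fresh scratch directory per test.
withr_like_tempdir <- function() {
  d <- tempfile("npvuln-test-")
  dir.create(d)
  d
}
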