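# Independent brute-force oracles, written directly from the textbook
# definitions and kept free of the package's implementation paths.

# Pearson r by explicit summation.
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# Kruskal-Wallis H from the explicit rank formula with tie correction.
brute_kw <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# Efron log partial likelihood for a single covariate.
brute_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    m <- length(D)
    eR <- sum(exp(beta * x[R]))
    eD <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (j in seq_len(m) - 1L) {
      ll <- ll - log(eR - (j / m) * eD)
    }
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood, refined to 1e-7.
brute_cox_beta <- function(time, status, x, lo = -10, hi = 10) {
  step <- (hi - lo) / 200
  repeat {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, brute_cox_loglik, 0, time = time, status = status, x = x)
    b <- grid[which.max(ll)]
    if (step < 1e-7) return(b)
    lo <- b - 2 * step; hi <- b + 2 * step
    step <- step / 10
  }
}

# Two-group log-rank chi-square from the O-E / hypergeometric-variance sums.
brute_logrank <- function(time, status, group) {
  group <- as.integer(factor(group)) - 1L  # 0/1
  OE <- 0; V <- 0
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    nt <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    dt <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & group == 1)
    OE <- OE + d1 - dt * n1 / nt
    if (nt > 1) V <- V + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  OE^2 / V
}

# Hypergeometric upper tail by summation of the pmf via choose().
brute_hyper <- function(k, n_draw, K, N) {
  js <- k:min(n_draw, K)
  sum(choose(K, js) * choose(N - K, n_draw - js)) / choose(N, n_draw)
}

# AUC by exhaustive pair enumeration (ties count one half).
brute_auc <- function(scores, status) {
  pos <- scores[status == 1]; neg <- scores[status == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up, written out.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
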