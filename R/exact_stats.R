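## Self-contained exact binomial machinery: Wilson score interval,
## Boschloo's exact unconditional test, and its power.

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form score interval without continuity correction. The interval is
#' centered at `(p + z^2/2n) / (1 + z^2/n)` and always contains the point
#' estimate `k/n`; at `k = 0` the lower bound is exactly 0 and at `k = n`
#' the upper bound is exactly 1.
#'
#' @param k number of successes (vectorized).
#' @param n number of trials (>= 1).
#' @param confidence confidence level, default 0.95.
#' @return data frame with columns `point`, `lo`, `hi`, `confidence`.
#' @examples
#' wilson_interval(48, 48)
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  data.frame(point = p, lo = pmax(0, center - half),
             hi = pmin(1, center + half), confidence = confidence)
}

#' One-sided Fisher exact p-value for two binomial samples
#'
#' Conditional hypergeometric tail probability of the observed 2x2 table.
#' For `direction = "p1_less"` this is `P(X1 <= k1)` given the margins
#' (evidence that group 1's success probability is lower); ties at the
#' observed count are included.
#'
#' @param k1,n1 successes and size of group 1.
#' @param k2,n2 successes and size of group 2 (the reference/baseline).
#' @param direction alternative hypothesis: `"p1_less"` or `"p1_greater"`.
#' @return p-value in (0, 1].
#' @export
fisher_p_one_sided <- function(k1, n1, k2, n2,
                               direction = c("p1_less", "p1_greater")) {
  direction <- match.arg(direction)
  if (direction == "p1_greater") return(fisher_p_one_sided(k2, n2, k1, n1))
  stats::phyper(k1, k1 + k2, n1 + n2 - k1 - k2, n1)
}

# H(s) = P(Fisher p <= fobs | X1 + X2 = s), which is hypergeometric and free
# of the nuisance probability: the key identity behind the fast evaluation.
boschloo_cond_prob <- function(fobs, n1, n2, tol = 1e-12) {
  s <- 0:(n1 + n2)
  x0 <- stats::qhyper(pmin(fobs, 1), s, n1 + n2 - s, n1)
  at_x0 <- stats::phyper(x0, s, n1 + n2 - s, n1)
  cc <- ifelse(at_x0 <= fobs + tol, x0, x0 - 1)
  stats::phyper(cc, s, n1 + n2 - s, n1)
}

#' Boschloo's exact unconditional one-sided test
#'
#' Uses the one-sided Fisher exact p-value of the observed table as test
#' statistic and maximizes, over the common nuisance success probability, the
#' probability (under two independent binomials) of a Fisher p-value at most
#' as extreme as observed:
#' `p = max_pi P( fisher(X1, X2) <= fisher(k1, k2) )`,
#' `X1 ~ Bin(n1, pi)`, `X2 ~ Bin(n2, pi)`. Uniformly at least as powerful as
#' Fisher's exact test. The maximization scans an equally spaced grid on
#' \[0, 1\] and then refines around the argmax with golden-section search.
#' Ties at the observed statistic are included (tolerance `1e-12`).
#'
#' @inheritParams fisher_p_one_sided
#' @param grid_size number of nuisance-grid points (default 1001).
#' @param refine logical; refine around the grid argmax with [stats::optimize()].
#' @return p-value in (0, 1].
#' @examples
#' boschloo_one_sided(2, 10, 9, 10)  # target proportion clearly lower
#' @export
boschloo_one_sided <- function(k1, n1, k2, n2,
                               direction = c("p1_less", "p1_greater"),
                               grid_size = 1001, refine = TRUE) {
  direction <- match.arg(direction)
  if (n1 < 1 || n2 < 1) stop("degenerate group sizes")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("counts out of range")
  if (direction == "p1_greater")
    return(boschloo_one_sided(k2, n2, k1, n1, "p1_less", grid_size, refine))
  fobs <- fisher_p_one_sided(k1, n1, k2, n2, "p1_less")
  if (fobs >= 1 - 1e-12) return(1)
  N <- n1 + n2
  s <- 0:N
  H <- boschloo_cond_prob(fobs, n1, n2)
  keep <- H > 0
  sv <- s[keep]; Hv <- H[keep]
  if (!length(sv)) return(min(1, max(fobs, .Machine$double.xmin)))
  f <- function(p) sum(stats::dbinom(sv, N, p) * Hv)
  grid <- seq(0, 1, length.out = grid_size)
  vals <- vapply(grid, f, 0)
  i <- which.max(vals)
  best <- vals[i]
  if (refine) {
    lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_size, i + 1)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
    best <- max(best, opt$objective)
  }
  min(1, max(best, .Machine$double.xmin))
}

# Boschloo p-value for every table of (n1+1) x (n2+1) outcomes, direction
# p1_less. Returns a matrix indexed [k1+1, k2+1]. Used for power/size work at
# small n: the p-value is a monotone function of the Fisher statistic, so it
# is enough to compute, for each distinct Fisher value t, max_pi P(F <= t).
boschloo_all_tables <- function(n1, n2, grid_size = 1001) {
  Fm <- outer(0:n1, 0:n2, function(a, b)
    stats::phyper(a, a + b, n1 + n2 - a - b, n1))
  fv <- as.vector(Fm)
  ord <- order(fv)
  x1 <- as.vector(row(Fm))[ord] - 1L
  x2 <- as.vector(col(Fm))[ord] - 1L
  fs <- fv[ord]
  grid <- seq(0, 1, length.out = grid_size)
  # cumulative probability of tables in Fisher order, per nuisance value
  cums <- vapply(grid, function(p)
    cumsum(stats::dbinom(x1, n1, p) * stats::dbinom(x2, n2, p)),
    numeric(length(fs)))
  maxcum <- apply(cums, 1, max)
  # ties share the probability of the whole tied block
  last_of_tie <- rev(!duplicated(rev(signif(fs, 12))))
  pB <- numeric(length(fs))
  block_val <- NA_real_
  for (i in rev(seq_along(fs))) {
    if (last_of_tie[i]) block_val <- maxcum[i]
    pB[i] <- block_val
  }
  out <- matrix(NA_real_, n1 + 1, n2 + 1)
  out[cbind(x1 + 1L, x2 + 1L)] <- pmin(pB, 1)
  out
}

#' Power (or size) of the one-sided Boschloo test
#'
#' Probability that [boschloo_one_sided()] rejects at level `alpha` when the
#' two groups have true success probabilities `p1` and `p2`
#' (`direction = "p1_less"` rejects for evidence that `p1 < p2`). With
#' `method = "enumerate"` the rejection region is built exactly over all
#' `(n1+1)(n2+1)` tables (practical for small groups); `"monte_carlo"` draws
#' tables from the two binomials and reports a standard error.
#'
#' At `p1 = p2` the result is the test's size, which exactness keeps at or
#' below `alpha`.
#'
#' @param n1,n2 group sizes.
#' @param p1,p2 true success probabilities.
#' @param alpha rejection level in (0, 1).
#' @param method `"enumerate"` or `"monte_carlo"`.
#' @param nsim Monte-Carlo replicates.
#' @param grid_size nuisance-grid size for the embedded tests.
#' @return list with `power`, `se` (`NA` for enumeration), `method`.
#' @export
boschloo_power <- function(n1, n2, p1, p2, alpha,
                           method = c("enumerate", "monte_carlo"),
                           nsim = 2000, grid_size = 1001) {
  method <- match.arg(method)
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, alpha > 0, alpha < 1)
  if (method == "enumerate") {
    pB <- boschloo_all_tables(n1, n2, grid_size)
    rej <- pB <= alpha
    w <- outer(stats::dbinom(0:n1, n1, p1), stats::dbinom(0:n2, n2, p2))
    list(power = sum(w[rej]), se = NA_real_, method = method)
  } else {
    k1 <- stats::rbinom(nsim, n1, p1)
    k2 <- stats::rbinom(nsim, n2, p2)
    rej <- mapply(function(a, b)
      boschloo_one_sided(a, n1, b, n2, grid_size = grid_size) <= alpha,
      k1, k2)
    p <- mean(rej)
    list(power = p, se = sqrt(p * (1 - p) / nsim), method = method)
  }
}
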