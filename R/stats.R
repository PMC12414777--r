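#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summing, over the hypergeometric null with the
#' observed margins fixed, the probabilities of all tables no more probable
#' than the observed one. The point estimate is the sample (cross-product)
#' odds ratio `ad/bc`; when a zero cell makes it 0 or infinite, a
#' Haldane-Anscombe companion estimate (0.5 added to every cell) is reported
#' alongside the sentinel.
#'
#' @param a,b,c_,d non-negative integer cell counts; rows are exposure, the
#'   first column is the outcome (`a` = exposed cases, `b` = exposed
#'   non-cases, `c_` = unexposed cases, `d` = unexposed non-cases).
#' @return list: `odds_ratio` (ad/bc, may be `0` or `Inf`),
#'   `odds_ratio_haldane`, `p_two_sided`, `table`.
#' @export
#' @examples
#' fisher_2x2(60, 16, 2551, 2219)$odds_ratio
fisher_2x2 <- function(a, b, c_, d) {
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  m <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("degenerate 2x2 table: a row or column margin is zero")
  }
  # margins: row1 = a+b draws from an urn with a+c successes out of N
  n1 <- a + b
  k <- a + c_
  N <- sum(cells)
  support <- max(0, n1 + k - N):min(n1, k)
  probs <- dhyper(support, k, N - k, n1)
  p_obs <- dhyper(a, k, N - k, n1)
  # tolerance guards against FP noise when comparing equal probabilities
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  if (a * d == 0 && b * c_ > 0) or <- 0
  list(
    odds_ratio = or,
    odds_ratio_haldane = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)),
    p_two_sided = min(1, p),
    table = m
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For small samples (both
#' groups of size 8 or fewer) the two-sided p-value is computed by exact
#' enumeration of all group assignments of the pooled values (ties handled
#' naturally); otherwise a tie-corrected normal approximation is used. The
#' two-sided p is `P(|U - n1*n2/2| >= |u_obs - n1*n2/2|)`, which for a
#' tie-free (symmetric) null equals the usual doubled tail.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_max largest per-group size for exact enumeration (default 8).
#' @return list: `U` (for the first sample), `p_two_sided`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1.2, 3.4, 2.2), c(4.5, 5.1, 3.9, 6.0))
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty")
  }
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      # all pooled values identical: no evidence against the null
      return(list(U = u_obs, p_two_sided = 1, method = "degenerate (all ties)"))
    }
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  list(U = u_obs, p_two_sided = min(1, p), method = method)
}
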