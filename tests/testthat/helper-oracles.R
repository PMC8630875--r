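# Independent oracles, deliberately naive implementations.

# Cox-de Boor recursion, one basis function at a time. Half-open intervals,
# right-closed at the global last knot.
deboor_one <- function(x, knots, m, degree) {
  if (degree == 0) {
    closed_right <- knots[m + 1] == knots[length(knots)]
    return(as.numeric(x >= knots[m] & (x < knots[m + 1] |
                                         (closed_right & x == knots[m + 1]))))
  }
  left_den <- knots[m + degree] - knots[m]
  right_den <- knots[m + degree + 1] - knots[m + 1]
  left <- if (left_den > 0) {
    (x - knots[m]) / left_den * deboor_one(x, knots, m, degree - 1)
  } else 0
  right <- if (right_den > 0) {
    (knots[m + degree + 1] - x) / right_den *
      deboor_one(x, knots, m + 1, degree - 1)
  } else 0
  left + right
}

# full design matrix via the recursion (d = length(knots) - degree - 1)
deboor_design <- function(x, knots, degree) {
  d <- length(knots) - degree - 1L
  vapply(seq_len(d), function(m) deboor_one(x, knots, m, degree),
         numeric(length(x)))
}

# hand-rolled Newton-Raphson for logistic regression (maximum likelihood)
newton_logistic <- function(X, y, tol = 1e-10, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    grad <- crossprod(X, y - p)
    H <- crossprod(X * W, X)
    step <- solve(H, grad)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# sort-based quantile with linear interpolation of order statistics (type 7)
quantile_sorted <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Monte-Carlo permutation p-value for independence in a 2-way table
perm_chi2_p <- function(x, y, n_perm = 2000) {
  stat <- function(a, b) {
    tab <- table(a, b)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  s0 <- stat(x, y)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (stat(x, sample(y)) >= s0 - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
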