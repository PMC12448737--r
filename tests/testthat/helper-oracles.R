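# Independent brute-force oracles used to check the implementation.
# Everything here is deliberately naive (loops, explicit accumulation) and
# shares no code with the package internals.

tiny_lem <- function(values, labels) {
  labeled_expression_matrix(as.matrix(values), labels)
}

# per-feature Fisher score by direct looping over classes
fisher_score_brute <- function(values, labels) {
  p <- ncol(values)
  classes <- sort(unique(labels))
  out <- numeric(p)
  for (i in seq_len(p)) {
    mu_all <- mean(values[, i])
    num <- 0; den <- 0
    for (cl in classes) {
      x <- values[labels == cl, i]
      q <- length(x)
      mu <- mean(x)
      sig2 <- sum((x - mu)^2) / q      # population variance
      num <- num + q * (mu - mu_all)^2
      den <- den + q * sig2
    }
    out[i] <- if (den > 0) num / den else if (num > 0) Inf else 0
  }
  out
}

# trace ratio by explicit outer-product accumulation of scatter matrices
trace_ratio_brute <- function(values, labels, subset) {
  z <- values[, subset, drop = FALSE]
  classes <- sort(unique(labels))
  r <- ncol(z)
  mu <- colMeans(z)
  Mb <- matrix(0, r, r); Mw <- matrix(0, r, r)
  for (cl in classes) {
    zc <- z[labels == cl, , drop = FALSE]
    mu_c <- colMeans(zc)
    Mb <- Mb + nrow(zc) * outer(mu_c - mu, mu_c - mu)
    for (j in seq_len(nrow(zc))) {
      d <- zc[j, ] - mu_c
      Mw <- Mw + outer(d, d)
    }
  }
  sum(diag(Mb)) / sum(diag(Mw))
}

# plug-in MI by direct summation over the contingency table (nats)
mi_brute <- function(a, b) {
  n <- length(a)
  ua <- sort(unique(a)); ub <- sort(unique(b))
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) {
      mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
    }
  }
  mi
}

# one exhaustive mRMR step: objective of every remaining candidate
mrmr_step_brute <- function(codes, y, selected, candidates) {
  vapply(candidates, function(j) {
    D <- mi_brute(codes[, j], y)
    R <- if (length(selected) == 0L) 0 else {
      mean(vapply(selected, function(s) mi_brute(codes[, j], codes[, s]),
                  numeric(1)))
    }
    D - R
  }, numeric(1))
}

# AUC by exhaustive case/control pair counting, ties worth one half
auc_paircount <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# chord-distance deflection oracle: explicit computation at every index
deflection_brute <- function(s) {
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  x1 <- x[1]; y1 <- y[1]; xn <- x[n]; yn <- y[n]
  d <- numeric(n)
  for (i in seq_len(n)) {
    # distance from point to the line through (x1,y1)-(xn,yn)
    d[i] <- abs((yn - y1) * x[i] - (xn - x1) * y[i] + xn * y1 - yn * x1) /
      sqrt((yn - y1)^2 + (xn - x1)^2)
  }
  d[c(1, n)] <- -Inf
  which.max(d)
}

# small planted-signal dataset for classifier tests
make_planted <- function(n, p, n_inf, delta, seed) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, seq_len(n_inf)] <- X[, seq_len(n_inf)] + delta * y
  list(X = X, y = y)
}
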