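# Independent oracles used across the test suite.  These deliberately use
# different algorithms than the package (proximal gradient instead of
# coordinate descent; exhaustive path enumeration instead of Dijkstra).

# Proximal-gradient (ISTA) solver for
#   min_{a0, b} -loglik(y | a0 + X b) + lambda * n * sum(|b|)
# with an unpenalized intercept.
ista_lasso_logistic <- function(y, X, lambda, max_iter = 200000, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  Xt <- cbind(1, X)
  L <- max(eigen(crossprod(Xt), only.values = TRUE)$values) / 4
  step <- 1 / L
  theta <- rep(0, p + 1)
  thr <- step * lambda * n
  for (it in seq_len(max_iter)) {
    eta <- drop(Xt %*% theta)
    grad <- drop(crossprod(Xt, plogis(eta) - y))
    new <- theta - step * grad
    # soft-threshold the slopes only
    new[-1] <- sign(new[-1]) * pmax(abs(new[-1]) - thr, 0)
    if (max(abs(new - theta)) < tol) { theta <- new; break }
    theta <- new
  }
  list(a0 = theta[1], beta = theta[-1])
}

# Exhaustive simple-path enumeration for small weighted graphs.
# Edge length = 1/|w|.  Returns distances, betweenness (fractional path
# counting) and both closeness variants.
brute_force_graph <- function(W, tol = 1e-9) {
  p <- nrow(W)
  len <- ifelse(W != 0, 1 / abs(W), Inf)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, total) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1L]] <<- list(path = path, len = total); return() }
      for (u in seq_len(p)) {
        if (is.finite(len[v, u]) && !(u %in% path))
          walk(c(path, u), total + len[v, u])
      }
    }
    walk(s, 0)
    out
  }
  d <- matrix(Inf, p, p); diag(d) <- 0
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      ps <- paths_between(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      dmin <- min(lens)
      d[s, t] <- d[t, s] <- dmin
      short <- ps[lens <= dmin + tol]
      nshort <- length(short)
      for (sp in short) {
        inner <- setdiff(sp$path, c(s, t))
        btw[inner] <- btw[inner] + 1 / nshort
      }
    }
  }
  clo_inv <- clo_harm <- numeric(p)
  for (i in seq_len(p)) {
    di <- d[i, -i]; reach <- is.finite(di)
    clo_inv[i] <- if (any(reach)) 1 / sum(di[reach]) else 0
    clo_harm[i] <- sum(1 / di[reach])
  }
  list(distances = d, betweenness = btw,
       closeness_inverse_sum = clo_inv, closeness_harmonic = clo_harm)
}

# Random sparse symmetric weight matrix with continuous weights (ties in
# shortest-path length have probability zero).
random_weight_matrix <- function(p, edge_prob = 0.5, signed = TRUE) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < edge_prob) {
        w <- runif(1, 0.2, 2)
        if (signed && runif(1) < 0.3) w <- -w
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  W
}

# Log-likelihood of a logistic model, for checking solver objectives.
logistic_loglik <- function(y, X, a0, beta) {
  eta <- a0 + drop(as.matrix(X) %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Non-degenerate binary matrix: resample until every column has both
# classes (used where a test needs a guaranteed-estimable dataset).
nondegenerate_binary <- function(n, p, prob = 0.3) {
  repeat {
    X <- matrix(rbinom(n * p, 1, prob), n, p)
    if (all(colSums(X) > 0) && all(colSums(X) < n)) return(X)
  }
}
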