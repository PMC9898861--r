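#' Phi correlation of edge presence
#'
#' Cross-tabulates the nonzero/zero status of the `p(p-1)/2` unique edges
#' of two networks on the same nodes and reports the phi coefficient
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` with the p-value of the
#' (uncorrected) chi-squared test on that 2 x 2 table.  If a margin is
#' zero (e.g. one network has no edges at all) phi is undefined and
#' reported as `NA` with an explanatory message.
#'
#' @param W1,W2 Symmetric weight matrices or `ising_network` objects with
#'   the same node set.
#' @return List: `phi`, `p.value`, `table` (2 x 2 counts), `note`.
#' @export
edge_presence_phi <- function(W1, W2) {
  W1 <- weights_of(W1); W2 <- weights_of(W2)
  if (!all(dim(W1) == dim(W2))) stop("networks must share a node set")
  ut <- upper.tri(W1)
  s1 <- factor(W1[ut] != 0, levels = c(TRUE, FALSE))
  s2 <- factor(W2[ut] != 0, levels = c(TRUE, FALSE))
  tab <- table(s1, s2)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  denom <- sqrt(prod(c(a + b, cc + d, a + cc, b + d)))
  if (denom == 0) {
    return(list(phi = NA_real_, p.value = NA_real_, table = tab,
                note = "a margin of the presence table is zero; phi undefined"))
  }
  phi <- (a * d - b * cc) / denom
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(phi = unname(phi), p.value = p, table = tab, note = NULL)
}

#' Spearman rank correlation
#'
#' Rho on average-ranked data (ties averaged), with the two-sided p-value
#' from the t approximation `t = rho * sqrt((n-2) / (1 - rho^2))` on
#' `n - 2` df.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return List: `rho`, `p.value`, `n`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p.value = NA_real_, n = n,
                note = "constant input; rank correlation undefined"))
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p.value = p, n = n)
}

#' Congruence of two estimated networks
#'
#' Edge-presence phi, Spearman rank correlation of edge weights, and
#' Spearman rank correlations of each centrality index between two
#' undirected networks on the same nodes.
#'
#' @param net1,net2 `ising_network` objects (or weight matrices).
#' @param indices Centrality indices to compare.
#' @param closeness_variant Passed to [centrality_table()].
#' @return List with components `phi`, `edge_weights`, and one rank
#'   correlation per centrality index.
#' @export
compare_networks <- function(net1, net2,
                             indices = c("strength", "closeness", "betweenness"),
                             closeness_variant = "inverse_sum") {
  W1 <- weights_of(net1); W2 <- weights_of(net2)
  ut <- upper.tri(W1)
  out <- list(phi = edge_presence_phi(W1, W2),
              edge_weights = rank_correlation(W1[ut], W2[ut]))
  c1 <- centrality_table(W1, indices = indices,
                         closeness_variant = closeness_variant)
  c2 <- centrality_table(W2, indices = indices,
                         closeness_variant = closeness_variant)
  for (idx in indices) {
    out[[idx]] <- rank_correlation(c1$value[c1$index == idx],
                                   c2$value[c2$index == idx])
  }
  out
}

#' Permutation invariance test for two networks
#'
#' Tests whether two samples of binary symptom data come from the same
#' network, via the maximum absolute edge-weight difference
#' `M = max |W1 - W2|` and the global strength difference
#' `S = |gs(W1) - gs(W2)|` of the re-estimated networks.  The null
#' distribution pools the two samples and either re-splits them into
#' groups of the original sizes (`paired = FALSE`, the standard
#' independent-groups test) or randomly swaps wave labels within person
#' (`paired = TRUE`, for two waves of the same people; requires equal
#' group sizes and aligned rows).  P-values use the
#' `(r + 1) / (n_perm + 1)` smoothing, so they are never exactly zero.
#'
#' @param data1,data2 Binary person x symptom matrices on the same node
#'   set.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param gamma,rule,nlambda,lambda_min_ratio Estimator settings passed to
#'   [estimate_ising()].
#' @param paired Use the within-person label-swapping null instead of
#'   independent re-splitting.
#' @return A `network_invariance` object: `M`, `S`, `p_M`, `p_S`, the
#'   permuted statistics, settings and seed.
#' @export
invariance_test <- function(data1, data2, n_perm = 1000L, seed = NULL,
                            gamma = 0.25, rule = "AND", nlambda = 100L,
                            lambda_min_ratio = 1e-3, paired = FALSE) {
  data1 <- as.matrix(data1); data2 <- as.matrix(data2)
  if (ncol(data1) != ncol(data2)) stop("networks must share a node set")
  if (paired && nrow(data1) != nrow(data2))
    stop("paired mode requires equal group sizes with aligned rows")
  if (!is.null(seed)) set.seed(seed)
  est <- function(d) suppressWarnings(
    estimate_ising(d, gamma = gamma, rule = rule, nlambda = nlambda,
                   lambda_min_ratio = lambda_min_ratio))
  stat <- function(d1, d2) {
    n1 <- est(d1); n2 <- est(d2)
    c(M = max(abs(n1$weights - n2$weights)),
      S = abs(global_strength(n1) - global_strength(n2)))
  }
  obs <- stat(data1, data2)
  n1 <- nrow(data1); n2 <- nrow(data2)
  pooled <- rbind(data1, data2)
  perm <- matrix(NA_real_, n_perm, 2, dimnames = list(NULL, c("M", "S")))
  for (b in seq_len(n_perm)) {
    if (paired) {
      swap <- stats::runif(n1) < 0.5
      d1 <- data1; d2 <- data2
      d1[swap, ] <- data2[swap, , drop = FALSE]
      d2[swap, ] <- data1[swap, , drop = FALSE]
    } else {
      idx <- sample.int(n1 + n2, n1)
      d1 <- pooled[idx, , drop = FALSE]
      d2 <- pooled[-idx, , drop = FALSE]
    }
    perm[b, ] <- stat(d1, d2)
  }
  structure(
    list(M = unname(obs["M"]), S = unname(obs["S"]),
         p_M = (sum(perm[, "M"] >= obs["M"]) + 1) / (n_perm + 1),
         p_S = (sum(perm[, "S"] >= obs["S"]) + 1) / (n_perm + 1),
         perm = perm, n_perm = n_perm, paired = paired, seed = seed,
         gamma = gamma, rule = rule),
    class = "network_invariance")
}

#' @export
print.network_invariance <- function(x, ...) {
  cat(sprintf("network invariance test (%s, %d permutations)\n",
              if (x$paired) "paired label swap" else "independent re-split",
              x$n_perm))
  cat(sprintf("  max edge difference M = %.3f, p = %.3f\n", x$M, x$p_M))
  cat(sprintf("  global strength difference S = %.3f, p = %.3f\n", x$S, x$p_S))
  invisible(x)
}
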