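# Uniform estimator interface for the bootstrap machinery.
#
# `estimator` is either "ising" (data = binary matrix), "clpn" (data =
# two-wave binary panel or list(w1, w2)), or a user function data -> fitted
# network.  Internally everything is reduced to:
#   fit(data)            -> network object
#   params(fit)          -> named numeric vector of edge parameters
#   centr(fit, index)    -> numeric vector of node centralities
resolve_estimator <- function(estimator, ...) {
  dots <- list(...)
  if (is.function(estimator)) {
    fit <- function(d) estimator(d)
  } else {
    estimator <- match.arg(estimator, c("ising", "clpn"))
    fit <- if (estimator == "ising") {
      function(d) do.call(estimate_ising, c(list(d), dots))
    } else {
      function(d) do.call(estimate_clpn, c(list(d), dots))
    }
  }
  list(fit = function(d) suppressWarnings(suppressMessages(fit(d))))
}

network_params <- function(net) {
  if (inherits(net, "ising_network")) {
    W <- net$weights
    p <- nrow(W)
    idx <- which(upper.tri(W), arr.ind = TRUE)
    stats::setNames(W[upper.tri(W)],
                    paste0(idx[, 1], "--", idx[, 2]))
  } else if (inherits(net, "clpn_network")) {
    B <- net$coefficients
    p <- nrow(B)
    idx <- expand.grid(from = seq_len(p), to = seq_len(p))
    stats::setNames(as.vector(B), paste0(idx$from, "->", idx$to))
  } else stop("unsupported network object")
}

network_centrality <- function(net, index, closeness_variant = "inverse_sum") {
  if (inherits(net, "ising_network")) {
    switch(index,
           strength = node_strength(net$weights),
           closeness = as.numeric(closeness_centrality(net$weights,
                                                       closeness_variant)),
           betweenness = betweenness_centrality(net$weights),
           stop("unknown centrality index: ", index))
  } else if (inherits(net, "clpn_network")) {
    s <- directed_strength(net$coefficients)
    switch(index,
           out_strength = s$out_strength,
           in_strength = s$in_strength,
           stop("unknown centrality index: ", index))
  } else stop("unsupported network object")
}

default_indices <- function(data, estimator) {
  if (is.character(estimator) && estimator == "clpn")
    c("out_strength", "in_strength")
  else c("strength", "closeness", "betweenness")
}

n_persons <- function(data) {
  if (inherits(data, "symptom_panel")) dim(data)[1]
  else if (is.list(data)) nrow(data$w1)
  else nrow(data)
}

subset_persons <- function(data, idx) {
  if (inherits(data, "symptom_panel")) {
    cov <- if (is.null(data$covariates)) NULL
           else data$covariates[idx, , drop = FALSE]
    symptom_panel(data$responses[idx, , , drop = FALSE], scale = data$scale,
                  items = data$items, covariates = cov)
  } else if (is.list(data) && !is.null(data$w1)) {
    list(w1 = data$w1[idx, , drop = FALSE], w2 = data$w2[idx, , drop = FALSE])
  } else {
    data[idx, , drop = FALSE]
  }
}

# Shared engine: B bootstrap (with replacement) refits, collecting edge
# parameters and centralities.
bootstrap_fits <- function(data, estimator, B, seed, indices,
                           closeness_variant = "inverse_sum", ...) {
  eng <- resolve_estimator(estimator, ...)
  n <- n_persons(data)
  full <- eng$fit(data)
  par0 <- network_params(full)
  if (!is.null(seed)) set.seed(seed)
  boot_par <- matrix(NA_real_, B, length(par0),
                     dimnames = list(NULL, names(par0)))
  boot_cent <- lapply(indices, function(i)
    matrix(NA_real_, B, length(network_centrality(full, i, closeness_variant))))
  names(boot_cent) <- indices
  n_degenerate <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- eng$fit(subset_persons(data, idx))
    if (any(fit$degenerate %||% FALSE)) n_degenerate <- n_degenerate + 1L
    boot_par[b, ] <- network_params(fit)
    for (i in indices)
      boot_cent[[i]][b, ] <- network_centrality(fit, i, closeness_variant)
  }
  list(full = full, sample_params = par0, boot_params = boot_par,
       boot_centralities = boot_cent, n_degenerate = n_degenerate)
}

#' Bootstrap confidence intervals for edge weights
#'
#' Nonparametric bootstrap: `B` resamples of persons with replacement,
#' re-estimating the network each time, with percentile confidence
#' intervals per edge parameter.  Resamples containing degenerate nodes
#' are kept (handled by the estimator's zero-edge policy) and counted, to
#' avoid biasing the bootstrap distribution.
#'
#' @param data Binary matrix (Ising) or two-wave panel (CLPN).
#' @param estimator `"ising"`, `"clpn"`, or a function `data -> network`.
#' @param B Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf Confidence level for the percentile interval.
#' @param ... Estimator settings (e.g. `gamma`, `nlambda`, `folds`).
#' @return An `edge_bootstrap` object: `sample` (point estimates),
#'   `lower`, `upper`, `boot` (B x n_params matrix), `n_degenerate`.
#' @export
bootstrap_edges <- function(data, estimator = "ising", B = 1000L,
                            seed = NULL, conf = 0.95, ...) {
  if (B < 2) warning("B < 2 gives a degenerate interval equal to the single resample")
  bf <- bootstrap_fits(data, estimator, B = max(B, 1L), seed = seed,
                       indices = character(0), ...)
  a <- (1 - conf) / 2
  structure(
    list(sample = bf$sample_params,
         lower = apply(bf$boot_params, 2, stats::quantile, probs = a),
         upper = apply(bf$boot_params, 2, stats::quantile, probs = 1 - a),
         boot = bf$boot_params, B = B, conf = conf,
         n_degenerate = bf$n_degenerate, seed = seed),
    class = "edge_bootstrap")
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat(sprintf("edge bootstrap: %d parameters, B = %d, %.0f%% percentile CIs\n",
              length(x$sample), x$B, 100 * x$conf))
  excl <- sum(x$lower > 0 | x$upper < 0)
  cat(sprintf("  %d interval(s) exclude zero; %d degenerate resample(s)\n",
              excl, x$n_degenerate))
  invisible(x)
}

#' Bootstrap difference tests for edges and centralities
#'
#' For every pair of edge parameters (and, per centrality index, every
#' pair of nodes), bootstraps the difference and declares it significant
#' when the `conf` percentile interval of the bootstrapped differences
#' excludes zero.  The resulting significance matrices are symmetric, and
#' a parameter compared with itself is never significant.
#'
#' @inheritParams bootstrap_edges
#' @param targets Which difference tests to run.
#' @param indices Centrality indices (defaults per estimator type).
#' @return A `difference_tests` object with logical matrices
#'   `edges` and `centralities[[index]]`.
#' @export
difference_tests <- function(data, estimator = "ising",
                             targets = c("edges", "centralities"),
                             B = 1000L, seed = NULL, conf = 0.95,
                             indices = NULL, ...) {
  targets <- match.arg(targets, several.ok = TRUE)
  if (is.null(indices)) indices <- default_indices(data, estimator)
  bf <- bootstrap_fits(data, estimator, B = B, seed = seed,
                       indices = if ("centralities" %in% targets) indices
                                 else character(0), ...)
  a <- (1 - conf) / 2
  sig_matrix <- function(boot) {
    m <- ncol(boot)
    sig <- matrix(FALSE, m, m, dimnames = list(colnames(boot), colnames(boot)))
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (j <= i) next
        d <- boot[, i] - boot[, j]
        ci <- stats::quantile(d, probs = c(a, 1 - a))
        sig[i, j] <- sig[j, i] <- ci[1] > 0 || ci[2] < 0
      }
    }
    sig
  }
  out <- list(B = B, conf = conf, seed = seed,
              n_degenerate = bf$n_degenerate)
  if ("edges" %in% targets) out$edges <- sig_matrix(bf$boot_params)
  if ("centralities" %in% targets)
    out$centralities <- lapply(bf$boot_centralities, sig_matrix)
  structure(out, class = "difference_tests")
}

#' Case-dropping correlation-stability coefficient
#'
#' For each drop proportion `q`, draws `B` subsamples *without*
#' replacement keeping `(1 - q) * n` persons, re-estimates the network,
#' and correlates the subset centralities with the full-sample
#' centralities.  The CS-coefficient per index is the largest `q` such
#' that at least `prob` of the `B` correlations reach `r_threshold`
#' (conventionally 0.70 with 95\% probability; CS of at least 0.50 is
#' considered good, at least 0.25 acceptable).  Undefined correlations
#' (constant subset centralities) count as below threshold.
#'
#' @inheritParams bootstrap_edges
#' @param indices Centrality indices to track.
#' @param proportions Grid of drop proportions.
#' @param r_threshold Correlation to retain.
#' @param prob Required probability of retaining `r_threshold`.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param closeness_variant Closeness definition used when tracking
#'   closeness centrality.
#' @return A `cs_result`: `cs` (named per index), `table` (long data frame
#'   of drop proportion x replicate correlations), `n_undefined`.
#' @export
case_dropping_cs <- function(data, estimator = "ising",
                             indices = NULL,
                             proportions = seq(0.1, 0.75, by = 0.05),
                             B = 1000L, seed = NULL, r_threshold = 0.70,
                             prob = 0.95, cor_method = "pearson",
                             closeness_variant = "inverse_sum", ...) {
  if (is.null(indices)) indices <- default_indices(data, estimator)
  eng <- resolve_estimator(estimator, ...)
  n <- n_persons(data)
  full <- eng$fit(data)
  full_cent <- lapply(indices, function(i)
    network_centrality(full, i, closeness_variant))
  names(full_cent) <- indices
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  n_undefined <- 0L
  for (q in proportions) {
    keep <- max(3L, round((1 - q) * n))
    for (b in seq_len(B)) {
      idx <- sample.int(n, keep, replace = FALSE)
      fit <- eng$fit(subset_persons(data, idx))
      for (i in indices) {
        sub <- network_centrality(fit, i, closeness_variant)
        r <- suppressWarnings(stats::cor(full_cent[[i]], sub,
                                         method = cor_method))
        if (is.na(r)) n_undefined <- n_undefined + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          proportion = q, replicate = b, index = i, cor = r)
      }
    }
  }
  tab <- do.call(rbind, rows)
  cs <- vapply(indices, function(i) {
    qs_ok <- vapply(proportions, function(q) {
      rs <- tab$cor[tab$index == i & tab$proportion == q]
      rs[is.na(rs)] <- -Inf
      mean(rs >= r_threshold) >= prob
    }, logical(1))
    if (any(qs_ok)) max(proportions[qs_ok]) else 0
  }, numeric(1))
  if (n_undefined > 0)
    message(sprintf("%d undefined subset correlation(s) counted as below threshold",
                    n_undefined))
  structure(
    list(cs = cs, table = tab, proportions = proportions, B = B,
         r_threshold = r_threshold, prob = prob, cor_method = cor_method,
         n_undefined = n_undefined, seed = seed),
    class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("correlation-stability coefficients (r >= %.2f with prob >= %.2f, B = %d):\n",
              x$r_threshold, x$prob, x$B))
  for (i in names(x$cs)) cat(sprintf("  %-14s CS = %.2f\n", i, x$cs[i]))
  invisible(x)
}

#' Recompute CS-coefficients from a stability table
#'
#' Applies a (possibly different) correlation threshold and probability to
#' an already computed case-dropping table; CS is non-increasing in both.
#'
#' @param x A `cs_result`.
#' @param r_threshold,prob New criteria.
#' @return Named numeric vector of CS-coefficients.
#' @export
cs_coefficient <- function(x, r_threshold = 0.70, prob = 0.95) {
  stopifnot(inherits(x, "cs_result"))
  idxs <- unique(x$table$index)
  vapply(idxs, function(i) {
    qs_ok <- vapply(x$proportions, function(q) {
      rs <- x$table$cor[x$table$index == i & x$table$proportion == q]
      rs[is.na(rs)] <- -Inf
      mean(rs >= r_threshold) >= prob
    }, logical(1))
    if (any(qs_ok)) max(x$proportions[qs_ok]) else 0
  }, numeric(1))
}
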