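#' Ising model parameters
#'
#' Thresholds (per-node log-odds) and a symmetric zero-diagonal coupling
#' matrix on the pairwise log-odds scale, for binary variables coded {0,1}.
#' With this coding the node-wise logistic regression coefficients of an
#' Ising model equal the couplings directly.
#'
#' @param thresholds Numeric length-p vector of node thresholds.
#' @param couplings Symmetric p x p numeric matrix with zero diagonal.
#' @return An `ising_parameters` object.
#' @export
ising_parameters <- function(thresholds, couplings) {
  couplings <- as.matrix(couplings)
  p <- length(thresholds)
  if (!all(dim(couplings) == p)) stop("couplings must be p x p")
  if (!isTRUE(all.equal(couplings, t(couplings), tolerance = 1e-10)))
    stop("couplings must be symmetric")
  if (any(diag(couplings) != 0)) stop("couplings must have zero diagonal")
  if (!all(is.finite(thresholds)) || !all(is.finite(couplings)))
    stop("parameters must be finite")
  structure(list(thresholds = as.numeric(thresholds), couplings = couplings),
            class = "ising_parameters")
}

#' Cross-lagged regression parameters
#'
#' Per-outcome logistic intercepts and a p x p coefficient matrix `B` in
#' which `B[j, k]` is the log-odds effect of wave-1 symptom `j` on wave-2
#' symptom `k`; the diagonal holds the autoregressive effects.
#'
#' @param intercepts Numeric length-p vector.
#' @param coefficients p x p numeric matrix.
#' @return A `crosslag_parameters` object; the nonzero pattern is stored as
#'   ground truth for recovery checks.
#' @export
crosslag_parameters <- function(intercepts, coefficients) {
  coefficients <- as.matrix(coefficients)
  p <- length(intercepts)
  if (!all(dim(coefficients) == p)) stop("coefficients must be p x p")
  if (!all(is.finite(intercepts)) || !all(is.finite(coefficients)))
    stop("parameters must be finite")
  structure(list(intercepts = as.numeric(intercepts),
                 coefficients = coefficients,
                 support = coefficients != 0),
            class = "crosslag_parameters")
}

#' Exact state probabilities of an Ising model
#'
#' Enumerates all `2^p` binary states and returns their normalized
#' probabilities, `P(x) propto exp(sum_i tau_i x_i + sum_{i<j} W_ij x_i x_j)`.
#' Serves as the exact oracle for the samplers; guarded at p <= 20.
#'
#' @param params An `ising_parameters` object.
#' @return List with `states` (2^p x p 0/1 matrix, first variable varying
#'   fastest) and `prob` (probabilities summing to 1).
#' @export
#' @examples
#' enumerate_ising(ising_parameters(c(0, 0), matrix(c(0, log(2), log(2), 0), 2)))
enumerate_ising <- function(params) {
  stopifnot(inherits(params, "ising_parameters"))
  p <- length(params$thresholds)
  if (p > 20) stop("exact enumeration is limited to p <= 20")
  states <- as.matrix(expand.grid(rep(list(0:1), p), KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- NULL
  storage.mode(states) <- "double"
  # x' W x / 2 gives sum_{i<j} W_ij x_i x_j for symmetric zero-diagonal W
  logw <- drop(states %*% params$thresholds) +
    rowSums((states %*% params$couplings) * states) / 2
  logw <- logw - max(logw)
  pr <- exp(logw)
  list(states = states, prob = pr / sum(pr))
}

# marginal P(x_i = 1) under the exact distribution
ising_marginals <- function(params) {
  en <- enumerate_ising(params)
  drop(crossprod(en$states, en$prob))
}

#' Sample from an Ising model
#'
#' Exact sampling from the enumerated state table for p <= 12 (or when
#' `method = "exact"`); single-chain Gibbs sampling with burn-in and
#' thinning otherwise.
#'
#' @param params An `ising_parameters` object.
#' @param n Number of samples.
#' @param seed Optional RNG seed for reproducibility.
#' @param method `"auto"`, `"exact"` or `"gibbs"`.
#' @param burnin Gibbs burn-in sweeps (full passes over the p variables).
#' @param thin Gibbs sweeps between recorded samples.
#' @return n x p binary matrix.
#' @export
sample_ising <- function(params, n, seed = NULL,
                         method = c("auto", "exact", "gibbs"),
                         burnin = 1000L, thin = 10L) {
  stopifnot(inherits(params, "ising_parameters"))
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  p <- length(params$thresholds)
  if (method == "auto") method <- if (p <= 12) "exact" else "gibbs"
  if (!is.null(seed)) set.seed(seed)
  if (method == "exact") {
    en <- enumerate_ising(params)
    idx <- sample.int(nrow(en$states), n, replace = TRUE, prob = en$prob)
    x <- en$states[idx, , drop = FALSE]
  } else {
    tau <- params$thresholds; W <- params$couplings
    cur <- stats::rbinom(p, 1, stats::plogis(tau))
    x <- matrix(0, n, p)
    sweep_once <- function(cur) {
      for (j in seq_len(p)) {
        pr <- stats::plogis(tau[j] + sum(W[, j] * cur))
        cur[j] <- stats::rbinom(1, 1, pr)
      }
      cur
    }
    for (s in seq_len(burnin)) cur <- sweep_once(cur)
    for (i in seq_len(n)) {
      for (s in seq_len(max(1L, thin))) cur <- sweep_once(cur)
      x[i, ] <- cur
    }
  }
  storage.mode(x) <- "integer"
  x
}

#' Generate a two-wave binary symptom panel
#'
#' Wave 1 is drawn from the Ising model; wave-2 symptom `k` is then drawn
#' independently given wave 1 as
#' `Bernoulli(plogis(alpha_k + sum_j B[j, k] * x_j^w1))` - exactly the
#' first-order process the cross-lagged panel network estimator assumes.
#'
#' @param ising An `ising_parameters` object (wave-1 distribution).
#' @param clpn A `crosslag_parameters` object (wave-1 to wave-2 transition).
#' @param n Number of persons.
#' @param seed Optional RNG seed.
#' @param ... Passed to [sample_ising()].
#' @return A binary two-wave `symptom_panel`.
#' @export
generate_two_wave <- function(ising, clpn, n, seed = NULL, ...) {
  stopifnot(inherits(ising, "ising_parameters"),
            inherits(clpn, "crosslag_parameters"))
  p <- length(ising$thresholds)
  if (length(clpn$intercepts) != p)
    stop("dimension mismatch between Ising and cross-lagged parameters")
  if (!is.null(seed)) set.seed(seed)
  w1 <- sample_ising(ising, n, seed = NULL, ...)
  eta <- matrix(clpn$intercepts, n, p, byrow = TRUE) + w1 %*% clpn$coefficients
  w2 <- matrix(stats::rbinom(n * p, 1, stats::plogis(eta)), n, p)
  symptom_panel(w1, w2, scale = "binary",
                items = if (p == 9) pgsi_items() else NULL)
}

# Solve thresholds so that exact Ising marginals hit the targets, by
# damped fixed-point iteration on the log-odds scale (couplings held fixed).
calibrate_thresholds <- function(couplings, target, max_iter = 100, tol = 1e-8) {
  tau <- stats::qlogis(target)
  for (it in seq_len(max_iter)) {
    m <- ising_marginals(ising_parameters(tau, couplings))
    step <- stats::qlogis(target) - stats::qlogis(m)
    tau <- tau + step
    if (max(abs(step)) < tol) break
  }
  tau
}

#' Built-in simulation scenarios
#'
#' Returns ground-truth parameters and a default sample size for one of
#' three study conditions:
#' \describe{
#'   \item{`pgsi`}{Nine PGSI-like symptoms at n = 335: thresholds calibrated
#'     (by exact enumeration) so each wave-1 marginal endorsement rate lies
#'     in the 2-8\% band typical of community gambling panels; a sparse
#'     positive coupling graph; and cross-lagged effects emanating from the
#'     "Tolerance" (2) and "Health problems" (6) nodes, plus autoregression.}
#'   \item{`null`}{Independent symptoms: zero couplings and zero
#'     cross-lagged matrix, 5\% marginals, n = 335.}
#'   \item{`strong`}{A chain coupling graph `W[i, i+1] = 2` with balanced
#'     marginals and large cross-lagged effects at n = 2000, for recovery
#'     checks.}
#' }
#'
#' @param name Scenario name.
#' @return List with `ising`, `clpn`, `n`, `name`.
#' @export
default_scenario <- function(name = c("pgsi", "null", "strong")) {
  name <- match.arg(name)
  p <- 9L
  if (name == "pgsi") {
    W <- matrix(0, p, p)
    edges <- rbind(c(1, 2), c(2, 3), c(3, 9), c(4, 8), c(5, 7),
                   c(6, 7), c(1, 9), c(2, 5), c(4, 5), c(7, 8))
    for (r in seq_len(nrow(edges))) {
      W[edges[r, 1], edges[r, 2]] <- 2.0
      W[edges[r, 2], edges[r, 1]] <- 2.0
    }
    W[7, 8] <- W[8, 7] <- 2.5
    target_w1 <- c(0.048, 0.057, 0.069, 0.027, 0.039, 0.033, 0.036, 0.027, 0.048)
    tau <- calibrate_thresholds(W, target_w1)
    B <- matrix(0, p, p)
    diag(B) <- 2.0
    B[2, c(5, 7, 8)] <- 2.0
    B[6, c(1, 3, 5, 7, 8)] <- 2.0
    alpha <- stats::qlogis(c(0.072, 0.060, 0.054, 0.054, 0.051,
                             0.054, 0.051, 0.063, 0.063)) - 0.15
    n <- 335L
  } else if (name == "null") {
    W <- matrix(0, p, p)
    tau <- rep(stats::qlogis(0.05), p)
    B <- matrix(0, p, p)
    alpha <- rep(stats::qlogis(0.05), p)
    n <- 335L
  } else {
    W <- matrix(0, p, p)
    for (i in seq_len(p - 1)) W[i, i + 1] <- W[i + 1, i] <- 2.0
    tau <- -0.5 * rowSums(W)           # keeps marginals near 1/2
    B <- matrix(0, p, p)
    diag(B) <- 2.0
    B[2, 5] <- 2.0
    B[6, 3] <- 2.0
    alpha <- rep(stats::qlogis(0.2), p)
    n <- 2000L
  }
  list(ising = ising_parameters(tau, W),
       clpn = crosslag_parameters(alpha, B),
       n = n, name = name)
}

#' Serialize scenario parameters to JSON
#'
#' @param scenario A list as returned by [default_scenario()].
#' @param path Output JSON path.
#' @export
write_scenario_json <- function(scenario, path) {
  jsonlite::write_json(
    list(name = scenario$name, n = scenario$n,
         thresholds = scenario$ising$thresholds,
         couplings = scenario$ising$couplings,
         intercepts = scenario$clpn$intercepts,
         coefficients = scenario$clpn$coefficients),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read scenario parameters from JSON
#'
#' @param path JSON path written by [write_scenario_json()].
#' @return List with `ising`, `clpn`, `n`, `name`.
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(ising = ising_parameters(x$thresholds, x$couplings),
       clpn = crosslag_parameters(x$intercepts, x$coefficients),
       n = x$n, name = x$name)
}
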