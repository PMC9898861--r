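#' L1-penalized logistic regression path
#'
#' Fits the full LASSO path for a binary outcome, minimizing
#' `-loglik(y | a + X b) + lambda * n * sum(|b|)` with an unpenalized
#' intercept.  The grid runs from `lambda_max` (the smallest penalty at
#' which every slope is zero, `max |x_j'(y - ybar)| / n`) down to
#' `lambda_min_ratio * lambda_max` on a log scale.  Solutions are computed
#' by coordinate descent via \pkg{glmnet}.
#'
#' @param y Binary 0/1 outcome with both classes present.
#' @param X Predictor matrix (binary predictors in the Ising application;
#'   not standardized by default so coefficients stay on the log-odds
#'   coupling scale).
#' @param lambda Optional explicit decreasing penalty sequence.
#' @param nlambda Grid length when `lambda` is `NULL`.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @param standardize Standardize predictors internally (coefficients are
#'   always returned on the input scale).
#' @return A `coef_path` object: `lambda`, `a0` (intercepts), `beta`
#'   (p x nlambda coefficient matrix), `loglik`, `df` (nonzero counts),
#'   `n`.
#' @export
lasso_logistic_path <- function(y, X, lambda = NULL, nlambda = 100L,
                                lambda_min_ratio = 1e-3,
                                standardize = FALSE) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y dimensions disagree")
  if (!all(y %in% 0:1)) stop("y must be binary 0/1")
  if (length(unique(y)) < 2)
    stop("outcome is all-0 or all-1; handle the degenerate node upstream")
  padded <- FALSE
  if (ncol(X) == 1L) {         # glmnet requires >= 2 columns
    X <- cbind(X, 0)
    padded <- TRUE
  }
  if (is.null(lambda)) {
    lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
    if (lambda_max <= 0) lambda_max <- 1e-3
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  }
  # rare symptoms routinely trip glmnet's small-class advisory; expected here
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", lambda = lambda,
                   standardize = standardize, thresh = 1e-12),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- as.matrix(fit$beta)
  a0 <- as.numeric(fit$a0)
  lam <- fit$lambda
  if (padded) beta <- beta[1, , drop = FALSE]
  eta <- sweep(X[, seq_len(nrow(beta)), drop = FALSE] %*% beta, 2, a0, "+")
  loglik <- colSums(y * eta - log1p(exp(eta)))
  structure(
    list(lambda = lam, a0 = a0, beta = unname(beta),
         loglik = unname(loglik), df = unname(colSums(beta != 0)), n = n),
    class = "coef_path")
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 * loglik + k * log(n) + 2 * gamma * k * log(p_neighbors)`,
#' where `k` counts nonzero slopes and `p_neighbors` is the number of
#' candidate predictors.  `gamma = 0` reduces to the BIC; larger values
#' favour sparser models.
#'
#' @param loglik Log-likelihood(s) of the fitted model(s).
#' @param k Nonzero coefficient count(s), `>= 0`.
#' @param n Sample size.
#' @param p_neighbors Number of candidate predictors.
#' @param gamma Sparsity hyperparameter, default 0.25.
#' @return EBIC score(s); lower is better.
#' @export
ebic <- function(loglik, k, n, p_neighbors, gamma = 0.25) {
  if (any(k < 0)) stop("k must be nonnegative")
  if (n < 1) stop("n must be positive")
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p_neighbors)
}

#' Fit one node of an Ising network
#'
#' Regresses the node on all remaining columns along the LASSO path and
#' selects the penalty minimizing the EBIC (`p_neighbors = p - 1`), with
#' ties broken toward the larger penalty, i.e. the sparser model.  A
#' degenerate node (all 0 or all 1) yields an all-zero coefficient vector
#' with a warning rather than an error, since low-prevalence symptom data
#' make such nodes likely at realistic sample sizes.
#'
#' @param data Binary person x symptom matrix.
#' @param node Column index of the node to fit.
#' @param gamma EBIC hyperparameter.
#' @param nlambda,lambda_min_ratio Path grid settings (see
#'   [lasso_logistic_path()]).
#' @return List: `intercept`, `coef` (length p, zero at `node`), `lambda`
#'   (selected penalty), `ebic` (score at the selection), `degenerate`.
#' @export
fit_elasso_node <- function(data, node, gamma = 0.25, nlambda = 100L,
                            lambda_min_ratio = 1e-3) {
  data <- as.matrix(data)
  p <- ncol(data)
  y <- data[, node]
  X <- data[, -node, drop = FALSE]
  coefs <- numeric(p)
  if (min(sum(y == 0), sum(y == 1)) < 2) {
    # constant or near-constant nodes cannot support a logistic fit
    warning(sprintf("node %d is degenerate (fewer than 2 observations in a class); returning zero coefficients",
                    node))
    return(list(intercept = stats::qlogis(max(min(mean(y), 1 - 1e-12), 1e-12)),
                coef = coefs,
                lambda = NA_real_, ebic = NA_real_, degenerate = TRUE))
  }
  path <- lasso_logistic_path(y, X, nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio)
  scores <- ebic(path$loglik, path$df, path$n, p_neighbors = p - 1,
                 gamma = gamma)
  # lambda is stored decreasing, so the first index attaining the minimum
  # is the sparsest (largest-penalty) minimizer
  best <- which(scores <= min(scores) + 1e-9)[1]
  coefs[-node] <- path$beta[, best]
  list(intercept = path$a0[best], coef = coefs, lambda = path$lambda[best],
       ebic = scores[best], degenerate = FALSE)
}

# Combine the p x p directed coefficient matrix D (row i = regression of
# node i on the others) into symmetric edge weights under the AND/OR rule.
assemble_weights <- function(D, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  p <- nrow(D)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      a <- D[i, j]; b <- D[j, i]
      w <- if (rule == "AND") {
        if (a != 0 && b != 0) (a + b) / 2 else 0
      } else {
        if (a != 0 && b != 0) (a + b) / 2
        else if (a != 0) a
        else if (b != 0) b
        else 0
      }
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}

#' Estimate a cross-sectional Ising network
#'
#' The eLasso procedure: each node is regressed on all others with
#' L1-penalized logistic regression, the penalty is chosen per node by the
#' EBIC (hyperparameter `gamma`), and the two directed coefficients of each
#' pair are combined into an undirected edge.  Under the AND rule an edge
#' is nonzero only if both directed coefficients are nonzero (the weight is
#' their arithmetic mean); under the OR rule one nonzero coefficient
#' suffices.
#'
#' @param data Binary person x symptom matrix (or a one-wave binary
#'   `symptom_panel`).
#' @param gamma EBIC hyperparameter, default 0.25.
#' @param rule Edge assembly rule, `"AND"` (default) or `"OR"`.
#' @param labels Node labels; defaults to column names.
#' @param nlambda,lambda_min_ratio Path grid settings.
#' @param wave Wave to use when `data` is a panel.
#' @return An `ising_network`: `weights` (symmetric, zero diagonal),
#'   `thresholds`, `directed` (the raw node-wise coefficients),
#'   `labels`, `gamma`, `rule`, `degenerate` (logical per node),
#'   `lambda_selected`.
#' @export
estimate_ising <- function(data, gamma = 0.25, rule = c("AND", "OR"),
                           labels = NULL, nlambda = 100L,
                           lambda_min_ratio = 1e-3, wave = 1L) {
  rule <- match.arg(rule)
  if (inherits(data, "symptom_panel")) {
    if (data$scale != "binary")
      stop("Ising estimation requires a binary panel; call dichotomize() first")
    data <- panel_wave(require_complete(data), wave)
  }
  data <- as.matrix(data)
  if (anyNA(data)) stop("data contains missing values; analysis requires complete cases")
  n <- nrow(data); p <- ncol(data)
  if (n < 3) stop("need at least 3 persons")
  if (is.null(labels)) labels <- colnames(data) %||% paste0("node", seq_len(p))
  D <- matrix(0, p, p)
  tau <- numeric(p)
  lam <- rep(NA_real_, p)
  degen <- logical(p)
  for (i in seq_len(p)) {
    fit <- fit_elasso_node(data, i, gamma = gamma, nlambda = nlambda,
                           lambda_min_ratio = lambda_min_ratio)
    D[i, ] <- fit$coef
    tau[i] <- fit$intercept
    lam[i] <- fit$lambda
    degen[i] <- fit$degenerate
  }
  W <- assemble_weights(D, rule)
  dimnames(W) <- list(labels, labels)
  structure(
    list(weights = W, thresholds = tau, directed = D, labels = labels,
         gamma = gamma, rule = rule, degenerate = degen,
         lambda_selected = lam, n = n),
    class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  p <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  tot <- p * (p - 1) / 2
  cat(sprintf("ising_network: %d nodes, %d/%d nonzero edges (%s rule, gamma = %g)\n",
              p, ne, tot, x$rule, x$gamma))
  if (any(x$degenerate))
    cat("  degenerate nodes:", paste(which(x$degenerate), collapse = ", "), "\n")
  invisible(x)
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over the unordered node pairs.
#'
#' @param W Symmetric weight matrix or an `ising_network`.
#' @return Scalar.
#' @export
global_strength <- function(W) {
  if (inherits(W, "ising_network")) W <- W$weights
  sum(abs(W[upper.tri(W)]))
}
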