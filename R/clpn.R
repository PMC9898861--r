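#' Cross-validated LASSO logistic regression with the 1SE rule
#'
#' Ten-fold cross-validation on the binomial deviance selects the penalty:
#' `lambda_min` minimizes the mean out-of-fold deviance, and `lambda_1se`
#' is the largest penalty whose mean deviance lies within one standard
#' error of that minimum - the sparsest model statistically
#' indistinguishable from the best one.  Folds are stratified on the
#' outcome (event counts balanced across folds to within one), which keeps
#' every fold estimable when events are rare; fold assignment is
#' reproducible under `seed`.  Predictors are standardized internally
#' during fitting and coefficients returned on the input scale.
#'
#' @param y Binary 0/1 outcome with both classes present.
#' @param X Predictor matrix.
#' @param folds Number of CV folds.
#' @param seed RNG seed for the fold assignment.
#' @param nlambda,lambda_min_ratio Penalty grid settings.
#' @return List: `lambda_min`, `lambda_1se`, `intercept` and `coef` at
#'   `lambda_1se`, `cvm`, `cvsd`, `lambda`, `nonzero_min`, `nonzero_1se`,
#'   `seed`.
#' @export
cv_lasso_logistic <- function(y, X, folds = 10L, seed = NULL,
                              nlambda = 100L, lambda_min_ratio = 1e-3) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y dimensions disagree")
  if (!all(y %in% 0:1)) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("outcome is all-0 or all-1")
  if (n < folds) stop("need at least as many observations as folds")
  n_event <- sum(y == 1)
  if (min(n_event, n - n_event) < 2)
    stop("fewer than 2 observations in one outcome class; ",
         "cross-validation cannot be stratified - reduce folds or pool data")
  if (!is.null(seed)) set.seed(seed)
  foldid <- integer(n)
  for (cls in 0:1) {     # balanced fold labels within each outcome class
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(X, y, family = "binomial",
                      type.measure = "deviance", foldid = foldid,
                      nlambda = nlambda,
                      lambda.min.ratio = lambda_min_ratio,
                      standardize = TRUE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co_1se <- as.numeric(stats::coef(cv, s = "lambda.1se"))
  co_min <- as.numeric(stats::coef(cv, s = "lambda.min"))
  list(lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
       intercept = co_1se[1], coef = co_1se[-1],
       nonzero_min = sum(co_min[-1] != 0),
       nonzero_1se = sum(co_1se[-1] != 0),
       cvm = cv$cvm, cvsd = cv$cvsd, lambda = cv$lambda, seed = seed)
}

#' Estimate a cross-lagged panel network
#'
#' One LASSO logistic regression per wave-2 symptom, with all wave-1
#' symptoms (including the symptom's own wave-1 value) as predictors and
#' the penalty chosen by ten-fold cross-validated deviance with the 1SE
#' rule.  The selected coefficients form the directed matrix
#' `B[j, k]` = effect of wave-1 symptom `j` on wave-2 symptom `k`; the
#' diagonal holds the autoregressive effects.  A degenerate wave-2 outcome
#' (all 0 or all 1) yields an all-zero column, flagged in the result.
#'
#' @param panel A complete two-wave binary `symptom_panel`, or a list with
#'   elements `w1` and `w2` (binary matrices).
#' @param folds CV folds.
#' @param seed Master seed; per-outcome fold seeds are derived from it.
#' @param labels Node labels.
#' @param nlambda,lambda_min_ratio Penalty grid settings.
#' @return A `clpn_network`: `coefficients` (p x p), `intercepts`,
#'   `lambda_min`, `lambda_1se` (per outcome), `degenerate`, `labels`,
#'   `folds`, `seed`.
#' @export
estimate_clpn <- function(panel, folds = 10L, seed = NULL, labels = NULL,
                          nlambda = 100L, lambda_min_ratio = 1e-3) {
  if (inherits(panel, "symptom_panel")) {
    if (panel$scale != "binary")
      stop("CLPN estimation requires a binary panel; call dichotomize() first")
    if (dim(panel)[3] < 2) stop("CLPN estimation needs two waves")
    panel <- require_complete(panel)
    w1 <- panel_wave(panel, 1); w2 <- panel_wave(panel, 2)
    if (is.null(labels)) labels <- panel$items
  } else {
    w1 <- as.matrix(panel$w1); w2 <- as.matrix(panel$w2)
  }
  if (anyNA(w1) || anyNA(w2)) stop("analysis requires complete cases")
  p <- ncol(w1)
  if (is.null(labels)) labels <- colnames(w1) %||% paste0("node", seq_len(p))
  B <- matrix(0, p, p, dimnames = list(labels, labels))
  alpha <- numeric(p)
  lam_min <- lam_1se <- rep(NA_real_, p)
  degen <- logical(p)
  if (!is.null(seed)) set.seed(seed)
  outcome_seeds <- sample.int(.Machine$integer.max - 1L, p)
  for (k in seq_len(p)) {
    y <- w2[, k]
    if (length(unique(y)) < 2) {
      warning(sprintf("wave-2 outcome %d is degenerate; zero column returned", k))
      degen[k] <- TRUE
      alpha[k] <- if (all(y == 1)) Inf else -Inf
      next
    }
    fit <- tryCatch(
      cv_lasso_logistic(y, w1, folds = folds,
                        seed = if (is.null(seed)) NULL else outcome_seeds[k],
                        nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio),
      error = function(e) NULL)
    if (is.null(fit)) {   # e.g. too few events to stratify in a subsample
      warning(sprintf("wave-2 outcome %d not estimable; zero column returned", k))
      degen[k] <- TRUE
      alpha[k] <- stats::qlogis(mean(y))
      next
    }
    B[, k] <- fit$coef
    alpha[k] <- fit$intercept
    lam_min[k] <- fit$lambda_min
    lam_1se[k] <- fit$lambda_1se
  }
  structure(
    list(coefficients = B, intercepts = alpha, lambda_min = lam_min,
         lambda_1se = lam_1se, degenerate = degen, labels = labels,
         folds = folds, seed = seed, n = nrow(w1)),
    class = "clpn_network")
}

#' @export
print.clpn_network <- function(x, ...) {
  p <- nrow(x$coefficients)
  nz <- sum(x$coefficients != 0)
  cat(sprintf("clpn_network: %d nodes, %d/%d nonzero directed edges (%d-fold CV, 1SE rule)\n",
              p, nz, p * p, x$folds))
  if (any(x$degenerate))
    cat("  degenerate outcomes:", paste(which(x$degenerate), collapse = ", "), "\n")
  invisible(x)
}
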