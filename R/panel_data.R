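#' PGSI item labels
#'
#' The nine items of the Problem Gambling Severity Index, in their
#' conventional order.  These are the default node labels throughout the
#' package.
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' pgsi_items()
pgsi_items <- function() {
  c("Betting more than one can afford",
    "Tolerance",
    "Chasing losses",
    "Borrowing money",
    "Recognizes one has a problem",
    "Health problems",
    "Criticized by others",
    "Financial problems",
    "Feelings of guilt")
}

#' Construct a symptom panel
#'
#' A `symptom_panel` holds per-person item responses to `p` symptoms at one
#' or more waves, either on the ordinal 0-3 response scale or dichotomized
#' to 0/1.  Missing values are permitted in the container but are flagged:
#' analysis stages require complete cases.
#'
#' @param ... One matrix per wave (person x symptom), all with identical
#'   dimensions.  Alternatively a single 3-d array (person x symptom x wave).
#' @param scale `"ordinal"` (values 0-3) or `"binary"` (values 0/1).
#' @param items Character vector of symptom labels; defaults to
#'   `pgsi_items()` when `p == 9`, else `"item1"..."itemp"`.
#' @param covariates Optional data frame of person-level covariates
#'   (e.g. sex, age) with one row per person.
#' @return An object of class `symptom_panel` with elements `responses`
#'   (3-d integer array), `scale`, `items`, `waves`, `covariates`, and
#'   `complete` (logical vector marking rows with no missing responses).
#' @export
#' @examples
#' w1 <- matrix(rbinom(30, 3, 0.1), 10, 3)
#' symptom_panel(w1, scale = "ordinal")
symptom_panel <- function(..., scale = c("ordinal", "binary"),
                          items = NULL, covariates = NULL) {
  scale <- match.arg(scale)
  args <- list(...)
  if (length(args) == 1L && is.array(args[[1]]) && length(dim(args[[1]])) == 3L) {
    resp <- args[[1]]
  } else {
    mats <- lapply(args, as.matrix)
    dims <- unique(lapply(mats, dim))
    if (length(dims) != 1L)
      stop("all wave matrices must have identical dimensions")
    resp <- array(unlist(mats), dim = c(dims[[1]], length(mats)))
  }
  n <- dim(resp)[1]; p <- dim(resp)[2]; w <- dim(resp)[3]
  if (p < 2) stop("a symptom panel needs at least 2 symptoms")
  if (is.null(items)) {
    items <- if (p == 9) pgsi_items() else paste0("item", seq_len(p))
  }
  if (length(items) != p) stop("length(items) must equal the symptom count")
  vals <- resp[!is.na(resp)]
  allowed <- if (scale == "ordinal") 0:3 else 0:1
  if (length(vals) && !all(vals %in% allowed))
    stop(sprintf("responses outside the %s range {%s}", scale,
                 paste(allowed, collapse = ",")))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per person")
  }
  dimnames(resp) <- list(NULL, items, paste0("wave", seq_len(w)))
  structure(
    list(responses = resp, scale = scale, items = items,
         waves = paste0("wave", seq_len(w)), covariates = covariates,
         complete = apply(resp, 1, function(x) !anyNA(x))),
    class = "symptom_panel")
}

#' @export
print.symptom_panel <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("symptom_panel: %d persons x %d symptoms x %d wave(s), %s scale\n",
              d[1], d[2], d[3], x$scale))
  inc <- sum(!x$complete)
  if (inc > 0) cat(sprintf("  %d person(s) with missing responses\n", inc))
  invisible(x)
}

#' @export
dim.symptom_panel <- function(x) dim(x$responses)

#' Extract one wave of a panel as a matrix
#'
#' @param panel A `symptom_panel`.
#' @param wave Wave index (1-based).
#' @param complete_only Drop persons with any missing response (across all
#'   waves) first.
#' @return Integer matrix, persons x symptoms.
#' @export
panel_wave <- function(panel, wave = 1L, complete_only = FALSE) {
  stopifnot(inherits(panel, "symptom_panel"))
  if (wave < 1 || wave > dim(panel)[3]) stop("wave out of range")
  m <- panel$responses[, , wave, drop = FALSE]
  dim(m) <- dim(panel)[1:2]
  colnames(m) <- panel$items
  if (complete_only) m <- m[panel$complete, , drop = FALSE]
  m
}

# keep only complete cases; error if nothing remains
require_complete <- function(panel, drop = TRUE) {
  if (all(panel$complete)) return(panel)
  if (!drop) stop("panel contains persons with missing responses")
  n_drop <- sum(!panel$complete)
  message(sprintf("dropping %d person(s) with missing responses", n_drop))
  keep <- panel$complete
  cov <- if (is.null(panel$covariates)) NULL else panel$covariates[keep, , drop = FALSE]
  symptom_panel(panel$responses[keep, , , drop = FALSE], scale = panel$scale,
                items = panel$items, covariates = cov)
}

#' Read a symptom panel from CSV
#'
#' Expects one row per person, with item columns named according to
#' `item_pattern` (a `sprintf` pattern taking the item number and the wave
#' number, default `"pg%d_w%d"`, e.g. `pg3_w2`).
#'
#' @param path CSV file path.
#' @param scale Response scale of the stored items.
#' @param n_items,n_waves Panel dimensions to look for.
#' @param item_pattern `sprintf` pattern building each item column name from
#'   `(item, wave)`.
#' @param id_col Optional person-identifier column; duplicated IDs are an
#'   error.
#' @param covariate_cols Columns to carry along as person covariates;
#'   defaults to `sex` and `age` when present.
#' @param drop_incomplete Drop rows with missing item responses (with a
#'   message) instead of keeping them flagged.
#' @param items Symptom labels (see [symptom_panel()]).
#' @return A `symptom_panel`.
#' @export
read_panel <- function(path, scale = c("ordinal", "binary"),
                       n_items = 9L, n_waves = 2L,
                       item_pattern = "pg%d_w%d", id_col = NULL,
                       covariate_cols = NULL, drop_incomplete = FALSE,
                       items = NULL) {
  scale <- match.arg(scale)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(id_col)) {
    if (!id_col %in% names(df)) stop("id column not found: ", id_col)
    if (anyDuplicated(df[[id_col]])) stop("duplicate person IDs in ", id_col)
  }
  mats <- vector("list", n_waves)
  for (w in seq_len(n_waves)) {
    cols <- sprintf(item_pattern, seq_len(n_items), w)
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols))
      stop("missing item columns: ", paste(missing_cols, collapse = ", "))
    mats[[w]] <- as.matrix(df[, cols])
  }
  if (is.null(covariate_cols))
    covariate_cols <- intersect(c("sex", "age"), names(df))
  cov <- if (length(covariate_cols)) df[, covariate_cols, drop = FALSE] else NULL
  panel <- do.call(symptom_panel,
                   c(mats, list(scale = scale, items = items, covariates = cov)))
  if (drop_incomplete) panel <- require_complete(panel)
  panel
}

#' Write a symptom panel to CSV
#'
#' Inverse of [read_panel()] for the same `item_pattern`.
#'
#' @inheritParams read_panel
#' @param panel A `symptom_panel`.
#' @export
write_panel <- function(panel, path, item_pattern = "pg%d_w%d") {
  stopifnot(inherits(panel, "symptom_panel"))
  d <- dim(panel)
  out <- list()
  for (w in seq_len(d[3])) {
    m <- panel_wave(panel, w)
    colnames(m) <- sprintf(item_pattern, seq_len(d[2]), w)
    out[[w]] <- as.data.frame(m)
  }
  df <- do.call(cbind, out)
  if (!is.null(panel$covariates)) df <- cbind(df, panel$covariates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' PGSI total score
#'
#' Sums the nine ordinal (0-3) item responses; defined on the ordinal scale
#' only, since dichotomized items no longer carry severity information.
#'
#' @param x A numeric vector of ordinal item responses, a person x item
#'   matrix, or an ordinal `symptom_panel` (scored per wave via `wave`).
#' @param wave Wave to score when `x` is a panel.
#' @return Total score(s), range 0 to `3 * p`.
#' @export
#' @examples
#' score_pgsi(c(1, 1, 1, 0, 0, 0, 0, 0, 0))
score_pgsi <- function(x, wave = 1L) {
  if (inherits(x, "symptom_panel")) {
    if (x$scale != "ordinal")
      stop("PGSI scoring is defined on the ordinal 0-3 scale, not binary items")
    x <- panel_wave(x, wave)
  }
  if (is.matrix(x)) {
    if (!all(x[!is.na(x)] %in% 0:3)) stop("item values must be in 0..3")
    return(rowSums(x))
  }
  if (!all(x[!is.na(x)] %in% 0:3)) stop("item values must be in 0..3")
  sum(x)
}

#' Classify a PGSI total score into a risk category
#'
#' Cut points: 0 = non-problematic; 1-2 = low risk; 3-7 = moderate risk;
#' 8 or more = severe problem gambling.
#'
#' @param total Integer total score(s) in 0..27.
#' @return Factor with levels `non_problematic`, `low_risk`,
#'   `moderate_risk`, `severe`.
#' @export
#' @examples
#' classify_risk(c(0, 2, 7, 8))
classify_risk <- function(total) {
  if (any(is.na(total))) stop("missing total scores")
  if (any(total < 0 | total > 27)) stop("PGSI totals must lie in 0..27")
  lv <- c("non_problematic", "low_risk", "moderate_risk", "severe")
  cut(total, breaks = c(-0.5, 0.5, 2.5, 7.5, 27.5), labels = lv)
}

#' Dichotomize an ordinal panel
#'
#' Maps 0 to 0 ("never") and 1-3 to 1 ("at least sometimes").  A panel
#' that is already binary is returned unchanged with a message; the
#' operation is idempotent.
#'
#' @param panel A `symptom_panel`.
#' @return A binary `symptom_panel`.
#' @export
dichotomize <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  if (panel$scale == "binary") {
    message("panel is already binary; returning unchanged")
    return(panel)
  }
  resp <- panel$responses
  resp[] <- as.integer(resp > 0)
  symptom_panel(resp, scale = "binary", items = panel$items,
                covariates = panel$covariates)
}

#' Prevalence table of symptoms and risk categories
#'
#' Per-symptom endorsement rates (from the dichotomized items) and, for
#' ordinal panels, the distribution of PGSI risk categories, per wave and
#' optionally per covariate group.  Percentages are `100 * count / n`,
#' stored at full precision; counts are exact.
#'
#' @param panel A `symptom_panel` (ordinal or binary).
#' @param group Optional name of a covariate column to stratify by.
#' @return A data frame with columns `wave`, `group`, `measure`
#'   (`"symptom"` or `"risk_category"`), `label`, `count`, `n`, `pct`.
#' @export
prevalence_table <- function(panel, group = NULL) {
  stopifnot(inherits(panel, "symptom_panel"))
  panel <- require_complete(panel)
  d <- dim(panel)
  grp <- if (is.null(group)) {
    factor(rep("total", d[1]))
  } else {
    if (is.null(panel$covariates) || !group %in% names(panel$covariates))
      stop("grouping covariate not found: ", group)
    factor(panel$covariates[[group]])
  }
  if (any(table(grp) == 0)) stop("empty group in ", group %||% "total")
  bin <- if (panel$scale == "binary") panel else suppressMessages(dichotomize(panel))
  rows <- list()
  for (w in seq_len(d[3])) {
    bm <- panel_wave(bin, w)
    for (g in levels(grp)) {
      idx <- grp == g
      ng <- sum(idx)
      cnt <- colSums(bm[idx, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        wave = w, group = g, measure = "symptom", label = panel$items,
        count = as.integer(cnt), n = ng, pct = 100 * cnt / ng,
        row.names = NULL)
      if (panel$scale == "ordinal") {
        cats <- classify_risk(score_pgsi(panel, wave = w)[idx])
        tab <- table(cats)
        rows[[length(rows) + 1L]] <- data.frame(
          wave = w, group = g, measure = "risk_category",
          label = names(tab), count = as.integer(tab), n = ng,
          pct = 100 * as.integer(tab) / ng, row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cronbach's alpha
#'
#' Internal consistency, `alpha = k/(k-1) * (1 - sum(item variances) /
#' var(total score))`, with sample (n-1) variances.
#'
#' @param x Person x item matrix (at least 2 items, 3 persons), or `NULL`
#'   when `covmat` is given.
#' @param covmat Optional item covariance matrix to compute alpha from
#'   directly.
#' @return Scalar alpha.
#' @export
#' @examples
#' cronbach_alpha(covmat = matrix(c(1, 0.5, 0.5, 1), 2))
cronbach_alpha <- function(x = NULL, covmat = NULL) {
  if (is.null(covmat)) {
    x <- as.matrix(x)
    if (ncol(x) < 2) stop("need at least 2 items")
    if (nrow(x) < 3) stop("need at least 3 persons")
    covmat <- stats::cov(x)
  }
  k <- ncol(covmat)
  total_var <- sum(covmat)
  if (total_var <= 0) stop("total-score variance is zero; alpha undefined")
  (k / (k - 1)) * (1 - sum(diag(covmat)) / total_var)
}

#' Dependent-samples t test for paired wave scores
#'
#' Two-sided t test on the wave-2 minus wave-1 differences, with the
#' between-wave Pearson correlation and a pooled-SD standardized mean
#' difference `d = mean(diff) / sqrt((sd1^2 + sd2^2)/2)` (the averaged
#' variance form, labelled as such in the output).
#'
#' @param x1,x2 Equal-length paired score vectors (wave 1, wave 2), n >= 3.
#' @return A `paired_test` object: `statistic`, `df`, `p.value`,
#'   `mean_diff`, `r` (+ its p), `d_pooled`, `sd1`, `sd2`.
#' @export
paired_t <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("paired vectors must have equal length")
  n <- length(x1)
  if (n < 3) stop("need at least 3 pairs")
  d <- x2 - x1
  sd_d <- stats::sd(d)
  if (sd_d == 0 && mean(d) != 0)
    stop("zero variance of paired differences")
  if (sd_d == 0) {        # identical waves: no change, trivially t = 0
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(x2, x1, paired = TRUE)
  }
  ct <- stats::cor.test(x1, x2)
  structure(
    list(test = "dependent t",
         statistic = unname(tt$statistic), df = n - 1L,
         p.value = tt$p.value, mean_diff = mean(d),
         sd1 = stats::sd(x1), sd2 = stats::sd(x2),
         d_pooled = mean(d) / sqrt((stats::var(x1) + stats::var(x2)) / 2),
         r = unname(ct$estimate), r_p.value = ct$p.value, n = n),
    class = "paired_test")
}

#' McNemar test for paired binary outcomes
#'
#' Uses the discordant counts `b` (0 at wave 1, 1 at wave 2) and `c`
#' (1 then 0).  Reports the standard (uncorrected) chi-squared statistic
#' `(b - c)^2 / (b + c)` on 1 df, the exact two-sided binomial p-value
#' `min(1, 2 * P(Binom(b + c, 1/2) <= min(b, c)))`, and Cohen's
#' `g = b/(b+c) - 1/2` as an explicitly labelled effect size.
#'
#' @param b1,b2 Paired binary vectors (wave 1, wave 2).
#' @return A `paired_test` object with `b`, `c`, `statistic` (chi-squared),
#'   `df`, `p.value`, `p.binomial`, `cohen_g`.
#' @export
mcnemar_paired <- function(b1, b2) {
  if (length(b1) != length(b2)) stop("paired vectors must have equal length")
  if (!all(c(b1, b2) %in% 0:1)) stop("inputs must be binary 0/1")
  b <- sum(b1 == 0 & b2 == 1)
  cc <- sum(b1 == 1 & b2 == 0)
  if (b + cc == 0) {
    chi2 <- NA_real_; p_chi <- NA_real_; p_bin <- 1
  } else {
    chi2 <- (b - cc)^2 / (b + cc)
    p_chi <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    p_bin <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
  }
  g <- if (b + cc == 0) NA_real_ else b / (b + cc) - 0.5
  structure(
    list(test = "McNemar", b = b, c = cc, statistic = chi2, df = 1L,
         p.value = p_chi, p.binomial = p_bin, cohen_g = g,
         n = length(b1)),
    class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("%s test\n", x$test))
  if (x$test == "McNemar") {
    cat(sprintf("  discordant b = %d, c = %d\n", x$b, x$c))
    cat(sprintf("  chi-squared(1) = %s, p = %s; exact binomial p = %.3f\n",
                format(round(x$statistic, 3)), format(round(x$p.value, 3)),
                x$p.binomial))
    cat(sprintf("  Cohen's g = %s\n", format(round(x$cohen_g, 3))))
  } else {
    cat(sprintf("  t(%d) = %.3f, p = %.3f; mean diff = %.3f\n",
                x$df, x$statistic, x$p.value, x$mean_diff))
    cat(sprintf("  dependent r = %.3f (p = %.3f); d (pooled SD) = %.3f\n",
                x$r, x$r_p.value, x$d_pooled))
  }
  invisible(x)
}
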