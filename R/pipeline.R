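#' Analysis configuration
#'
#' Bundles every setting of the full two-wave workflow.  All randomness is
#' governed by the single `seed`: stage seeds are derived from it
#' deterministically, so any stage can be rerun in isolation.
#'
#' @param input Path to a panel CSV, or `NULL` to simulate.
#' @param scenario Scenario name for simulation when `input` is `NULL`
#'   (see [default_scenario()]).
#' @param scale Response scale of the input CSV.
#' @param n Sample size for simulation (`NULL` = the scenario default).
#' @param item_pattern Column pattern for [read_panel()].
#' @param gamma EBIC hyperparameter.
#' @param rule Edge assembly rule.
#' @param closeness_variant Closeness definition.
#' @param folds CLPN cross-validation folds.
#' @param n_perm Permutations for the invariance test.
#' @param n_boot Bootstrap resamples for accuracy/difference diagnostics.
#' @param cs_boot Subsamples per drop proportion for the CS analysis.
#' @param nlambda Penalty grid length.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input = NULL, scenario = "pgsi",
                            scale = "ordinal", n = NULL,
                            item_pattern = "pg%d_w%d",
                            gamma = 0.25, rule = "AND",
                            closeness_variant = "inverse_sum",
                            folds = 10L, n_perm = 1000L, n_boot = 1000L,
                            cs_boot = 1000L, nlambda = 100L,
                            seed = 1L, out_dir = "symptomnet_out") {
  structure(
    list(input = input, scenario = scenario, scale = scale, n = n,
         item_pattern = item_pattern, gamma = gamma, rule = rule,
         closeness_variant = closeness_variant, folds = folds,
         n_perm = n_perm, n_boot = n_boot, cs_boot = cs_boot,
         nlambda = nlambda, seed = seed, out_dir = out_dir),
    class = "analysis_config")
}

#' Read an analysis configuration from JSON
#'
#' @param path JSON file with (a subset of) the [analysis_config()] fields.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, x)
}

# deterministic stage seeds derived from the master seed
stage_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(2^31 - 2, 8)
  names(s) <- c("simulate", "clpn", "invariance", "boot_w1", "boot_w2",
                "boot_clpn", "cs", "spare")
  s
}

#' Run the full two-wave network analysis workflow
#'
#' Executes, in order: descriptive statistics (prevalence, internal
#' consistency, paired tests), the two cross-sectional Ising networks with
#' centrality tables, their congruence and permutation invariance test,
#' the cross-lagged panel network with in-/out-strength, and bootstrap
#' accuracy plus case-dropping stability diagnostics.  Every table is
#' written to `config$out_dir` (CSV/JSON/GraphML) together with a manifest
#' recording the configuration, seeds and package version.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with all in-memory results (`panel`, `net_w1`,
#'   `net_w2`, `comparison`, `invariance`, `clpn`, `stability`, ...).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  out <- list(config = config)

  # ---- data ----
  panel <- stage("data", {
    if (!is.null(config$input)) {
      read_panel(config$input, scale = config$scale,
                 item_pattern = config$item_pattern, drop_incomplete = TRUE)
    } else {
      sc <- default_scenario(config$scenario)
      generate_two_wave(sc$ising, sc$clpn, n = config$n %||% sc$n,
                        seed = seeds["simulate"])
    }
  })
  out$panel <- panel
  bin <- if (panel$scale == "binary") panel else suppressMessages(dichotomize(panel))

  # ---- descriptives ----
  out$descriptives <- stage("descriptives", {
    prev <- prevalence_table(panel)
    utils::write.csv(prev, file.path(config$out_dir, "prevalence.csv"),
                     row.names = FALSE)
    desc <- list(prevalence = prev)
    if (dim(panel)[3] >= 2) {
      b1 <- panel_wave(bin, 1); b2 <- panel_wave(bin, 2)
      desc$mcnemar_any_symptom <- mcnemar_paired(as.integer(rowSums(b1) > 0),
                                                 as.integer(rowSums(b2) > 0))
      if (panel$scale == "ordinal") {
        t1 <- score_pgsi(panel, 1); t2 <- score_pgsi(panel, 2)
        desc$paired_t_total <- paired_t(t1, t2)
        desc$alpha <- c(wave1 = cronbach_alpha(panel_wave(panel, 1)),
                        wave2 = cronbach_alpha(panel_wave(panel, 2)))
      }
    }
    desc
  })

  # ---- cross-sectional networks ----
  w1 <- panel_wave(bin, 1, complete_only = TRUE)
  two_waves <- dim(panel)[3] >= 2
  out$net_w1 <- stage("ising_w1", suppressWarnings(
    estimate_ising(w1, gamma = config$gamma, rule = config$rule,
                   labels = panel$items, nlambda = config$nlambda)))
  cent1 <- centrality_table(out$net_w1,
                            closeness_variant = config$closeness_variant)
  utils::write.csv(cent1, file.path(config$out_dir, "centrality_wave1.csv"),
                   row.names = FALSE)
  write_edge_list(out$net_w1, file.path(config$out_dir, "network_wave1.csv"))
  write_network_json(out$net_w1, file.path(config$out_dir, "network_wave1.json"))
  write_graphml(out$net_w1, file.path(config$out_dir, "network_wave1.graphml"))

  if (two_waves) {
    w2 <- panel_wave(bin, 2, complete_only = TRUE)
    out$net_w2 <- stage("ising_w2", suppressWarnings(
      estimate_ising(w2, gamma = config$gamma, rule = config$rule,
                     labels = panel$items, nlambda = config$nlambda)))
    cent2 <- centrality_table(out$net_w2,
                              closeness_variant = config$closeness_variant)
    utils::write.csv(cent2, file.path(config$out_dir, "centrality_wave2.csv"),
                     row.names = FALSE)
    write_edge_list(out$net_w2, file.path(config$out_dir, "network_wave2.csv"))
    write_network_json(out$net_w2, file.path(config$out_dir, "network_wave2.json"))
    write_graphml(out$net_w2, file.path(config$out_dir, "network_wave2.graphml"))

    # ---- congruence + invariance ----
    out$comparison <- stage("comparison", compare_networks(
      out$net_w1, out$net_w2, closeness_variant = config$closeness_variant))
    out$invariance <- stage("invariance", invariance_test(
      w1, w2, n_perm = config$n_perm, seed = seeds["invariance"],
      gamma = config$gamma, rule = config$rule, nlambda = config$nlambda))
    jsonlite::write_json(
      list(phi = out$comparison$phi$phi, phi_p = out$comparison$phi$p.value,
           rho_edges = out$comparison$edge_weights$rho,
           rho_edges_p = out$comparison$edge_weights$p.value,
           M = out$invariance$M, p_M = out$invariance$p_M,
           S = out$invariance$S, p_S = out$invariance$p_S,
           n_perm = config$n_perm),
      file.path(config$out_dir, "comparison.json"),
      digits = NA, auto_unbox = TRUE)

    # ---- cross-lagged network ----
    out$clpn <- stage("clpn", suppressWarnings(estimate_clpn(
      bin, folds = config$folds, seed = seeds["clpn"],
      nlambda = config$nlambda)))
    cent_clpn <- centrality_table(out$clpn)
    utils::write.csv(cent_clpn, file.path(config$out_dir, "centrality_clpn.csv"),
                     row.names = FALSE)
    write_edge_list(out$clpn, file.path(config$out_dir, "network_clpn.csv"))
    write_network_json(out$clpn, file.path(config$out_dir, "network_clpn.json"))
    write_graphml(out$clpn, file.path(config$out_dir, "network_clpn.graphml"))
  }

  # ---- stability ----
  out$stability <- stage("stability", {
    st <- list(
      boot_w1 = bootstrap_edges(w1, "ising", B = config$n_boot,
                                seed = seeds["boot_w1"], gamma = config$gamma,
                                rule = config$rule, nlambda = config$nlambda),
      cs_w1 = case_dropping_cs(w1, "ising", B = config$cs_boot,
                               seed = seeds["cs"], gamma = config$gamma,
                               rule = config$rule, nlambda = config$nlambda,
                               closeness_variant = config$closeness_variant))
    if (two_waves) {
      st$boot_clpn <- bootstrap_edges(bin, "clpn", B = config$n_boot,
                                      seed = seeds["boot_clpn"],
                                      folds = config$folds,
                                      nlambda = config$nlambda)
      st$cs_clpn <- case_dropping_cs(bin, "clpn", B = config$cs_boot,
                                     seed = seeds["cs"] + 1,
                                     folds = config$folds,
                                     nlambda = config$nlambda)
    }
    st
  })
  cs_all <- c(out$stability$cs_w1$cs,
              if (two_waves) out$stability$cs_clpn$cs)
  jsonlite::write_json(as.list(cs_all),
                       file.path(config$out_dir, "cs_coefficients.json"),
                       digits = NA, auto_unbox = TRUE)

  # ---- manifest ----
  manifest <- list(package = "symptomnet",
                   version = as.character(utils::packageVersion("symptomnet")),
                   r_version = R.version.string,
                   config = unclass(config), stage_seeds = as.list(seeds))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(out)
}

#' Summarize a result bundle
#'
#' Renders a human-readable markdown summary of a completed
#' [run_full_analysis()] output directory: edge counts and percentages of
#' possible edges, mean nonzero edge weights, most central nodes, the
#' invariance statistics, and CS-coefficients.  Missing components are
#' listed rather than failing.
#'
#' @param out_dir Bundle directory.
#' @return Character vector of report lines (also printed).
#' @export
summarize_bundle <- function(out_dir) {
  lines <- c("# symptomnet analysis summary", "")
  missing <- character(0)
  net_line <- function(file, label, directed) {
    path <- file.path(out_dir, file)
    if (!file.exists(path)) { missing <<- c(missing, file); return(NULL) }
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    W <- if (directed) x$coefficients else x$weights
    if (!is.matrix(W))
      W <- matrix(unlist(W), nrow = length(x$labels), byrow = TRUE)
    vals <- if (directed) as.vector(W) else W[upper.tri(W)]
    nz <- sum(vals != 0)
    tot <- length(vals)
    mw <- if (nz > 0) mean(vals[vals != 0]) else NA_real_
    sprintf("- %s: %d of %d possible edges nonzero (%.1f%%), mean nonzero weight %s",
            label, nz, tot, 100 * nz / tot,
            if (is.na(mw)) "-" else sprintf("%.2f", mw))
  }
  lines <- c(lines, "## Networks",
             net_line("network_wave1.json", "Wave 1 cross-sectional", FALSE),
             net_line("network_wave2.json", "Wave 2 cross-sectional", FALSE),
             net_line("network_clpn.json", "Cross-lagged (directed)", TRUE), "")
  for (f in c("centrality_wave1.csv", "centrality_wave2.csv",
              "centrality_clpn.csv")) {
    path <- file.path(out_dir, f)
    if (!file.exists(path)) { missing <- c(missing, f); next }
    ct <- utils::read.csv(path)
    tops <- vapply(split(ct, ct$index), function(d)
      sprintf("%s (%s)", d$node[which.max(d$value)], unique(d$index)),
      character(1))
    lines <- c(lines, sprintf("- most central in %s: %s", f,
                              paste(tops, collapse = "; ")))
  }
  comp <- file.path(out_dir, "comparison.json")
  if (file.exists(comp)) {
    x <- jsonlite::read_json(comp, simplifyVector = TRUE)
    lines <- c(lines, "", "## Replicability",
               sprintf("- edge presence phi = %s", format(round(x$phi, 3))),
               sprintf("- max edge difference M = %.2f (p = %.3f)", x$M, x$p_M),
               sprintf("- global strength difference S = %.2f (p = %.3f)",
                       x$S, x$p_S))
  } else missing <- c(missing, "comparison.json")
  csf <- file.path(out_dir, "cs_coefficients.json")
  if (file.exists(csf)) {
    x <- jsonlite::read_json(csf, simplifyVector = TRUE)
    lines <- c(lines, "", "## Stability",
               vapply(names(x), function(i)
                 sprintf("- CS(%s) = %.2f", i, x[[i]]), character(1)))
  } else missing <- c(missing, "cs_coefficients.json")
  if (length(missing))
    lines <- c(lines, "", "## Missing components",
               paste0("- ", unique(missing)))
  lines <- lines[!vapply(lines, is.null, logical(1))]
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
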