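#' Simulate a study and write its artifact files
#'
#' Writes `panel.csv` (node-level panel, clipped into the instrument range
#' for file validity), `items.csv`, `trials.csv` and `truth.json` (the
#' generating parameters) plus a run `manifest.json`.
#'
#' @param tm an [true_model()] (default: the shipped preset).
#' @param dir output directory.
#' @param seed integer seed.
#' @param sigma_item item noise SD for the item-level file.
#' @return list of written paths, invisibly.
#' @export
run_simulate <- function(tm = paper_preset(), dir, seed = 1,
                         sigma_item = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(tm, seed = seed, clip = TRUE)
  items <- simulate_items(panel, default_composites(), sigma_item,
                          seed = seed + 1L)
  # item files mimic the bounded visual-analog instrument
  items$value <- pmin(pmax(items$value, 0), 100)
  trials <- simulate_trials(panel, seed = seed + 2L)
  paths <- list(panel = file.path(dir, "panel.csv"),
                items = file.path(dir, "items.csv"),
                trials = file.path(dir, "trials.csv"),
                truth = file.path(dir, "truth.json"),
                manifest = file.path(dir, "manifest.json"))
  write_ema_panel(panel, paths$panel)
  items_df <- as.data.frame(items)
  utils::write.csv(items_df, paths$items, row.names = FALSE, na = "")
  write_trial_log(trials, paths$trials)
  jsonlite::write_json(
    list(nodes = tm$nodes, mu = unname(tm$mu),
         sigma_b = unname_matrix(tm$sigma_b), b = unname_matrix(tm$b),
         slope_sd = unname_matrix(tm$slope_sd),
         sigma_c = unname_matrix(tm$sigma_c),
         sigma_am = unname_matrix(tm$sigma_am),
         compliance = as.list(tm$compliance),
         n_persons = tm$n_persons, n_days = tm$n_days),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(paths$manifest, list(command = "simulate", seed = seed,
                                      sigma_item = sigma_item,
                                      n_persons = tm$n_persons,
                                      n_days = tm$n_days))
  invisible(paths)
}

#' Score a raw panel: composites plus Go/No-go sessions
#'
#' @param panel an [ema_panel()] of item-level records.
#' @param trials optional `ema_trial_log`; when given, no-go accuracy is
#'   scored and merged in as `response_inhibition`.
#' @param specs composite specifications.
#' @return a scored [ema_panel()].
#' @export
run_score <- function(panel, trials = NULL, specs = default_composites()) {
  scored <- score_composites(panel, specs)
  if (!is.null(trials)) {
    scored <- merge_panels(scored, sessions_to_panel(trials))
  }
  scored
}

#' Run the full network pipeline on a scored panel
#'
#' Builds within-day AM-to-PM lag pairs, fits the two-step node-wise
#' multilevel VAR and selects FDR-controlled edges; optionally writes the
#' network JSON/TSV artifacts.
#'
#' @param panel scored [ema_panel()] containing the node variables.
#' @param nodes node variables.
#' @param options a [netfit_options()].
#' @param fdr_level edge-selection threshold on adjusted p.
#' @param rule `"or"` or `"and"` (symmetric networks).
#' @param pooling `"per_network"` or `"global"` FDR pooling.
#' @param dir optional output directory for [write_networks()] and a
#'   manifest.
#' @param seed recorded in the manifest (estimation itself is
#'   deterministic).
#' @return list with `networks` (the `ema_network_set`) and `edges` (the
#'   edge decisions).
#' @export
run_fit <- function(panel,
                    nodes = c("self_control", "response_inhibition",
                              "anger", "anger_rumination"),
                    options = netfit_options(), fdr_level = 0.05,
                    rule = "or", pooling = "per_network", dir = NULL,
                    seed = NULL) {
  if (all(is.na(panel$value))) stop("panel has no observed values")
  lags <- build_lag_pairs(panel, nodes)
  ns <- fit_mlvar(lags, nodes, options)
  edges <- select_edges(ns, threshold = fdr_level, rule = rule,
                        pooling = pooling)
  if (!is.null(dir)) {
    write_networks(ns, dir, threshold = fdr_level, rule = rule,
                   pooling = pooling)
    write_manifest(file.path(dir, "manifest.json"),
                   list(command = "fit", seed = seed, nodes = nodes,
                        fdr_level = fdr_level, rule = rule,
                        pooling = pooling,
                        options = unclass(options)))
  }
  list(networks = ns, edges = edges)
}

#' Reliability report for a study's item and task files
#'
#' @param items item-level [ema_panel()].
#' @param task_panel panel holding the task outcome.
#' @param specs composite specifications.
#' @param split_half_vars variables for split-half rows.
#' @param path optional TSV output path.
#' @return the report data.frame.
#' @export
run_reliability <- function(items, task_panel = NULL,
                            specs = default_composites(),
                            split_half_vars =
                              if (!is.null(task_panel))
                                "response_inhibition" else character(),
                            path = NULL) {
  rep_items <- reliability_report(items, specs = specs)
  out <- rep_items
  if (!is.null(task_panel) && length(split_half_vars) > 0L) {
    sh <- do.call(rbind, lapply(split_half_vars, function(v) {
      s <- split_half_sb(task_panel, v)
      data.frame(statistic = c("split_half_r", "spearman_brown"),
                 variable = v, value = c(s$r, s$sb), n = s$n)
    }))
    out <- rbind(out, sh)
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  out
}

#' Simulate-and-refit parameter recovery study
#'
#' Repeatedly simulates a study from a ground-truth model, runs the full
#' pipeline, and summarizes recovery of every temporal coefficient and
#' partial correlation: mean estimate, bias, 95% Wald coverage (temporal),
#' and how often each edge was selected.
#'
#' @param tm an [true_model()].
#' @param replications number of simulated studies.
#' @param seed base seed; replication r uses `seed + r`.
#' @param options a [netfit_options()].
#' @param fdr_level,rule,pooling edge-selection settings.
#' @return list with `temporal`, `contemporaneous`, `between` recovery
#'   tables and `edge_rates`.
#' @export
run_recovery <- function(tm, replications = 20, seed = 1,
                         options = netfit_options(), fdr_level = 0.05,
                         rule = "or", pooling = "per_network") {
  V <- length(tm$nodes)
  beta_hat <- array(NA_real_, c(replications, V, V))
  beta_cov <- array(NA_real_, c(replications, V, V))
  beta_sig <- array(NA_real_, c(replications, V, V))
  cont_hat <- array(NA_real_, c(replications, V, V))
  betw_hat <- array(NA_real_, c(replications, V, V))
  cont_sig <- array(NA_real_, c(replications, V, V))
  betw_sig <- array(NA_real_, c(replications, V, V))
  true_cont <- partial_cor(tm$sigma_c)
  true_betw <- partial_cor(tm$sigma_b)

  for (r in seq_len(replications)) {
    panel <- simulate_panel(tm, seed = seed + r)
    lags <- build_lag_pairs(panel, tm$nodes)
    ns <- fit_mlvar(lags, tm$nodes, options)
    edges <- select_edges(ns, threshold = fdr_level, rule = rule,
                          pooling = pooling)
    beta_hat[r, , ] <- ns$temporal$beta
    lo <- ns$temporal$beta - 1.96 * ns$temporal$se
    hi <- ns$temporal$beta + 1.96 * ns$temporal$se
    beta_cov[r, , ] <- (tm$b >= lo & tm$b <= hi) * 1
    cont_hat[r, , ] <- ns$contemporaneous$pcor
    betw_hat[r, , ] <- ns$between$pcor
    for (i in seq_len(nrow(edges))) {
      e <- edges[i, ]
      j <- match(e$target, tm$nodes); k <- match(e$source, tm$nodes)
      if (e$network == "temporal") {
        beta_sig[r, j, k] <- e$significant * 1
      } else if (e$network == "contemporaneous") {
        cont_sig[r, j, k] <- cont_sig[r, k, j] <- e$significant * 1
      } else {
        betw_sig[r, j, k] <- betw_sig[r, k, j] <- e$significant * 1
      }
    }
  }
  mean_mat <- function(a) apply(a, c(2L, 3L), mean, na.rm = TRUE)
  tidy <- function(true, est_mean, extra = NULL) {
    df <- expand.grid(target = tm$nodes, source = tm$nodes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$true <- as.vector(true)
    df$mean_estimate <- as.vector(est_mean)
    df$bias <- df$mean_estimate - df$true
    if (!is.null(extra)) for (nm in names(extra)) {
      df[[nm]] <- as.vector(extra[[nm]])
    }
    df
  }
  list(
    temporal = tidy(tm$b, mean_mat(beta_hat),
                    list(coverage_95 = mean_mat(beta_cov),
                         selection_rate = mean_mat(beta_sig))),
    contemporaneous = tidy(true_cont, mean_mat(cont_hat),
                           list(selection_rate = mean_mat(cont_sig))),
    between = tidy(true_betw, mean_mat(betw_hat),
                   list(selection_rate = mean_mat(betw_sig))),
    replications = replications
  )
}

write_manifest <- function(path, config) {
  config$package_version <- as.character(utils::packageVersion("emanet"))
  config$r_version <- R.version.string
  config$config_hash <- sum(utf8ToInt(paste(deparse(config),
                                            collapse = "")))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
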