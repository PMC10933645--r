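#' Build a covariance matrix from a target partial-correlation structure
#'
#' Constructs the precision matrix `K` with unit diagonal and
#' `K[j, k] = -rho[j, k]`, inverts it, and rescales the result to the
#' requested marginal SDs. Inverting the returned covariance therefore
#' recovers exactly the requested partial correlations.
#'
#' @param partial symmetric matrix of target partial correlations
#'   (|entries| < 1; the diagonal is ignored).
#' @param sds vector of target marginal standard deviations.
#' @return covariance matrix.
#' @export
build_covariance <- function(partial, sds) {
  partial <- as.matrix(partial)
  V <- nrow(partial)
  stopifnot(ncol(partial) == V, length(sds) == V, all(sds > 0))
  offd <- partial[row(partial) != col(partial)]
  if (any(abs(offd) >= 1, na.rm = TRUE)) {
    stop("partial correlations must have absolute value < 1")
  }
  K <- -partial
  diag(K) <- 1
  K[is.na(K)] <- 0
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("partial-correlation structure is not positive definite ",
         "(smallest precision eigenvalue ", signif(min(ev), 4), ")")
  }
  sigma0 <- solve(K)
  d <- sds / sqrt(diag(sigma0))
  D <- diag(d, nrow = length(d))
  sigma <- D %*% sigma0 %*% D
  dimnames(sigma) <- dimnames(partial)
  (sigma + t(sigma)) / 2
}

#' Partial correlations of a covariance matrix
#'
#' Standardized negative inverse covariance -- the closed-form counterpart
#' of the node-wise network estimates, used as an independent oracle.
#'
#' @param sigma covariance matrix.
#' @return symmetric partial-correlation matrix with `NA` diagonal.
#' @export
partial_cor <- function(sigma) {
  K <- solve(sigma)
  D <- diag(1 / sqrt(diag(K)))
  P <- -D %*% K %*% D
  diag(P) <- NA_real_
  dimnames(P) <- dimnames(sigma)
  P
}

#' Define a ground-truth model for a synthetic EMA study
#'
#' The generative model behind [simulate_panel()]: person means drawn from
#' `MVN(mu, sigma_b)`; per person a lag-1 coefficient matrix `b + delta`
#' with independent `N(0, slope_sd^2)` random-slope perturbations; each
#' day an independent morning deviation `MVN(0, sigma_am)` (fresh every
#' day -- no overnight carry-over, matching the estimator's lag structure)
#' and an afternoon deviation `b_p %*% am + MVN(0, sigma_c)`.
#'
#' @param nodes node names.
#' @param mu grand means (0-100 scale).
#' @param sigma_b between-person covariance of person means.
#' @param b temporal lag-1 matrix (rows = afternoon outcome).
#' @param slope_sd matrix of random-slope SDs (same shape as `b`).
#' @param sigma_c afternoon-innovation covariance.
#' @param sigma_am morning-deviation covariance (defaults to `sigma_c`).
#' @param compliance named observation probabilities per modality
#'   (`self_report`, `task`), each in (0, 1\].
#' @param modality named character vector mapping each node to a modality.
#' @param n_persons,n_days design size.
#' @return object of class `ema_true_model`.
#' @export
true_model <- function(nodes, mu, sigma_b, b, slope_sd, sigma_c,
                       sigma_am = sigma_c,
                       compliance = c(self_report = 1, task = 1),
                       modality = NULL, n_persons = 62L, n_days = 9L) {
  V <- length(nodes)
  stopifnot(length(mu) == V, nrow(b) == V, ncol(b) == V,
            nrow(slope_sd) == V, all(slope_sd >= 0),
            n_persons >= 1L, n_days >= 1L)
  for (nm in c("sigma_b", "sigma_c", "sigma_am")) {
    m <- get(nm)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(nm, " is not positive definite")
  }
  if (any(compliance <= 0 | compliance > 1)) {
    stop("compliance probabilities must lie in (0, 1]")
  }
  if (is.null(modality)) {
    modality <- stats::setNames(
      ifelse(nodes == "response_inhibition", "task", "self_report"), nodes)
  }
  if (!all(modality %in% names(compliance))) {
    stop("every modality needs a compliance probability")
  }
  sr <- max(Mod(eigen(b, only.values = TRUE)$values))
  if (sr >= 1) {
    warning("temporal matrix has spectral radius ", round(sr, 3),
            " >= 1; the day-resetting design still simulates, but the ",
            "coefficients do not describe a stable process")
  }
  dn <- list(nodes, nodes)
  dimnames(b) <- dimnames(slope_sd) <- dn
  dimnames(sigma_b) <- dimnames(sigma_c) <- dimnames(sigma_am) <- dn
  structure(list(nodes = nodes, mu = stats::setNames(mu, nodes),
                 sigma_b = sigma_b, b = b, slope_sd = slope_sd,
                 sigma_c = sigma_c, sigma_am = sigma_am,
                 compliance = compliance, modality = modality,
                 n_persons = as.integer(n_persons),
                 n_days = as.integer(n_days)),
            class = "ema_true_model")
}

#' @export
print.ema_true_model <- function(x, ...) {
  cat("EMA true model: ", length(x$nodes), " nodes, ", x$n_persons,
      " persons x ", x$n_days, " days x AM/PM\n", sep = "")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  cat("  compliance:",
      paste(names(x$compliance), round(x$compliance, 3), sep = "="), "\n")
  invisible(x)
}

sparse_partial <- function(nodes, entries) {
  V <- length(nodes)
  P <- matrix(0, V, V, dimnames = list(nodes, nodes))
  for (e in entries) {
    a <- e$pair[[1L]]; b <- e$pair[[2L]]
    P[a, b] <- P[b, a] <- e$value
  }
  P
}

#' Load a ground-truth model from a YAML preset
#'
#' @param path path to a YAML file structured like the shipped
#'   `paper_preset.yaml` (see [paper_preset()]).
#' @param n_persons,n_days,compliance,icc optional overrides.
#' @return an [true_model()].
#' @export
true_model_from_yaml <- function(path, n_persons = NULL, n_days = NULL,
                                 compliance = NULL, icc = NULL) {
  y <- yaml::read_yaml(path)
  nodes <- unlist(y$nodes)
  total_sd <- unlist(y$total_sd)
  if (is.null(icc)) icc <- y$icc
  between_sd <- total_sd * sqrt(icc)
  within_sd <- total_sd * sqrt(1 - icc)
  sigma_b <- build_covariance(sparse_partial(nodes, y$between_partial),
                              between_sd)
  sigma_c <- build_covariance(
    sparse_partial(nodes, y$contemporaneous_partial), within_sd)
  b <- do.call(rbind, y$temporal)
  slope_sd <- do.call(rbind, y$slope_sd)
  true_model(
    nodes = nodes, mu = unlist(y$mu), sigma_b = sigma_b, b = b,
    slope_sd = slope_sd, sigma_c = sigma_c,
    compliance = if (is.null(compliance)) unlist(y$compliance)
      else compliance,
    n_persons = if (is.null(n_persons)) y$n_persons else n_persons,
    n_days = if (is.null(n_days)) y$n_days else n_days)
}

#' The default four-node ground-truth preset
#'
#' The shipped preset parameterizes the generator with the estimated
#' self-regulation networks of the twice-daily adolescent EMA study the
#' package models: nonzero lag-1 effects (three self-loops, response
#' inhibition to self-control, rumination to anger) with their
#' person-to-person slope SDs, one negative contemporaneous anger /
#' self-control partial correlation, three between-person partial
#' correlations centred on anger, instrument-scale means and SDs, and the
#' study's design (62 persons, 9 weekdays, AM/PM, compliance .85 self-report
#' / .793 task). Total variance is split between/within by `icc`.
#'
#' @param n_persons,n_days,compliance,icc overrides of the preset design.
#' @param null_effects if `TRUE`, zero out all temporal coefficients, slope
#'   SDs and partial correlations (a no-signal model for false-positive
#'   calibration) while keeping means, SDs and design.
#' @return an [true_model()].
#' @export
paper_preset <- function(n_persons = NULL, n_days = NULL, compliance = NULL,
                         icc = NULL, null_effects = FALSE) {
  path <- system.file("extdata", "paper_preset.yaml", package = "emanet",
                      mustWork = TRUE)
  tm <- true_model_from_yaml(path, n_persons = n_persons, n_days = n_days,
                             compliance = compliance, icc = icc)
  if (null_effects) {
    V <- length(tm$nodes)
    zero <- matrix(0, V, V, dimnames = list(tm$nodes, tm$nodes))
    tm$b <- zero
    tm$slope_sd <- zero
    tm$sigma_b <- diag(diag(tm$sigma_b))
    tm$sigma_c <- diag(diag(tm$sigma_c))
    tm$sigma_am <- diag(diag(tm$sigma_am))
    dimnames(tm$sigma_b) <- dimnames(tm$sigma_c) <-
      dimnames(tm$sigma_am) <- list(tm$nodes, tm$nodes)
  }
  tm
}

#' Simulate an EMA panel from a ground-truth model
#'
#' Draws person means, person-specific lag-1 matrices, fresh morning
#' deviations each day and afternoon deviations through the person's lag
#' matrix plus innovation noise; each occasion is then observed per modality
#' with the model's compliance probability. Values are NOT clipped to
#' \[0, 100\] by default -- clipping truncates the linear model and biases
#' parameter recovery -- so the returned panel skips range validation; set
#' `clip = TRUE` for realism demonstrations.
#'
#' @param tm an [true_model()].
#' @param seed optional integer seed (fixed seed + model give a bit-identical
#'   panel).
#' @param clip clip observed values into \[0, 100\].
#' @return an [ema_panel()] with one record per observed occasion and node;
#'   the generating model is attached as attribute `truth`.
#' @export
simulate_panel <- function(tm, seed = NULL, clip = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  V <- length(tm$nodes)
  P <- tm$n_persons
  D <- tm$n_days
  persons <- sprintf("p%03d", seq_len(P))
  M <- MASS::mvrnorm(P, tm$mu, tm$sigma_b)
  if (P == 1L) M <- matrix(M, nrow = 1L)

  chunks <- vector("list", P)
  for (p in seq_len(P)) {
    delta <- matrix(stats::rnorm(V * V, 0, as.vector(tm$slope_sd)), V, V)
    bp <- tm$b + delta
    d_am <- t(MASS::mvrnorm(D, rep(0, V), tm$sigma_am))
    eps <- t(MASS::mvrnorm(D, rep(0, V), tm$sigma_c))
    if (D == 1L) { d_am <- matrix(d_am, ncol = 1L); eps <- matrix(eps, ncol = 1L) }
    d_pm <- bp %*% d_am + eps
    am_vals <- M[p, ] + d_am   # V x D
    pm_vals <- M[p, ] + d_pm
    chunks[[p]] <- data.frame(
      person = persons[p],
      day = rep(rep(seq_len(D), each = V), 2L),
      slot = rep(c("AM", "PM"), each = V * D),
      variable = rep(tm$nodes, times = 2L * D),
      value = c(as.vector(am_vals), as.vector(pm_vals)))
  }
  out <- do.call(rbind, chunks)

  # per-occasion, per-modality Bernoulli observation
  modal <- unname(tm$modality[out$variable])
  occ_key <- paste(out$person, out$day, out$slot, modal, sep = "\r")
  u_keys <- unique(occ_key)
  keep_occ <- stats::setNames(
    stats::runif(length(u_keys)) <=
      tm$compliance[sub("^.*\r", "", u_keys)],
    u_keys)
  out <- out[keep_occ[occ_key], , drop = FALSE]
  if (clip) out$value <- pmin(pmax(out$value, 0), 100)
  rownames(out) <- NULL
  panel <- ema_panel(out, registry = data.frame(
    variable = tm$nodes,
    role = ifelse(tm$modality[tm$nodes] == "task", "task-score",
                  "composite")),
    validate_range = clip)
  attr(panel, "truth") <- tm
  panel
}

#' Simulate item-level responses around composite values
#'
#' Each item equals the occasion's composite value plus independent
#' `N(0, sigma_item^2)` noise; reverse-coded items are stored flipped
#' (`100 - value`) so that scoring reverses them back. With equal loadings
#' the implied Cronbach's alpha has the closed form
#' `k * lambda / (1 + (k - 1) * lambda)` with
#' `lambda = var(composite) / (var(composite) + sigma_item^2)`
#' (see [implied_alpha()]).
#'
#' @param panel a panel containing the composite variables.
#' @param specs list of [composite_spec()] objects.
#' @param sigma_item item noise SD (>= 0).
#' @param seed optional seed.
#' @return an [ema_panel()] of item records.
#' @export
simulate_items <- function(panel, specs, sigma_item, seed = NULL) {
  if (sigma_item < 0) stop("sigma_item must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  recs <- list()
  for (spec in specs) {
    base <- panel[panel$variable == spec$name, , drop = FALSE]
    if (nrow(base) == 0L) {
      stop("composite '", spec$name, "' absent from panel")
    }
    for (item in spec$items) {
      v <- base$value + stats::rnorm(nrow(base), 0, sigma_item)
      if (item %in% spec$reverse) v <- 100 - v
      recs[[length(recs) + 1L]] <- data.frame(
        person = base$person, day = base$day, slot = base$slot,
        variable = item, value = v)
    }
  }
  out <- do.call(rbind, recs)
  vars <- unique(out$variable)
  ema_panel(out,
            registry = data.frame(variable = vars, role = "item"),
            validate_range = FALSE)
}

#' Closed-form Cronbach's alpha of the item generator
#'
#' @param var_composite variance of the composite across scoring units.
#' @param sigma_item item noise SD.
#' @param k number of items.
#' @return the alpha implied by [simulate_items()]'s equal-loading model.
#' @export
implied_alpha <- function(var_composite, sigma_item, k) {
  lambda <- var_composite / (var_composite + sigma_item^2)
  k * lambda / (1 + (k - 1) * lambda)
}

#' Simulate Go/No-go trial logs from response-inhibition values
#'
#' For every occasion carrying a `response_inhibition` value v (0-100), a
#' session of 4 blocks x 50 trials is generated with 10 no-go trials placed
#' uniformly at random per block; the response to each no-go trial is
#' withheld with probability v/100 (so rescoring the session recovers v in
#' expectation), go trials are answered with probability
#' `go_response_prob`, and RTs are lognormal nuisance.
#'
#' @param panel panel containing `response_inhibition` values in \[0, 100\].
#' @param seed optional seed.
#' @param go_response_prob response probability on go trials.
#' @return an `ema_trial_log`.
#' @export
simulate_trials <- function(panel, seed = NULL, go_response_prob = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  occ <- panel[panel$variable == "response_inhibition" &
                 !is.na(panel$value), , drop = FALSE]
  if (nrow(occ) == 0L) stop("panel has no response_inhibition values")
  if (any(occ$value < 0 | occ$value > 100)) {
    stop("response_inhibition values must lie in [0, 100]")
  }
  logs <- vector("list", nrow(occ))
  for (i in seq_len(nrow(occ))) {
    v <- occ$value[i]
    block <- rep(1:4, each = 50L)
    trial <- rep(1:50, times = 4L)
    stimulus <- rep("go", 200L)
    for (blk in 1:4) {
      stimulus[(blk - 1L) * 50L + sample.int(50L, 10L)] <- "nogo"
    }
    nogo <- stimulus == "nogo"
    responded <- logical(200L)
    responded[nogo] <- stats::runif(sum(nogo)) > v / 100
    responded[!nogo] <- stats::runif(sum(!nogo)) <= go_response_prob
    rt <- rep(NA_real_, 200L)
    rt[responded] <- stats::rlnorm(sum(responded), log(420), 0.2)
    logs[[i]] <- data.frame(
      person = occ$person[i], day = occ$day[i], slot = occ$slot[i],
      block = block, trial = trial, stimulus = stimulus,
      responded = responded, rt_ms = rt)
  }
  trial_log(do.call(rbind, logs))
}
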