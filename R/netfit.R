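#' Estimation options for the node-wise multilevel VAR
#'
#' @param random random-effects structure for the temporal node models:
#'   `"slopes"` (default; per-person random intercept plus mutually
#'   independent random slopes on every lagged predictor), `"intercept"`
#'   (random intercept only), or `"none"` (plain least squares; used for
#'   oracle checks against closed-form regression).
#' @param min_rows,min_persons minimum usable lag rows / persons per node.
#' @param standardize if `TRUE`, each node is divided by its grand SD
#'   (computed over the lag rows) before fitting, so coefficients are on a
#'   standardized scale. Default `FALSE`: the instruments' raw 0-100 scale.
#' @param reml fit by REML (default) or ML.
#' @param calc_derivs forwarded to [lme4::lmerControl()]; setting `FALSE`
#'   skips the post-fit derivative check and speeds up large fits.
#' @return list of class `netfit_options`.
#' @export
netfit_options <- function(random = c("slopes", "intercept", "none"),
                           min_rows = 10L, min_persons = 5L,
                           standardize = FALSE, reml = TRUE,
                           calc_derivs = TRUE) {
  structure(list(random = match.arg(random),
                 min_rows = as.integer(min_rows),
                 min_persons = as.integer(min_persons),
                 standardize = isTRUE(standardize), reml = isTRUE(reml),
                 calc_derivs = isTRUE(calc_derivs)),
            class = "netfit_options")
}

lmer_messages <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  c(msgs, if (fit@optinfo$conv$opt != 0) "optimizer code nonzero")
}

is_nonconverged <- function(fit) {
  any(grepl("failed to converge|unable to evaluate|problems|nonzero",
            lmer_messages(fit)))
}

# One node of the temporal step. Returns an ema_node_fit:
# coefficient table, random-effect SDs, residuals on the rows used.
#' Fit one node of the temporal multilevel VAR
#'
#' Regresses the node's afternoon value on the person-mean of every other
#' node (between-person part) and the person-mean-centered morning value of
#' every node (within-person lag-1 part), with a per-person random intercept
#' and, by default, mutually independent random slopes on the lagged
#' predictors. Estimated by REML; fixed-effect p-values are Wald z.
#' Residuals (observed minus fixed plus predicted random effects) feed the
#' second, contemporaneous step.
#'
#' Non-convergence triggers a deterministic fallback ladder: random slopes
#' are dropped smallest-variance-first, then the model falls back to a
#' random intercept only; every fallback is recorded in the fit.
#'
#' @param lags an `ema_lag_pairs` set from [build_lag_pairs()].
#' @param node node (variable) name.
#' @param options a [netfit_options()] list.
#' @return object of class `ema_node_fit`.
#' @export
fit_temporal_node <- function(lags, node, options = netfit_options()) {
  vars <- attr(lags, "variables")
  if (!node %in% vars) stop("unknown node: ", node)
  c_cols <- paste0("c_", vars)
  m_cols <- paste0("m_", setdiff(vars, node), recycle0 = TRUE)
  d <- data.frame(person = lags$person, day = lags$day,
                  y = lags[[paste0("y_", node)]])
  for (col in c(c_cols, m_cols)) d[[col]] <- lags[[col]]
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) < options$min_rows) {
    stop("node '", node, "': only ", nrow(d), " usable lag rows (minimum ",
         options$min_rows, ")")
  }
  if (length(unique(d$person)) < options$min_persons) {
    stop("node '", node, "': fewer than ", options$min_persons,
         " persons with usable rows")
  }

  # fit on unit-variance working variables (stabilizes the optimizer and
  # its gradient checks on 0-100-scale data), then map estimates back
  s_y <- stats::sd(d$y)
  if (is.na(s_y) || s_y == 0) stop("node '", node, "': outcome is constant")
  s_x <- vapply(c(c_cols, m_cols), function(col) stats::sd(d[[col]]),
                numeric(1L))
  s_x[is.na(s_x) | s_x == 0] <- 1
  d$y <- d$y / s_y
  for (col in c(c_cols, m_cols)) d[[col]] <- d[[col]] / s_x[col]

  fixed <- paste("y ~", paste(c(m_cols, c_cols), collapse = " + "))
  fallbacks <- character()
  tau <- stats::setNames(rep(NA_real_, length(vars)), vars)
  tau_intercept <- NA_real_
  fit <- NULL
  unestimable <- FALSE

  if (options$random == "none") {
    fit <- stats::lm(stats::as.formula(fixed), data = d)
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    resid_vec <- stats::resid(fit)
    sigma <- summary(fit)$sigma
  } else {
    ctrl <- lme4::lmerControl(calc.derivs = options$calc_derivs,
                              check.conv.singular =
                                lme4::.makeCC(action = "ignore", tol = 1e-4))
    slope_set <- if (options$random == "slopes") vars else character()
    repeat {
      re_term <- if (length(slope_set) > 0L) {
        paste0("(1 + ", paste(paste0("c_", slope_set), collapse = " + "),
               " || person)")
      } else {
        "(1 | person)"
      }
      form <- stats::as.formula(paste(fixed, "+", re_term))
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(form, data = d, REML = options$reml, control = ctrl))),
        error = function(e) e)
      failed <- inherits(fit, "error") || is_nonconverged(fit)
      if (!failed) break
      if (length(slope_set) > 0L) {
        # drop the smallest estimated slope variance (or the last slope if
        # the fit errored before estimates exist); deterministic ordering
        drop_var <- slope_set[length(slope_set)]
        if (!inherits(fit, "error")) {
          vc <- as.data.frame(lme4::VarCorr(fit))
          sl <- vc[vc$var1 %in% paste0("c_", slope_set) & is.na(vc$var2), ]
          if (nrow(sl) > 0L) {
            drop_var <- sub("^c_", "", sl$var1[which.min(sl$vcov)])
          }
        }
        slope_set <- setdiff(slope_set, drop_var)
        fallbacks <- c(fallbacks, paste0("dropped random slope c_", drop_var))
      } else {
        fallbacks <- c(fallbacks, "intercept-only model did not converge")
        unestimable <- inherits(fit, "error")
        break
      }
    }
    if (unestimable) {
      return(structure(list(node = node, unestimable = TRUE,
                            fallbacks = fallbacks),
                       class = "ema_node_fit"))
    }
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    for (v in vars) {
      row <- vc$var1 %in% paste0("c_", v) & is.na(vc$var2)
      if (any(row)) tau[v] <- vc$sdcor[row][1L]
    }
    int_row <- vc$var1 %in% "(Intercept)" & is.na(vc$var2) &
      vc$grp != "Residual"
    if (any(int_row)) tau_intercept <- vc$sdcor[int_row][1L]
    sigma <- vc$sdcor[vc$grp == "Residual"][1L]
    resid_vec <- d$y - stats::fitted(fit)
  }

  # back-transform from working scale to the raw data scale
  scale_term <- function(term) {
    ifelse(term == "(Intercept)", s_y, s_y / s_x[term])
  }
  fac <- scale_term(names(est))
  est <- est * fac
  se <- se * fac
  tau <- tau * s_y / s_x[paste0("c_", names(tau))]
  tau_intercept <- tau_intercept * s_y
  sigma <- sigma * s_y
  resid_vec <- resid_vec * s_y

  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = unname(2 * stats::pnorm(-abs(z))))
  role <- rep("between", nrow(coefs))
  role[coefs$term == "(Intercept)"] <- "intercept"
  role[coefs$term %in% c_cols] <- "temporal"
  coefs$role <- role

  structure(list(
    node = node, unestimable = FALSE, coefficients = coefs,
    tau = tau, tau_intercept = tau_intercept, sigma = sigma,
    residuals = data.frame(person = d$person, day = d$day,
                           resid = as.numeric(resid_vec)),
    n_rows = nrow(d), n_persons = length(unique(d$person)),
    fallbacks = fallbacks, options = options
  ), class = "ema_node_fit")
}

#' @export
print.ema_node_fit <- function(x, ...) {
  if (isTRUE(x$unestimable)) {
    cat("Node fit '", x$node, "': unestimable (",
        paste(x$fallbacks, collapse = "; "), ")\n", sep = "")
    return(invisible(x))
  }
  cat("Node fit '", x$node, "': ", x$n_rows, " lag rows, ",
      x$n_persons, " persons\n", sep = "")
  print(x$coefficients, digits = 3)
  cat("random-slope SDs:",
      paste(names(x$tau), round(x$tau, 3), sep = "="), "\n")
  if (length(x$fallbacks) > 0L) {
    cat("fallbacks:", paste(x$fallbacks, collapse = "; "), "\n")
  }
  invisible(x)
}

coef_lookup <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) c(estimate = NA_real_, se = NA_real_, p = NA_real_)
  else c(estimate = fit$coefficients$estimate[i],
         se = fit$coefficients$se[i], p = fit$coefficients$p[i])
}

#' Assemble the temporal network from node fits
#'
#' Entry `[j, k]` is the fixed-effect coefficient of node `k`'s centered
#' morning value in node `j`'s afternoon model (edge k -> j); the diagonal
#' holds the autoregressive (self-loop) effects. Random-slope SDs are
#' returned alongside as `tau`.
#'
#' @param fits list of `ema_node_fit` objects, one per node.
#' @return list with matrices `beta`, `se`, `p`, `tau` (rows = outcome
#'   node, columns = predictor node).
#' @export
assemble_temporal_network <- function(fits) {
  nodes <- vapply(fits, `[[`, character(1L), "node")
  V <- length(nodes)
  beta <- se <- p <- tau <- matrix(NA_real_, V, V,
                                   dimnames = list(nodes, nodes))
  for (j in seq_len(V)) {
    f <- fits[[j]]
    if (isTRUE(f$unestimable)) next
    for (k in seq_len(V)) {
      ck <- coef_lookup(f, paste0("c_", nodes[k]))
      beta[j, k] <- ck["estimate"]; se[j, k] <- ck["se"]; p[j, k] <- ck["p"]
      tau[j, k] <- f$tau[nodes[k]]
    }
  }
  list(beta = beta, se = se, p = p, tau = tau)
}

# Signed-geometric-mean combination of a node-wise coefficient pair into a
# partial correlation; pairs with conflicting signs get 0 and a flag.
pcor_from_pairs <- function(theta) {
  V <- nrow(theta)
  pcor <- matrix(NA_real_, V, V, dimnames = dimnames(theta))
  conflict <- matrix(FALSE, V, V, dimnames = dimnames(theta))
  for (j in seq_len(V)) for (k in seq_len(V)) {
    if (j >= k) next
    a <- theta[j, k]; b <- theta[k, j]
    if (is.na(a) || is.na(b)) next
    if (a * b < 0) {
      pcor[j, k] <- pcor[k, j] <- 0
      conflict[j, k] <- conflict[k, j] <- TRUE
    } else {
      r <- sign(a) * min(1, sqrt(a * b))
      pcor[j, k] <- pcor[k, j] <- r
    }
  }
  list(pcor = pcor, sign_conflict = conflict)
}

#' Between-person network from person-mean coefficients
#'
#' The coefficient of node `k`'s person mean in node `j`'s model and vice
#' versa are combined into a partial correlation by the signed geometric
#' mean `sign * sqrt(gamma_jk * gamma_kj)`; pairs with conflicting signs are
#' set to 0 and flagged. Both directional p-values are kept for the OR edge
#' rule.
#'
#' @param fits list of `ema_node_fit` objects.
#' @return list with `pcor` (symmetric matrix, diagonal `NA`), `gamma`,
#'   `p_dir` (directional p, `[j, k]` = p of node k's mean in node j's
#'   model) and `sign_conflict`.
#' @export
between_network <- function(fits) {
  nodes <- vapply(fits, `[[`, character(1L), "node")
  V <- length(nodes)
  gamma <- p_dir <- matrix(NA_real_, V, V, dimnames = list(nodes, nodes))
  for (j in seq_len(V)) {
    f <- fits[[j]]
    if (isTRUE(f$unestimable)) next
    for (k in seq_len(V)) {
      if (j == k) next
      gk <- coef_lookup(f, paste0("m_", nodes[k]))
      gamma[j, k] <- gk["estimate"]; p_dir[j, k] <- gk["p"]
    }
  }
  res <- pcor_from_pairs(gamma)
  list(pcor = res$pcor, gamma = gamma, p_dir = p_dir,
       sign_conflict = res$sign_conflict)
}

#' Contemporaneous (same-occasion) network from step-one residuals
#'
#' Residuals of the temporal node models are aligned on the intersection of
#' the (person, day) rows every node used; each node's residual is then
#' regressed on all other nodes' residuals with a per-person random
#' intercept, and coefficient pairs are combined into partial correlations
#' by the signed geometric mean.
#'
#' @param fits list of `ema_node_fit` objects carrying residuals.
#' @param options a [netfit_options()]; `random = "none"` uses plain least
#'   squares (oracle checks), anything else a random intercept per person.
#' @return list with `pcor`, `theta`, `p_dir`, `sign_conflict`, `n_rows`.
#' @export
contemporaneous_network <- function(fits, options = netfit_options()) {
  nodes <- vapply(fits, `[[`, character(1L), "node")
  if (any(vapply(fits, function(f) isTRUE(f$unestimable), logical(1L)))) {
    stop("contemporaneous step needs residuals from every node fit")
  }
  res <- lapply(seq_along(fits), function(i) {
    r <- fits[[i]]$residuals
    names(r)[names(r) == "resid"] <- paste0("r_", nodes[i])
    r
  })
  wide <- Reduce(function(a, b) merge(a, b, by = c("person", "day")), res)
  if (nrow(wide) == 0L) stop("no common (person, day) rows across node fits")
  V <- length(nodes)
  if (V < 2L) {
    na1 <- matrix(NA_real_, V, V, dimnames = list(nodes, nodes))
    return(list(pcor = na1, theta = na1, p_dir = na1,
                sign_conflict = is.na(na1) & FALSE, n_rows = nrow(wide)))
  }
  theta <- p_dir <- matrix(NA_real_, V, V, dimnames = list(nodes, nodes))
  for (j in seq_len(V)) {
    others <- paste0("r_", nodes[-j])
    fixed <- paste0("r_", nodes[j], " ~ ", paste(others, collapse = " + "))
    if (options$random == "none") {
      fit <- stats::lm(stats::as.formula(fixed), data = wide)
      sm <- summary(fit)$coefficients
    } else {
      ctrl <- lme4::lmerControl(calc.derivs = options$calc_derivs,
                                check.conv.singular =
                                  lme4::.makeCC(action = "ignore",
                                                tol = 1e-4))
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(stats::as.formula(paste(fixed, "+ (1 | person)")),
                   data = wide, REML = options$reml, control = ctrl)))
      sm <- summary(fit)$coefficients
    }
    for (k in seq_len(V)) {
      if (k == j) next
      term <- paste0("r_", nodes[k])
      est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
      theta[j, k] <- est
      p_dir[j, k] <- 2 * stats::pnorm(-abs(est / se))
    }
  }
  comb <- pcor_from_pairs(theta)
  list(pcor = comb$pcor, theta = theta, p_dir = p_dir,
       sign_conflict = comb$sign_conflict, n_rows = nrow(wide))
}

#' Fit the full two-step multilevel VAR network model
#'
#' Step one fits one multilevel model per node ([fit_temporal_node()]),
#' yielding the directed temporal network (lag-1, morning to afternoon of
#' the same day) and, from the person-mean coefficients, the between-person
#' partial-correlation network. Step two regresses step-one residuals on
#' each other ([contemporaneous_network()]) for the same-occasion
#' within-person network.
#'
#' @param lags an `ema_lag_pairs` set from [build_lag_pairs()].
#' @param nodes node variables (defaults to the lag set's variables).
#' @param options a [netfit_options()].
#' @return object of class `ema_network_set` with elements `nodes`,
#'   `temporal` (`beta`, `se`, `p`, `tau`), `between` and `contemporaneous`
#'   (`pcor`, directional `p_dir`, `sign_conflict`), `fits` and `meta`.
#' @export
fit_mlvar <- function(lags, nodes = attr(lags, "variables"),
                      options = netfit_options()) {
  stopifnot(inherits(lags, "ema_lag_pairs"))
  if (options$standardize) {
    for (v in attr(lags, "variables")) {
      s <- stats::sd(c(lags[[paste0("y_", v)]],
                       lags[[paste0("c_", v)]] + lags[[paste0("m_", v)]]),
                     na.rm = TRUE)
      if (is.na(s) || s == 0) stop("cannot standardize constant node ", v)
      for (p in c("y_", "c_", "m_")) {
        lags[[paste0(p, v)]] <- lags[[paste0(p, v)]] / s
      }
    }
  }
  fits <- lapply(nodes, function(nd) fit_temporal_node(lags, nd, options))
  temporal <- assemble_temporal_network(fits)
  between <- between_network(fits)
  contemporaneous <- contemporaneous_network(fits, options)
  structure(list(
    nodes = nodes, temporal = temporal, between = between,
    contemporaneous = contemporaneous, fits = fits,
    meta = list(n_persons = length(unique(lags$person)),
                n_lag_rows = nrow(lags),
                options = unclass(options),
                fallbacks = stats::setNames(
                  lapply(fits, `[[`, "fallbacks"), nodes))
  ), class = "ema_network_set")
}

#' @export
print.ema_network_set <- function(x, digits = 3, ...) {
  cat("EMA network set (", length(x$nodes), " nodes, ",
      x$meta$n_persons, " persons, ", x$meta$n_lag_rows, " lag rows)\n",
      sep = "")
  cat("\nTemporal (beta, row = afternoon outcome, col = morning",
      "predictor):\n")
  print(round(x$temporal$beta, digits))
  cat("\nContemporaneous partial correlations:\n")
  print(round(x$contemporaneous$pcor, digits))
  cat("\nBetween-person partial correlations:\n")
  print(round(x$between$pcor, digits))
  fb <- unlist(x$meta$fallbacks)
  if (length(fb) > 0L) cat("\nfallbacks:", paste(fb, collapse = "; "), "\n")
  invisible(x)
}
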