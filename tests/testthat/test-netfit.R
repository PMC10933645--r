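test_that("with random effects off, node estimates equal closed-form
           least squares", {
  tm <- paper_preset(n_persons = 40L, n_days = 12L,
                     compliance = c(self_report = 1, task = 1))
  panel <- simulate_panel(tm, seed = 55)
  lags <- build_lag_pairs(panel, tm$nodes)
  opts <- netfit_options(random = "none")
  fit <- fit_temporal_node(lags, "anger", opts)

  # hand-built normal equations on the same design
  others <- setdiff(tm$nodes, "anger")
  X <- cbind(1, as.matrix(lags[paste0("m_", others)]),
             as.matrix(lags[paste0("c_", tm$nodes)]))
  y <- lags$y_anger
  beta_hat <- solve(crossprod(X), crossprod(X, y))
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est[c("(Intercept)", paste0("m_", others),
                            paste0("c_", tm$nodes))]),
               unname(drop(beta_hat)), tolerance = 1e-6)

  # residuals match the closed-form ones
  expect_equal(fit$residuals$resid, unname(drop(y - X %*% beta_hat)),
               tolerance = 1e-6)
})

test_that("node-wise partial correlations equal precision-matrix
           inversion on common data", {
  set.seed(70)
  n <- 10000L
  pc_true <- matrix(0, 4, 4)
  pc_true[1, 2] <- pc_true[2, 1] <- -0.3
  pc_true[2, 3] <- pc_true[3, 2] <- 0.25
  pc_true[1, 4] <- pc_true[4, 1] <- 0.15
  sigma <- build_covariance(pc_true, c(1, 1.5, 2, 1))
  r <- MASS::mvrnorm(n, rep(0, 4), sigma)
  nodes <- paste0("v", 1:4)
  fits <- lapply(1:4, function(j) {
    structure(list(node = nodes[j], unestimable = FALSE,
                   residuals = data.frame(person = "p1", day = seq_len(n),
                                          resid = r[, j])),
              class = "ema_node_fit")
  })
  net <- contemporaneous_network(fits, netfit_options(random = "none"))

  # algebraically identical to inverting the SAMPLE covariance
  sample_pc <- partial_cor(stats::cov(r))
  expect_equal(net$pcor, sample_pc, tolerance = 1e-8, ignore_attr = TRUE)
  # and close to the generating partials at this n
  off <- upper.tri(pc_true)
  expect_lt(max(abs(net$pcor[off] - pc_true[off])), 0.02)
  expect_false(any(net$sign_conflict))
})

test_that("between network recovers partials of the person means", {
  # strong between structure, tiny within noise: person means are nearly
  # the latent means, so the gamma pairs must match the precision oracle
  nodes <- c("u", "v", "w")
  pcb <- matrix(0, 3, 3)
  pcb[1, 2] <- pcb[2, 1] <- -0.45
  pcb[2, 3] <- pcb[3, 2] <- 0.3
  tm <- tiny_model(nodes = nodes, mu = rep(50, 3),
                   between_sd = c(10, 10, 10),
                   within_sd = c(0.5, 0.5, 0.5),
                   b = matrix(0, 3, 3), slope_sd = matrix(0, 3, 3),
                   between_partial = pcb, n_persons = 1500L, n_days = 2L)
  panel <- simulate_panel(tm, seed = 88)
  lags <- build_lag_pairs(panel, nodes)
  fits <- lapply(nodes, function(nd)
    fit_temporal_node(lags, nd, netfit_options(random = "none")))
  bw <- between_network(fits)
  means <- attr(lags, "person_means")
  oracle <- partial_cor(stats::cov(means))
  off <- upper.tri(oracle)
  expect_lt(max(abs(bw$pcor[off] - oracle[off])), 0.02)
  expect_lt(max(abs(bw$pcor[off] - pcb[off])), 0.06)
})

test_that("sign-conflicting coefficient pairs yield a flagged zero edge", {
  mk_fit <- function(node, terms, est, p = 0.5) {
    structure(list(node = node, unestimable = FALSE,
                   coefficients = data.frame(term = terms, estimate = est,
                                             se = 1, z = est,
                                             p = p, role = "between"),
                   tau = c(a = NA_real_, b = NA_real_),
                   residuals = data.frame(person = "p1", day = 1:3,
                                          resid = 0)),
              class = "ema_node_fit")
  }
  fits <- list(mk_fit("a", "m_b", 0.2), mk_fit("b", "m_a", -0.3))
  bw <- between_network(fits)
  expect_equal(bw$pcor["a", "b"], 0)
  expect_true(bw$sign_conflict["a", "b"])

  agree <- list(mk_fit("a", "m_b", 0.2), mk_fit("b", "m_a", 0.45))
  bw2 <- between_network(agree)
  expect_equal(bw2$pcor["a", "b"], sqrt(0.2 * 0.45))
  expect_false(bw2$sign_conflict["a", "b"])
})

test_that("single-node fits recover the autoregression", {
  b1 <- matrix(0.5, 1, 1)
  tm <- tiny_model(nodes = "x", mu = 50, between_sd = 10, within_sd = 8,
                   b = b1, slope_sd = matrix(0, 1, 1),
                   n_persons = 400L, n_days = 25L)
  panel <- simulate_panel(tm, seed = 12)
  lags <- build_lag_pairs(panel, "x")
  fit <- fit_temporal_node(lags, "x", netfit_options(random = "intercept"))
  net <- assemble_temporal_network(list(fit))
  expect_equal(dim(net$beta), c(1L, 1L))
  expect_equal(net$beta[1, 1], 0.5, tolerance = 0.1)
  expect_lt(abs(net$beta[1, 1] - 0.5), 0.05)
})

test_that("temporal estimates are scale-equivariant and partial
           correlations scale-invariant", {
  tm <- paper_preset(n_persons = 50L, n_days = 9L,
                     compliance = c(self_report = 1, task = 1))
  panel <- simulate_panel(tm, seed = 61)
  lags <- build_lag_pairs(panel, tm$nodes)
  opts <- netfit_options(random = "intercept")
  base <- fit_mlvar(lags, tm$nodes, opts)

  scaled_panel <- as.data.frame(panel)
  k <- 10
  rows <- scaled_panel$variable == "anger"
  scaled_panel$value[rows] <- scaled_panel$value[rows] * k
  lags2 <- build_lag_pairs(
    ema_panel(scaled_panel, validate_range = FALSE), tm$nodes)
  scaled <- fit_mlvar(lags2, tm$nodes, opts)

  j <- match("anger", tm$nodes)
  expect_equal(scaled$temporal$beta[j, -j], base$temporal$beta[j, -j] * k,
               tolerance = 1e-6)
  expect_equal(scaled$temporal$beta[-j, j], base$temporal$beta[-j, j] / k,
               tolerance = 1e-6)
  expect_equal(scaled$temporal$beta[j, j], base$temporal$beta[j, j],
               tolerance = 1e-6)
  expect_equal(scaled$contemporaneous$pcor, base$contemporaneous$pcor,
               tolerance = 1e-4)
  expect_equal(scaled$between$pcor, base$between$pcor, tolerance = 1e-4)
})

test_that("symmetric networks are exactly symmetric", {
  tm <- paper_preset(n_persons = 40L, n_days = 9L,
                     compliance = c(self_report = 1, task = 1))
  panel <- simulate_panel(tm, seed = 19)
  ns <- fit_mlvar(build_lag_pairs(panel, tm$nodes), tm$nodes,
                  netfit_options(random = "intercept"))
  for (net in list(ns$contemporaneous$pcor, ns$between$pcor)) {
    expect_identical(net, t(net))
    expect_true(all(is.na(diag(net))))
    expect_true(all(abs(net[upper.tri(net)]) <= 1))
  }
  # adjusted p never undercuts raw p
  edges <- select_edges(ns)
  expect_true(all(edges$adj_p >= edges$raw_p - 1e-12, na.rm = TRUE))
})

test_that("recovery error shrinks as the panel grows", {
  b <- matrix(c(0.3, 0.15, 0, 0.2), 2, 2, byrow = TRUE)
  err <- vapply(c(40L, 400L), function(P) {
    tm <- tiny_model(nodes = c("x", "y"), b = b,
                     between_sd = c(10, 10), within_sd = c(8, 8),
                     n_persons = P, n_days = 10L)
    panel <- simulate_panel(tm, seed = 500 + P)
    ns <- fit_mlvar(build_lag_pairs(panel, c("x", "y")), c("x", "y"),
                    netfit_options(random = "intercept"))
    max(abs(ns$temporal$beta - b))
  }, numeric(1L))
  expect_lt(err[2L], err[1L])
  expect_lt(err[2L], 0.05)
})

test_that("Bernoulli missingness leaves recovery unbiased", {
  # same seed: the two panels share their values, the second just drops
  # occasions at the study's compliance rates
  tm_full <- paper_preset(n_persons = 150L, n_days = 30L,
                          compliance = c(self_report = 1, task = 1))
  tm_miss <- paper_preset(n_persons = 150L, n_days = 30L)
  ns_full <- fit_mlvar(
    build_lag_pairs(simulate_panel(tm_full, seed = 909), tm_full$nodes),
    options = netfit_options(random = "intercept"))
  ns_miss <- fit_mlvar(
    build_lag_pairs(simulate_panel(tm_miss, seed = 909), tm_miss$nodes),
    options = netfit_options(random = "intercept"))
  expect_lt(max(abs(ns_full$temporal$beta - tm_full$b)), 0.1)
  expect_lt(max(abs(ns_miss$temporal$beta - tm_full$b)), 0.12)
  expect_lt(max(abs(ns_miss$temporal$beta - ns_full$temporal$beta)), 0.07)
})

test_that("minimum-size guards fire with actionable messages", {
  panel <- complete_panel(persons = 2L, days = 3L, variables = c("a", "b"))
  lags <- build_lag_pairs(panel, c("a", "b"))
  expect_error(fit_temporal_node(lags, "a"), "usable lag rows|persons")
  expect_error(fit_temporal_node(lags, "zzz"), "unknown node")
  expect_error(run_fit(ema_panel(data.frame(person = "p1", day = 1L,
                                            slot = "AM", variable = "a",
                                            value = NA_real_))),
               "no observed values")
})
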