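# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

# small complete panel: `persons` x `days` x AM/PM for the given variables,
# values drawn uniformly in [0, 100]
complete_panel <- function(persons = 2L, days = 3L,
                           variables = c("a", "b"), seed = 1) {
  set.seed(seed)
  grid <- expand.grid(person = sprintf("p%02d", seq_len(persons)),
                      day = seq_len(days), slot = c("AM", "PM"),
                      variable = variables, stringsAsFactors = FALSE)
  grid$value <- round(runif(nrow(grid), 0, 100), 2)
  ema_panel(grid)
}

# minimal ground-truth model for generator-level tests
tiny_model <- function(nodes = c("x", "y"), mu = c(50, 50),
                       between_sd = c(10, 10), within_sd = c(8, 8),
                       b = matrix(0, length(nodes), length(nodes)),
                       slope_sd = matrix(0, length(nodes), length(nodes)),
                       between_partial = NULL, contemp_partial = NULL,
                       compliance = c(self_report = 1, task = 1),
                       n_persons = 20L, n_days = 5L) {
  V <- length(nodes)
  zero <- matrix(0, V, V, dimnames = list(nodes, nodes))
  pb <- if (is.null(between_partial)) zero else between_partial
  pc <- if (is.null(contemp_partial)) zero else contemp_partial
  true_model(nodes = nodes, mu = mu,
             sigma_b = build_covariance(pb, between_sd),
             b = b, slope_sd = slope_sd,
             sigma_c = build_covariance(pc, within_sd),
             compliance = compliance,
             modality = stats::setNames(rep("self_report", V), nodes),
             n_persons = n_persons, n_days = n_days)
}

# hand-built network set for edge-selection and export tests
fake_network_set <- function(nodes, beta = NULL, p_temporal = NULL,
                             pcor_c = NULL, p_dir_c = NULL,
                             pcor_b = NULL, p_dir_b = NULL) {
  V <- length(nodes)
  dn <- list(nodes, nodes)
  full <- function(m, fill) {
    if (is.null(m)) m <- matrix(fill, V, V)
    dimnames(m) <- dn
    m
  }
  offdiag_na <- function(m) { diag(m) <- NA_real_; m }
  structure(list(
    nodes = nodes,
    temporal = list(beta = full(beta, 0), se = full(NULL, 1),
                    p = full(p_temporal, 1), tau = full(NULL, 0)),
    contemporaneous = list(pcor = offdiag_na(full(pcor_c, 0)),
                           theta = offdiag_na(full(pcor_c, 0)),
                           p_dir = offdiag_na(full(p_dir_c, 1)),
                           sign_conflict = full(NULL, FALSE) == 1),
    between = list(pcor = offdiag_na(full(pcor_b, 0)),
                   gamma = offdiag_na(full(pcor_b, 0)),
                   p_dir = offdiag_na(full(p_dir_b, 1)),
                   sign_conflict = full(NULL, FALSE) == 1),
    fits = list(),
    meta = list(n_persons = 10L, n_lag_rows = 90L, options = list(),
                fallbacks = list())
  ), class = "ema_network_set")
}

# occasion-by-variable matrix of a panel (test-side shim over the
# package-internal reshaper)
panel_to_wide_test <- function(panel, vars) {
  emanet:::panel_to_wide(panel, vars)[vars]
}

# independent step-up FDR oracle: literal textbook construction
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  prev <- Inf
  for (i in seq(n, 1L)) {
    val <- min(prev, n / i * p[o[i]], 1)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
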