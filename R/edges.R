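#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1); thin wrapper over
#' [stats::p.adjust()] kept as the package's single adjustment entry point.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value list")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select the displayed edges of a network set
#'
#' Temporal edges are kept when their own FDR-adjusted p falls below the
#' threshold. Contemporaneous and between-person edges come from a pair of
#' directional node-wise tests; under the `"or"` rule (default, matching the
#' two-step estimator's convention) an edge is significant when EITHER
#' direction's adjusted p clears the threshold, under `"and"` both must.
#' Adjustment pools: `"per_network"` (default) adjusts each network's
#' p-values separately (V^2 temporal p-values; the 2*C(V,2) directional
#' p-values of each symmetric network); `"global"` pools all three networks.
#'
#' @param ns an `ema_network_set`.
#' @param threshold significance threshold on the adjusted p (default .05).
#' @param rule `"or"` or `"and"` for the symmetric networks.
#' @param pooling `"per_network"` or `"global"`.
#' @return data.frame of edge decisions: `network`, `source`, `target`,
#'   `weight`, `raw_p`, `adj_p`, `significant`, `rule`, `sign_conflict`.
#'   Temporal rows are directed (source morning -> target afternoon);
#'   symmetric rows appear once per unordered pair. For symmetric edges
#'   `raw_p`/`adj_p` are the pair minimum under `"or"`, maximum under
#'   `"and"`.
#' @export
select_edges <- function(ns, threshold = 0.05, rule = c("or", "and"),
                         pooling = c("per_network", "global")) {
  rule <- match.arg(rule)
  pooling <- match.arg(pooling)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  nodes <- ns$nodes
  V <- length(nodes)

  # collect raw p-values with provenance
  pool <- list()
  tp <- ns$temporal$p
  for (j in seq_len(V)) for (k in seq_len(V)) {
    pool[[length(pool) + 1L]] <- list(network = "temporal", j = j, k = k,
                                      p = tp[j, k])
  }
  for (net in c("contemporaneous", "between")) {
    pd <- ns[[net]]$p_dir
    for (j in seq_len(V)) for (k in seq_len(V)) {
      if (j == k) next
      pool[[length(pool) + 1L]] <- list(network = net, j = j, k = k,
                                        p = pd[j, k])
    }
  }
  tab <- data.frame(network = vapply(pool, `[[`, character(1L), "network"),
                    j = vapply(pool, `[[`, integer(1L), "j"),
                    k = vapply(pool, `[[`, integer(1L), "k"),
                    p = vapply(pool, `[[`, numeric(1L), "p"))
  tab$adj <- NA_real_
  usable <- !is.na(tab$p)
  if (pooling == "global") {
    tab$adj[usable] <- bh_adjust(tab$p[usable])
  } else {
    for (net in unique(tab$network)) {
      idx <- usable & tab$network == net
      if (any(idx)) tab$adj[idx] <- bh_adjust(tab$p[idx])
    }
  }
  get_adj <- function(net, j, k) {
    tab$adj[tab$network == net & tab$j == j & tab$k == k]
  }

  rows <- list()
  for (j in seq_len(V)) for (k in seq_len(V)) {
    w <- ns$temporal$beta[j, k]
    if (is.na(w)) next
    adj <- get_adj("temporal", j, k)
    rows[[length(rows) + 1L]] <- data.frame(
      network = "temporal", source = nodes[k], target = nodes[j],
      weight = w, raw_p = tp[j, k], adj_p = adj,
      significant = !is.na(adj) && adj < threshold,
      rule = "single", sign_conflict = FALSE)
  }
  for (net in c("contemporaneous", "between")) {
    pd <- ns[[net]]$p_dir
    for (j in seq_len(V)) for (k in seq_len(V)) {
      if (j >= k) next
      w <- ns[[net]]$pcor[j, k]
      if (is.na(w) && is.na(pd[j, k]) && is.na(pd[k, j])) next
      adj_pair <- c(get_adj(net, j, k), get_adj(net, k, j))
      raw_pair <- c(pd[j, k], pd[k, j])
      if (rule == "or") {
        adj <- suppressWarnings(min(adj_pair, na.rm = TRUE))
        raw <- suppressWarnings(min(raw_pair, na.rm = TRUE))
      } else {
        adj <- suppressWarnings(max(adj_pair, na.rm = TRUE))
        raw <- suppressWarnings(max(raw_pair, na.rm = TRUE))
      }
      if (!is.finite(adj)) adj <- NA_real_
      if (!is.finite(raw)) raw <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        network = net, source = nodes[j], target = nodes[k],
        weight = w, raw_p = raw, adj_p = adj,
        significant = !is.na(adj) && adj < threshold,
        rule = rule,
        sign_conflict = isTRUE(ns[[net]]$sign_conflict[j, k]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a network set to disk
#'
#' `networks.json` carries the full matrices plus metadata; `edges.tsv` the
#' edge list (by default only edges whose adjusted p clears the threshold,
#' mirroring how the displayed networks keep significant edges only), with
#' a `line_style` column (solid = positive, dashed = negative weight).
#'
#' @param ns an `ema_network_set`.
#' @param dir output directory (created if needed).
#' @param threshold,rule,pooling forwarded to [select_edges()].
#' @param all_edges if `TRUE`, keep non-significant edges in the TSV too.
#' @return the edge-decision data.frame, invisibly.
#' @export
write_networks <- function(ns, dir, threshold = 0.05, rule = "or",
                           pooling = "per_network", all_edges = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- select_edges(ns, threshold = threshold, rule = rule,
                        pooling = pooling)
  payload <- list(
    nodes = ns$nodes,
    temporal = lapply(ns$temporal, unname_matrix),
    contemporaneous = lapply(
      ns$contemporaneous[c("pcor", "theta", "p_dir", "sign_conflict")],
      unname_matrix),
    between = lapply(
      ns$between[c("pcor", "gamma", "p_dir", "sign_conflict")],
      unname_matrix),
    meta = ns$meta,
    edge_selection = list(threshold = threshold, rule = rule,
                          pooling = pooling)
  )
  jsonlite::write_json(payload, file.path(dir, "networks.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  keep <- if (all_edges) edges else edges[edges$significant, , drop = FALSE]
  keep$line_style <- ifelse(is.na(keep$weight) | keep$weight >= 0,
                            "solid", "dashed")
  utils::write.table(keep, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(edges)
}

unname_matrix <- function(m) {
  if (is.matrix(m)) unname(m) else m
}

#' Read a network-set JSON file back into matrices
#'
#' @param path path to a `networks.json` written by [write_networks()].
#' @return list with the node names and the three networks' matrices.
#' @export
read_networks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(m, nodes) {
    m <- as.matrix(m)
    dimnames(m) <- list(nodes, nodes)
    m
  }
  nodes <- x$nodes
  for (net in c("temporal", "contemporaneous", "between")) {
    x[[net]] <- lapply(x[[net]], fix, nodes = nodes)
  }
  x
}
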