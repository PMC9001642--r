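#' Build a co-occurrence network from SparCC results
#'
#' Keeps an edge between two OTUs iff `|rho| >= rho_min` (inclusive) and
#' `p < alpha`. Edge attributes carry the signed correlation (`rho`,
#' `sign`); node attributes carry an optional class label (e.g. core /
#' specific) and mean abundance. Isolated nodes are dropped unless
#' `keep_isolated`.
#'
#' @param rho Symmetric SparCC correlation matrix.
#' @param p Matching pseudo p-value matrix.
#' @param rho_min Correlation magnitude threshold (default 0.6).
#' @param alpha Significance threshold (default 0.05).
#' @param node_classes Optional named character vector of node class labels.
#' @param mean_abundance Optional named numeric vector of mean abundances.
#' @param keep_isolated Keep nodes without edges (default FALSE).
#' @return An undirected `igraph` with edge attributes `rho`, `sign` and
#'   node attributes `class`, `mean_abundance` when supplied.
#' @export
build_network <- function(rho, p, rho_min = 0.6, alpha = 0.05,
                          node_classes = NULL, mean_abundance = NULL,
                          keep_isolated = FALSE) {
  if (!all(dim(rho) == dim(p))) stop("rho and p matrices are not aligned")
  adj <- (abs(rho) >= rho_min) & (p < alpha)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  ends <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(ends)) {
    igraph::E(g)$rho <- rho[cbind(ends[, 1], ends[, 2])]
    igraph::E(g)$sign <- ifelse(igraph::E(g)$rho >= 0, "positive", "negative")
  } else {
    g <- igraph::set_edge_attr(g, "rho", value = numeric(0))
    g <- igraph::set_edge_attr(g, "sign", value = character(0))
  }
  if (!is.null(node_classes))
    igraph::V(g)$class <- unname(node_classes[igraph::V(g)$name])
  if (!is.null(mean_abundance))
    igraph::V(g)$mean_abundance <- unname(mean_abundance[igraph::V(g)$name])
  if (!keep_isolated)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g
}

#' Topology metrics of a co-occurrence network
#'
#' Whole-network summaries (node/edge counts, average degree, average local
#' clustering coefficient, average shortest-path length over the largest
#' connected component, Newman modularity of a greedy partition,
#' positive:negative edge counts overall and within class pairs) and
#' per-node metrics (degree, betweenness, harmonic closeness — the
#' convention that stays defined on disconnected graphs — and module).
#'
#' @param g igraph network from [build_network()] (or any undirected graph).
#' @param modules Optional membership vector; by default greedy modularity
#'   maximization (deterministic) is used.
#' @return List with `summary` (list), `nodes` (data.frame), and
#'   `modules` (named membership vector).
#' @export
topology_metrics <- function(g, modules = NULL) {
  if (igraph::vcount(g) == 0) stop("empty network")
  if (is.null(modules)) {
    comm <- igraph::cluster_fast_greedy(igraph::simplify(g))
    modules <- stats::setNames(igraph::membership(comm), igraph::V(g)$name)
  }
  q <- igraph::modularity(g, membership = modules[igraph::V(g)$name])
  local_cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comps$membership == which.max(comps$csize)))
  apl <- if (igraph::vcount(giant) > 1) igraph::mean_distance(giant, directed = FALSE) else NA_real_

  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  clo <- igraph::harmonic_centrality(g, weights = NA, normalized = TRUE)

  sgn <- igraph::E(g)$sign
  ratio <- function(s) {
    pos <- sum(s == "positive"); neg <- sum(s == "negative")
    c(positive = pos, negative = neg,
      ratio = if (neg > 0) pos / neg else NA_real_)
  }
  class_pair <- NULL
  if (!is.null(igraph::V(g)$class) && !is.null(sgn) && igraph::ecount(g) > 0) {
    ends <- igraph::as_edgelist(g)
    cls <- stats::setNames(igraph::V(g)$class, igraph::V(g)$name)
    pair <- apply(cbind(cls[ends[, 1]], cls[ends[, 2]]), 1,
                  function(x) paste(sort(x), collapse = "-"))
    class_pair <- tapply(sgn, pair, ratio)
  }
  nodes <- data.frame(otu_id = igraph::V(g)$name, degree = unname(deg),
                      betweenness = unname(btw), closeness = unname(clo),
                      module = unname(modules[igraph::V(g)$name]),
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(igraph::V(g)$class)) nodes$class <- igraph::V(g)$class
  list(summary = list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
                      avg_degree = mean(deg),
                      avg_clustering = mean(local_cc, na.rm = TRUE),
                      avg_path_length = apl, modularity = q,
                      edge_signs = if (!is.null(sgn)) ratio(sgn) else NULL,
                      edge_signs_by_class = class_pair),
       nodes = nodes,
       modules = stats::setNames(modules[igraph::V(g)$name], igraph::V(g)$name))
}

#' Zi-Pi node role classification
#'
#' Within-module connectivity `Zi = (k_is - mean_s) / sd_s` (z-score of the
#' node's edge count into its own module, over that module's members;
#' 0 when the module sd is 0) and among-module connectivity
#' `Pi = 1 - sum_t (k_it / k_i)^2`. Roles follow the usual thresholds:
#' module hubs (`Zi > 2.5`), connectors (`Pi > 0.62`), network hubs (both),
#' peripherals (neither). Isolated nodes get `Pi = NA` and role
#' `peripheral` with a warning.
#'
#' @param g Undirected igraph.
#' @param modules Named membership vector covering all nodes (defaults to
#'   greedy modularity maximization).
#' @param zi_threshold,pi_threshold Role thresholds (defaults 2.5, 0.62).
#' @return data.frame with `otu_id`, `module`, `degree`, `zi`, `pi`, `role`.
#' @export
zipi <- function(g, modules = NULL, zi_threshold = 2.5, pi_threshold = 0.62) {
  if (is.null(modules)) {
    comm <- igraph::cluster_fast_greedy(igraph::simplify(g))
    modules <- stats::setNames(igraph::membership(comm), igraph::V(g)$name)
  }
  vn <- igraph::V(g)$name
  if (is.null(vn)) {
    vn <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- vn
  }
  mem <- modules[vn]
  if (anyNA(mem)) stop("module assignment must cover all nodes")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  mods <- sort(unique(mem))
  # k_to[v, t]: edges from node v into module t
  k_to <- vapply(mods, function(t) rowSums(adj[, mem == t, drop = FALSE]),
                 numeric(length(vn)))
  if (length(vn) == 1) k_to <- matrix(k_to, nrow = 1)
  deg <- rowSums(k_to)
  own <- match(mem, mods)
  k_in <- k_to[cbind(seq_along(vn), own)]
  zi <- numeric(length(vn))
  for (t in seq_along(mods)) {
    idx <- own == t
    mu <- mean(k_in[idx]); sdv <- stats::sd(k_in[idx])
    zi[idx] <- if (is.na(sdv) || sdv == 0) 0 else (k_in[idx] - mu) / sdv
  }
  pi <- ifelse(deg > 0, 1 - rowSums((k_to / pmax(deg, 1))^2), NA_real_)
  if (any(deg == 0)) warning("isolated node(s): Pi undefined, role set peripheral")
  role <- ifelse(is.na(pi), "peripheral",
          ifelse(zi > zi_threshold & pi > pi_threshold, "network_hub",
          ifelse(zi > zi_threshold, "module_hub",
          ifelse(pi > pi_threshold, "connector", "peripheral"))))
  data.frame(otu_id = vn, module = unname(mem), degree = unname(deg),
             zi = unname(zi), pi = unname(pi), role = role,
             row.names = NULL, stringsAsFactors = FALSE)
}
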