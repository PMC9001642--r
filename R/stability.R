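#' Per-taxon positive and negative connectedness
#'
#' For each taxon, the mean of its significant positive correlations and
#' the mean of its significant negative correlations (0 when it has none of
#' that sign). Significance uses the same mask as the network construction:
#' `|rho| >= rho_min` and `p < alpha`.
#'
#' @param rho SparCC correlation matrix.
#' @param p Pseudo p-value matrix.
#' @param rho_min,alpha Significance mask thresholds (defaults 0.6, 0.05).
#' @return data.frame with `otu_id`, `positive` (in `[0, 1]`), `negative`
#'   (in `[-1, 0]`).
#' @export
connectedness <- function(rho, p, rho_min = 0.6, alpha = 0.05) {
  if (!all(dim(rho) == dim(p))) stop("rho and p matrices are not aligned")
  sig <- (abs(rho) >= rho_min) & (p < alpha)
  diag(sig) <- FALSE
  pos <- neg <- numeric(nrow(rho))
  for (i in seq_len(nrow(rho))) {
    r <- rho[i, sig[i, ]]
    pos[i] <- if (any(r > 0)) mean(r[r > 0]) else 0
    neg[i] <- if (any(r < 0)) mean(r[r < 0]) else 0
  }
  data.frame(otu_id = colnames(rho), positive = pos, negative = neg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample community cohesion
#'
#' `cohesion_s = sum_i abundance_si x connectedness_i`, evaluated
#' separately for positive and negative connectedness; the reported ratio
#' is `|negative| / positive` (NA when positive cohesion is 0). Higher
#' negative:positive ratios indicate communities dominated by antagonistic
#' associations, read as more stable.
#'
#' @param relabund Relative-abundance matrix (samples x taxa).
#' @param conn data.frame from [connectedness()] (taxa aligned by `otu_id`).
#' @return data.frame with `sample_id`, `positive`, `negative`, `ratio`.
#' @export
cohesion <- function(relabund, conn) {
  m <- as.matrix(relabund)
  idx <- match(colnames(m), conn$otu_id)
  if (anyNA(idx)) stop("taxa in the abundance table missing from connectedness")
  pos <- drop(m %*% conn$positive[idx])
  neg <- drop(m %*% conn$negative[idx])
  data.frame(sample_id = rownames(m), positive = pos, negative = neg,
             ratio = ifelse(pos > 0, abs(neg) / pos, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Natural connectivity of a graph
#'
#' The log of the average exponentiated adjacency eigenvalue,
#' `ln((1/N) sum_i exp(lambda_i))` — a spectral measure of the redundancy
#' of alternative paths, used here as the robustness score. Computed on the
#' binarized (unweighted, sign-stripped) adjacency via a numerically stable
#' log-sum-exp.
#'
#' @param g An igraph, adjacency matrix, or logical matrix.
#' @return Scalar natural connectivity (0 for an edgeless graph).
#' @export
natural_connectivity <- function(g) {
  adj <- if (inherits(g, "igraph")) {
    igraph::as_adjacency_matrix(g, sparse = FALSE)
  } else {
    as.matrix(g)
  }
  if (nrow(adj) == 0) stop("empty graph")
  adj <- (adj != 0) * 1
  diag(adj) <- 0
  lam <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  m <- max(lam)
  m + log(mean(exp(lam - m)))
}

#' Natural-connectivity robustness under random node removal
#'
#' For each removal fraction `f` and repetition, removes
#' `ceiling(f * |target|)` nodes uniformly at random from the target set
#' and recomputes the natural connectivity of the remaining graph. Grid
#' points whose removal would empty the graph are dropped with a warning.
#'
#' @param g igraph network.
#' @param target_nodes Character vector of node names eligible for removal
#'   (e.g. all nodes, the core nodes, or the specific nodes).
#' @param fractions Removal-fraction grid in `[0, 1)`.
#' @param n_rep Repetitions per fraction.
#' @param seed Integer seed.
#' @return data.frame with `fraction`, `mean_nc`, `sd_nc`, `n_rep`.
#' @export
robustness_curve <- function(g, target_nodes = igraph::V(g)$name,
                             fractions = seq(0, 0.95, by = 0.05),
                             n_rep = 100, seed = 1) {
  if (length(target_nodes) == 0) stop("target set is empty")
  if (any(fractions < 0 | fractions >= 1)) stop("fractions must lie in [0, 1)")
  target_nodes <- intersect(target_nodes, igraph::V(g)$name)
  set.seed(seed)
  nv <- igraph::vcount(g)
  out <- lapply(fractions, function(f) {
    k <- ceiling(f * length(target_nodes))
    if (k >= nv) return(NULL)
    vals <- vapply(seq_len(n_rep), function(r) {
      drop <- if (k > 0) sample(target_nodes, k) else character(0)
      natural_connectivity(igraph::delete_vertices(g, drop))
    }, numeric(1))
    data.frame(fraction = f, mean_nc = mean(vals), sd_nc = stats::sd(vals),
               n_rep = n_rep)
  })
  kept <- !vapply(out, is.null, logical(1))
  if (any(!kept)) warning("curve truncated: some fractions would empty the graph")
  do.call(rbind, out[kept])
}
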