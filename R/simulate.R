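#' Simulate a multi-group, multi-habitat community experiment
#'
#' Generates a Dirichlet-multinomial count table emulating a factorial
#' culture-system design (groups x habitats with unbalanced replication),
#' together with sample metadata and the ground-truth taxon labels. The
#' community of each group x habitat cell is drawn around a habitat profile
#' that mixes a shared ("core") profile with a habitat-private one:
#' `kappa = 1` makes all habitat profiles identical (full cross-habitat
#' convergence), `kappa = 0` makes them independent. A designated core OTU
#' set carries most of the mass and occurs in every cell by construction;
#' habitat-private OTUs occur only in their habitat (intended
#' sample-specific), and group-private OTUs only in their group (intended
#' group-specific).
#'
#' The default design mirrors a 3-group x 3-habitat experiment with six
#' replicates per cell except four water and two biofloc replicates in the
#' control group.
#'
#' @param groups Group labels.
#' @param habitats Habitat labels.
#' @param replicates Integer matrix (groups x habitats) of replicate counts.
#' @param n_core,n_habitat_private,n_group_private Numbers of core OTUs,
#'   private OTUs per habitat, and private OTUs per group.
#' @param depth Sequencing depth per sample.
#' @param kappa Cross-habitat convergence in `[0, 1]`.
#' @param concentration Dirichlet-multinomial concentration (replicate
#'   overdispersion; smaller = noisier).
#' @param seed Integer seed.
#' @return List with `counts` (samples x OTUs), `metadata` (data.frame with
#'   `sample_id`, `group`, `habitat`), and `truth` (intended OTU classes,
#'   profiles, and the seed).
#' @export
simulate_multihabitat_experiment <- function(groups = c("CK", "CN10", "CN15"),
                                             habitats = c("water", "biofloc", "gut"),
                                             replicates = NULL,
                                             n_core = 15,
                                             n_habitat_private = 15,
                                             n_group_private = 3,
                                             depth = 5000,
                                             kappa = 0.5,
                                             concentration = 50,
                                             seed = 1) {
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (is.null(replicates)) {
    replicates <- matrix(6L, length(groups), length(habitats),
                         dimnames = list(groups, habitats))
    if (all(c("CK", "water", "biofloc") %in% c(groups, habitats))) {
      replicates["CK", "water"] <- 4L
      replicates["CK", "biofloc"] <- 2L
    }
  }
  if (any(replicates < 1)) stop("every group x habitat cell needs >= 1 replicate")
  set.seed(seed)

  core_ids <- sprintf("core_%02d", seq_len(n_core))
  hab_ids <- lapply(habitats, function(h) sprintf("hab_%s_%02d", h, seq_len(n_habitat_private)))
  names(hab_ids) <- habitats
  grp_ids <- lapply(groups, function(g) sprintf("grp_%s_%02d", g, seq_len(n_group_private)))
  names(grp_ids) <- groups
  otu_ids <- c(core_ids, unlist(hab_ids), unlist(grp_ids))
  n_otus <- length(otu_ids)

  # shared core profile and independent per-habitat core reweightings;
  # the additive floor keeps every core OTU abundant enough to occur in all
  # cells at realistic depths
  w_shared <- 0.6 + stats::rlnorm(n_core, 0, 1.2)
  p_shared <- w_shared / sum(w_shared)
  hab_profile <- matrix(0, length(habitats), n_otus,
                        dimnames = list(habitats, otu_ids))
  for (h in habitats) {
    w_core <- 0.6 + stats::rlnorm(n_core, 0, 1.2)
    w_priv <- stats::rlnorm(n_habitat_private, 0, 1)
    hab_profile[h, core_ids] <- 0.895 * w_core / sum(w_core)
    hab_profile[h, hab_ids[[h]]] <- 0.105 * w_priv / sum(w_priv)
  }
  grp_profile <- matrix(0, length(groups), n_otus,
                        dimnames = list(groups, otu_ids))
  for (g in groups) {
    w <- 0.5 + stats::rlnorm(n_group_private, 0, 0.5)
    grp_profile[g, grp_ids[[g]]] <- w / sum(w)
  }

  cell_profile <- function(g, h) {
    base <- kappa * c(p_shared, numeric(n_otus - n_core)) + (1 - kappa) * hab_profile[h, ]
    0.95 * base + 0.05 * grp_profile[g, ]
  }

  n_samples <- sum(replicates)
  counts <- matrix(0, n_samples, n_otus, dimnames = list(NULL, otu_ids))
  meta <- data.frame(sample_id = character(n_samples), group = character(n_samples),
                     habitat = character(n_samples), stringsAsFactors = FALSE)
  row <- 0
  for (g in groups) for (h in habitats) {
    pr <- cell_profile(g, h)
    for (r in seq_len(replicates[g, h])) {
      row <- row + 1
      alpha <- concentration * pr
      x <- stats::rgamma(n_otus, shape = alpha)
      if (sum(x) == 0) x[which.max(pr)] <- 1
      counts[row, ] <- stats::rmultinom(1, depth, x / sum(x))
      meta$sample_id[row] <- sprintf("%s_%s_%d", g, h, r)
      meta$group[row] <- g
      meta$habitat[row] <- h
    }
  }
  rownames(counts) <- meta$sample_id
  truth <- list(
    class = stats::setNames(
      c(rep("core", n_core),
        rep("sample_specific", length(habitats) * n_habitat_private),
        rep("group_specific", length(groups) * n_group_private)),
      otu_ids),
    habitat_profiles = hab_profile,
    shared_profile = p_shared,
    kappa = kappa,
    seed = seed)
  list(counts = counts, metadata = meta, truth = truth)
}

#' Simulate a neutral local community (Hubbell zero-sum dynamics)
#'
#' One individual dies per step and is replaced by an immigrant drawn from
#' the metacommunity with probability `m`, otherwise by the offspring of a
#' random local individual. Samples are censuses of the whole local
#' community taken after a burn-in of `20 * N` steps at intervals of `N`
#' steps (quasi-stationary spacing).
#'
#' @param p_meta Metacommunity relative abundances (sums to 1).
#' @param N Local community size (>= 10).
#' @param m Migration rate in (0, 1].
#' @param n_samples Number of censuses to return.
#' @param n_burn Burn-in steps (default `20 * N`).
#' @param interval Steps between censuses (default `N`).
#' @param seed Integer seed.
#' @return List with `counts` (`n_samples` x taxa, each row summing to `N`)
#'   and `truth` (the true `m`, `N`, `p_meta`, seed).
#' @export
simulate_neutral_community <- function(p_meta, N = 1000, m = 0.1, n_samples = 30,
                                       n_burn = 20 * N, interval = N, seed = 1) {
  if (abs(sum(p_meta) - 1) > 1e-8) stop("p_meta must sum to 1")
  if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
  if (N < 10) stop("N must be >= 10")
  set.seed(seed)
  n_taxa <- length(p_meta)
  ids <- if (is.null(names(p_meta))) sprintf("otu_%03d", seq_len(n_taxa)) else names(p_meta)
  community <- sample.int(n_taxa, N, replace = TRUE, prob = p_meta)
  total_steps <- n_burn + (n_samples - 1) * interval
  # pre-draw all randomness so the loop is O(1) per step
  deaths <- sample.int(N, total_steps, replace = TRUE)
  immigrate <- stats::runif(total_steps) < m
  immigrants <- sample.int(n_taxa, total_steps, replace = TRUE, prob = p_meta)
  parents <- sample.int(N, total_steps, replace = TRUE)
  counts <- matrix(0L, n_samples, n_taxa, dimnames = list(sprintf("t%02d", seq_len(n_samples)), ids))
  take <- n_burn + (seq_len(n_samples) - 1) * interval
  k <- 1
  for (step in seq_len(total_steps)) {
    community[deaths[step]] <- if (immigrate[step]) immigrants[step] else community[parents[step]]
    if (k <= n_samples && step == take[k]) {
      counts[k, ] <- tabulate(community, nbins = n_taxa)
      k <- k + 1
    }
  }
  if (take[1] == 0) counts[1, ] <- tabulate(community, nbins = n_taxa)
  list(counts = counts, truth = list(m = m, N = N, p_meta = p_meta, seed = seed))
}

#' Simulate communities assembled under habitat selection on a phylogeny
#'
#' Grows a pure-birth tree, evolves a trait by Brownian motion along its
#' branches, and samples communities whose tip weights are the product of a
#' lognormal base abundance and a Gaussian filter
#' `exp(-(trait - optimum)^2 / (2 sigma^2))` around each habitat's optimum.
#' Distant optima yield phylogenetically divergent (heterogeneous-selection)
#' communities; a shared optimum with a narrow filter yields clustered
#' (homogeneous-selection) communities.
#'
#' @param n_tips Number of tips (>= 4).
#' @param optima Named numeric vector of trait optima, one per habitat;
#'   values are interpreted in units of the realized trait standard
#'   deviation (so `c(a = -3, b = 3)` places the optima 6 trait SD apart).
#' @param sigma Selection width (> 0), same units as `optima`.
#' @param base_sd Lognormal standard deviation of the tips' base abundances
#'   (spread of the unselected metacommunity; default 1).
#' @param sample_concentration Dirichlet concentration for per-sample
#'   resampling of the habitat weights (replicate turnover among the
#'   selected taxa); `Inf` (default) draws every sample from the identical
#'   weight vector.
#' @param N Reads per sample.
#' @param n_samples_per_habitat Samples per habitat.
#' @param seed Integer seed.
#' @return List with `counts`, `metadata` (habitat per sample), `tree`
#'   (an `ape::phylo`), and `truth` (trait, optima, sigma, weights, seed).
#' @export
simulate_selected_communities <- function(n_tips = 40,
                                          optima = c(A = -3, B = 3),
                                          sigma = 1, base_sd = 1,
                                          sample_concentration = Inf, N = 1000,
                                          n_samples_per_habitat = 10, seed = 1) {
  if (n_tips < 4) stop("n_tips must be >= 4")
  if (sigma <= 0) stop("sigma must be > 0")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("otu_%03d", seq_len(n_tips))
  trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  trait <- (trait - mean(trait)) / stats::sd(trait)  # optima are in trait-SD units
  w_base <- stats::rlnorm(n_tips, 0, base_sd)
  names(w_base) <- tree$tip.label
  habitats <- names(optima)
  if (is.null(habitats)) habitats <- sprintf("H%d", seq_along(optima))
  counts <- NULL
  meta <- NULL
  weights <- matrix(0, length(optima), n_tips,
                    dimnames = list(habitats, tree$tip.label))
  for (k in seq_along(optima)) {
    w <- w_base * exp(-(trait - optima[k])^2 / (2 * sigma^2))
    if (sum(w) == 0) stop("selection filter annihilated all tips; widen sigma")
    weights[k, ] <- w / sum(w)
    draw <- t(vapply(seq_len(n_samples_per_habitat), function(i) {
      wi <- if (is.finite(sample_concentration)) {
        g <- stats::rgamma(n_tips, shape = sample_concentration * n_tips * weights[k, ])
        if (sum(g) == 0) weights[k, ] else g / sum(g)
      } else weights[k, ]
      stats::rmultinom(1, N, wi)[, 1]
    }, numeric(n_tips)))
    rownames(draw) <- sprintf("%s_%02d", habitats[k], seq_len(n_samples_per_habitat))
    counts <- rbind(counts, draw)
    meta <- rbind(meta, data.frame(sample_id = rownames(draw),
                                   habitat = habitats[k],
                                   stringsAsFactors = FALSE))
  }
  colnames(counts) <- tree$tip.label
  list(counts = counts, metadata = meta, tree = tree,
       truth = list(trait = trait, optima = optima, sigma = sigma,
                    base = w_base / sum(w_base), weights = weights, seed = seed))
}

#' Simulate compositional counts with a known basis correlation
#'
#' Draws log-normal absolute abundances with the given basis covariance,
#' closes them to the simplex, and samples multinomial counts — the
#' canonical fixture for validating compositional correlation inference.
#'
#' @param basis_corr Symmetric positive-semidefinite correlation matrix.
#' @param basis_var Basis log-variances (default 1).
#' @param mu Basis log-means (default 0).
#' @param n_samples Number of samples.
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @return List with `counts` (rows sum to `depth`) and `truth`.
#' @export
simulate_compositional_counts <- function(basis_corr, basis_var = NULL, mu = NULL,
                                          n_samples = 60, depth = 20000, seed = 1) {
  n <- nrow(basis_corr)
  if (!isSymmetric(unname(basis_corr), tol = 1e-8)) stop("basis_corr must be symmetric")
  if (any(abs(diag(basis_corr) - 1) > 1e-8)) stop("basis_corr must have unit diagonal")
  if (is.null(basis_var)) basis_var <- rep(1, n)
  if (is.null(mu)) mu <- rep(0, n)
  ev <- eigen(basis_corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("basis_corr is not positive-semidefinite")
  set.seed(seed)
  sdv <- sqrt(basis_var)
  sigma <- sweep(sweep(basis_corr, 1, sdv, "*"), 2, sdv, "*")
  L <- eigen(sigma, symmetric = TRUE)
  rt <- L$vectors %*% diag(sqrt(pmax(L$values, 0)), n) %*% t(L$vectors)
  z <- matrix(stats::rnorm(n_samples * n), n_samples, n) %*% rt
  abund <- exp(sweep(z, 2, mu, "+"))
  frac <- abund / rowSums(abund)
  counts <- t(apply(frac, 1, function(p) stats::rmultinom(1, depth, p)[, 1]))
  dimnames(counts) <- list(sprintf("s%02d", seq_len(n_samples)),
                           sprintf("otu_%03d", seq_len(n)))
  list(counts = counts,
       truth = list(basis_corr = basis_corr, basis_var = basis_var, seed = seed))
}

#' Simulate source communities and mixed sink communities
#'
#' Each sink is a multinomial draw from the mixture
#' `sum_s pi_s * profile_s + pi_unknown * novel`, where the novel profile is
#' supported on taxa absent from every source so that the unknown fraction
#' is identifiable.
#'
#' @param source_profiles Matrix (sources x taxa) of relative abundances;
#'   rownames are source names.
#' @param pi Mixing proportions of length `nrow(source_profiles) + 1`; the
#'   last element is the unknown fraction. Must sum to 1.
#' @param depth Reads per sample (sources and sinks).
#' @param n_sinks Number of sink samples.
#' @param n_unknown_otus Size of the novel taxon pool.
#' @param seed Integer seed.
#' @return List with `sources` (counts, one row per source), `sinks`
#'   (counts), and `truth` (`pi` and seed).
#' @export
simulate_source_sinks <- function(source_profiles, pi, depth = 5000, n_sinks = 3,
                                  n_unknown_otus = 20, seed = 1) {
  S <- nrow(source_profiles)
  if (length(pi) != S + 1) stop("pi must have one entry per source plus an unknown fraction")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("pi must be non-negative and sum to 1")
  if (any(rowSums(source_profiles) <= 0)) stop("every source profile needs positive total")
  set.seed(seed)
  source_profiles <- source_profiles / rowSums(source_profiles)
  taxa <- colnames(source_profiles)
  if (is.null(taxa)) taxa <- sprintf("otu_%03d", seq_len(ncol(source_profiles)))
  novel <- sprintf("novel_%02d", seq_len(n_unknown_otus))
  all_taxa <- c(taxa, novel)
  prof <- cbind(source_profiles, matrix(0, S, n_unknown_otus))
  colnames(prof) <- all_taxa
  w <- stats::rlnorm(n_unknown_otus, 0, 1)
  p_novel <- c(numeric(length(taxa)), w / sum(w))
  mix <- drop(pi[seq_len(S)] %*% prof) + pi[S + 1] * p_novel
  sources <- t(vapply(seq_len(S), function(s) stats::rmultinom(1, depth, prof[s, ])[, 1],
                      numeric(length(all_taxa))))
  dimnames(sources) <- list(rownames(source_profiles), all_taxa)
  sinks <- t(vapply(seq_len(n_sinks), function(i) stats::rmultinom(1, depth, mix)[, 1],
                    numeric(length(all_taxa))))
  dimnames(sinks) <- list(sprintf("sink_%02d", seq_len(n_sinks)), all_taxa)
  list(sources = sources, sinks = sinks,
       truth = list(pi = stats::setNames(pi, c(rownames(sources), "unknown")),
                    novel_profile = p_novel, seed = seed))
}

#' Simulate a modular graph with planted hubs and connectors
#'
#' Draws a stochastic block model and optionally rewires designated nodes
#' into module hubs (prescribed within-module degree) or connectors (edges
#' spread evenly across all blocks) — the analytic fixture for Zi-Pi and
#' robustness checks.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param p_within,p_between Edge probabilities inside and between blocks
#'   (`p_within > p_between`); either may be a vector of length
#'   `length(block_sizes)` (`p_within` only) for heterogeneous density.
#' @param hubs Optional list of `list(block =, degree =)` module-hub specs.
#' @param connectors Optional list of `list(block =, degree =)` connector
#'   specs; the node's edges are replaced by `degree` edges split evenly
#'   over all blocks.
#' @param seed Integer seed.
#' @return List with `graph` (igraph, node attribute `name`), and `truth`
#'   (block membership, hub/connector node names, seed).
#' @export
simulate_planted_network <- function(block_sizes, p_within = 0.3, p_between = 0.02,
                                     hubs = NULL, connectors = NULL, seed = 1) {
  if (any(c(p_within, p_between) < 0) || any(c(p_within, p_between) > 1))
    stop("edge probabilities must lie in [0, 1]")
  if (min(p_within) <= max(p_between)) stop("p_within must exceed p_between")
  set.seed(seed)
  k <- length(block_sizes)
  pw <- rep(p_within, length.out = k)
  pref <- matrix(p_between, k, k)
  diag(pref) <- pw
  g <- igraph::sample_sbm(sum(block_sizes), pref.matrix = pref,
                          block.sizes = block_sizes)
  membership <- rep(seq_len(k), block_sizes)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(sum(block_sizes)))
  blocks <- split(seq_len(sum(block_sizes)), membership)

  add_within <- function(g, v, target_degree) {
    mates <- setdiff(blocks[[membership[v]]], v)
    cur <- as.integer(igraph::neighbors(g, v))
    need <- target_degree - length(intersect(cur, mates))
    if (need > 0) {
      cand <- setdiff(mates, cur)
      pick <- sample(cand, min(need, length(cand)))
      g <- igraph::add_edges(g, as.vector(rbind(v, pick)))
    }
    g
  }
  hub_nodes <- character(0)
  for (spec in hubs) {
    v <- blocks[[spec$block]][1 + length(hub_nodes)]
    g <- add_within(g, v, spec$degree)
    hub_nodes <- c(hub_nodes, igraph::V(g)$name[v])
  }
  conn_nodes <- character(0)
  for (spec in connectors) {
    v <- blocks[[spec$block]][length(blocks[[spec$block]])]
    g <- igraph::delete_edges(g, igraph::incident(g, v))
    per <- spec$degree / k
    if (per != round(per)) stop("connector degree must be divisible by the number of blocks")
    tgt <- unlist(lapply(blocks, function(b) sample(setdiff(b, v), per)))
    g <- igraph::add_edges(g, as.vector(rbind(v, tgt)))
    conn_nodes <- c(conn_nodes, igraph::V(g)$name[v])
  }
  g <- igraph::simplify(g)
  list(graph = g,
       truth = list(membership = stats::setNames(membership, igraph::V(g)$name),
                    hubs = hub_nodes, connectors = conn_nodes, seed = seed))
}
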