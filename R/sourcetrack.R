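#' Bayesian source apportionment of sink communities (Gibbs sampling)
#'
#' Estimates, for each sink community, the fraction of its reads derived
#' from each source environment plus an "unknown" environment with no
#' training counts. Each sink read carries a latent source label sampled
#' from its full conditional
#' `P(z = s) ~ (m_st + nhat_st + alpha_s) / (m_s. + nhat_s. + alpha_s T) * (n_s + beta)`
#' where `m` are source training counts (zero for the unknown), `nhat` the
#' current assignments of the other sink reads, and `T` the number of taxa.
#' Proportions are averaged over retained draws and independent restarts;
#' the between-restart spread is reported as a convergence diagnostic.
#'
#' Hyperparameter defaults follow the published microbial source-tracking
#' convention (`alpha_source = 0.001`, `alpha_unknown = 0.1`, `beta = 10`).
#'
#' @param sources Count matrix, one row per source environment (taxa in
#'   columns, aligned by name with `sinks`).
#' @param sinks Count matrix of sink samples (rows), or a single named
#'   count vector.
#' @param alpha_source,alpha_unknown Dirichlet smoothing for known sources
#'   and for the unknown environment.
#' @param beta Symmetric prior on mixing proportions.
#' @param n_burn,n_draws,draw_interval Gibbs schedule per restart.
#' @param n_restarts Independent restarts averaged into the estimate.
#' @param rarefy_to Optional depth to subsample each sink to before
#'   sampling (default 1000; `NULL` uses all reads).
#' @param seed Integer seed.
#' @return List with `proportions` (sinks x sources+unknown, rows sum to
#'   1), `sd` (between-restart standard deviation), and the sampler
#'   settings.
#' @export
gibbs_source_apportion <- function(sources, sinks, alpha_source = 0.001,
                                   alpha_unknown = 0.1, beta = 10,
                                   n_burn = 100, n_draws = 50,
                                   draw_interval = 10, n_restarts = 5,
                                   rarefy_to = 1000, seed = 1) {
  if (is.null(dim(sinks))) sinks <- matrix(sinks, 1, dimnames = list("sink", names(sinks)))
  if (is.null(colnames(sources)) || is.null(colnames(sinks)))
    stop("sources and sinks must have taxon names")
  taxa <- union(colnames(sources), colnames(sinks))
  if (length(intersect(colnames(sources), colnames(sinks))) == 0)
    stop("sources and sinks share no taxa")
  expand <- function(m) {
    out <- matrix(0, nrow(m), length(taxa), dimnames = list(rownames(m), taxa))
    out[, colnames(m)] <- m
    out
  }
  src <- expand(as.matrix(sources))
  snk <- expand(as.matrix(sinks))
  S <- nrow(src)
  env_names <- c(rownames(src), "unknown")
  m <- rbind(src, unknown = 0)
  alpha <- c(rep(alpha_source, S), alpha_unknown)
  set.seed(seed)
  prop <- sdm <- matrix(NA_real_, nrow(snk), S + 1,
                        dimnames = list(rownames(snk), env_names))
  for (i in seq_len(nrow(snk))) {
    reads <- rep(seq_along(taxa), snk[i, ])
    if (length(reads) == 0) stop("sink ", rownames(snk)[i], " has no reads")
    if (!is.null(rarefy_to) && length(reads) > rarefy_to)
      reads <- sample(reads, rarefy_to)
    restarts <- vapply(seq_len(n_restarts), function(r) {
      draws <- gibbs_sink(reads - 1L, m, alpha, beta,
                          as.integer(n_burn), as.integer(n_draws),
                          as.integer(draw_interval))
      colMeans(draws)
    }, numeric(S + 1))
    prop[i, ] <- rowMeans(restarts)
    sdm[i, ] <- apply(restarts, 1, stats::sd)
  }
  list(proportions = prop, sd = sdm,
       settings = list(alpha_source = alpha_source, alpha_unknown = alpha_unknown,
                       beta = beta, n_burn = n_burn, n_draws = n_draws,
                       draw_interval = draw_interval, n_restarts = n_restarts,
                       rarefy_to = rarefy_to, seed = seed))
}
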