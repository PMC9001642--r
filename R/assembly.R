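#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Abundance-weighted by default:
#' `0.5 * (sum_i f_iA min_jB D_ij + sum_j f_jB min_iA D_ij)` where `f` are
#' relative abundances within each community and `D` is the patristic
#' distance; the nearest-taxon distance is 0 for shared taxa. Unweighted
#' mode replaces `f` by `1 / richness` over present taxa.
#'
#' @param xa,xb Count or abundance vectors named by OTU id.
#' @param tree Rooted `ape::phylo` covering all present OTUs, or a
#'   precomputed patristic distance matrix.
#' @param weighted Abundance-weighted (default) or presence-based.
#' @return Scalar betaMNTD.
#' @export
beta_mntd <- function(xa, xb, tree, weighted = TRUE) {
  D <- if (inherits(tree, "phylo")) ape::cophenetic.phylo(tree) else as.matrix(tree)
  counts <- rbind(xa, xb)
  miss <- setdiff(names(xa)[xa > 0 | xb > 0], rownames(D))
  if (length(miss)) stop("OTUs missing from tree: ", paste(miss, collapse = ", "))
  m <- beta_mntd_matrix(counts, D, weighted = weighted)
  m[1, 2]
}

#' All-pairs betaMNTD matrix
#'
#' Vectorized computation of [beta_mntd()] between every pair of rows.
#'
#' @param counts OTU table (samples x OTUs).
#' @param D Patristic distance matrix covering the OTUs.
#' @param weighted Abundance-weighted (default) or presence-based.
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
beta_mntd_matrix <- function(counts, D, weighted = TRUE) {
  counts <- as.matrix(counts)
  otus <- colnames(counts)
  if (!all(otus %in% rownames(D))) stop("distance matrix does not cover all OTUs")
  D <- D[otus, otus, drop = FALSE]
  f <- if (weighted) {
    counts / rowSums(counts)
  } else {
    pres <- counts > 0
    pres / pmax(rowSums(pres), 1)
  }
  # M[i, b] = min patristic distance from taxon i to any taxon present in b
  M <- vapply(seq_len(nrow(counts)), function(b) {
    idx <- which(counts[b, ] > 0)
    do.call(pmin, as.data.frame(D[, idx, drop = FALSE]))
  }, numeric(ncol(counts)))
  fm <- f %*% M
  out <- 0.5 * (fm + t(fm))
  diag(out) <- 0
  dimnames(out) <- list(rownames(counts), rownames(counts))
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' Z-score of the observed betaMNTD against a null distribution obtained
#' by shuffling taxa labels across the tips of the phylogeny. Each shuffle
#' is shared across all sample pairs (one permuted distance matrix serves
#' the whole betaMNTD matrix), which keeps the null count per pair at
#' `n_null` while touching the tree only once per shuffle.
#'
#' @param counts OTU table (samples x OTUs), >= 2 samples.
#' @param tree Rooted `ape::phylo` or patristic distance matrix.
#' @param n_null Number of tip shuffles (default 999).
#' @param weighted Abundance-weighted betaMNTD (default).
#' @param seed Integer seed.
#' @return Symmetric matrix of betaNTI values (NA with a warning where the
#'   null sd is 0).
#' @export
bnti <- function(counts, tree, n_null = 999, weighted = TRUE, seed = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 samples")
  D <- if (inherits(tree, "phylo")) ape::cophenetic.phylo(tree) else as.matrix(tree)
  D <- D[colnames(counts), colnames(counts), drop = FALSE]
  set.seed(seed)
  obs <- beta_mntd_matrix(counts, D, weighted = weighted)
  s1 <- matrix(0, nrow(counts), nrow(counts))
  s2 <- matrix(0, nrow(counts), nrow(counts))
  for (k in seq_len(n_null)) {
    perm <- sample.int(ncol(counts))
    Dp <- D[perm, perm]
    dimnames(Dp) <- dimnames(D)
    nb <- beta_mntd_matrix(counts, Dp, weighted = weighted)
    s1 <- s1 + nb
    s2 <- s2 + nb^2
  }
  mu <- s1 / n_null
  sdv <- sqrt(pmax(s2 / n_null - mu^2, 0) * n_null / (n_null - 1))
  out <- (obs - mu) / sdv
  out[sdv == 0] <- NA_real_
  diag(out) <- 0
  if (any(sdv[upper.tri(sdv)] == 0))
    warning("null sd is 0 for some pairs; betaNTI set NA")
  dimnames(out) <- dimnames(obs)
  out
}

#' Bray-Curtis-based Raup-Crick index
#'
#' For each sample pair, null communities preserve each sample's observed
#' richness and total abundance: taxa are drawn without replacement with
#' probability proportional to their metacommunity occupancy frequency,
#' then individuals fill the community with probability proportional to
#' metacommunity relative abundance among the drawn taxa. The index is
#' `2 * ((#null < obs) + 0.5 * (#null = obs)) / n_null - 1`, in `[-1, 1]`.
#'
#' @param counts Integer OTU table (samples x OTUs), >= 2 samples; the
#'   table itself defines the metacommunity.
#' @param n_null Null draws per pair (default 999).
#' @param seed Integer seed.
#' @return Symmetric matrix of RC values with zero diagonal.
#' @export
rc_bray <- function(counts, n_null = 999, seed = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 samples")
  if (any(counts != round(counts))) stop("rc_bray needs integer counts")
  set.seed(seed)
  n_taxa <- ncol(counts)
  occ <- colSums(counts > 0)
  relab <- colSums(counts) / sum(counts)
  rich <- rowSums(counts > 0)
  tot <- rowSums(counts)
  if (any(rich > sum(occ > 0))) stop("sample richness exceeds metacommunity richness")
  null_one <- function(R, N) rc_null_community(occ, relab, R, N) / N
  S <- nrow(counts)
  out <- matrix(0, S, S, dimnames = list(rownames(counts), rownames(counts)))
  frac <- counts / tot
  for (a in seq_len(S - 1)) for (b in (a + 1):S) {
    obs <- 1 - sum(pmin(frac[a, ], frac[b, ]))
    nulls <- vapply(seq_len(n_null), function(k) {
      xa <- null_one(rich[a], tot[a])
      xb <- null_one(rich[b], tot[b])
      1 - sum(pmin(xa, xb))
    }, numeric(1))
    rc <- (sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_null
    out[a, b] <- out[b, a] <- 2 * (rc - 0.5)
  }
  out
}

#' Draw one Raup-Crick null community
#'
#' The stochastic assembly process underlying [rc_bray()]'s null: `R` taxa
#' are drawn without replacement with probability proportional to their
#' metacommunity occupancy frequency, each receives one individual, and the
#' community is filled to `N` individuals with replacement proportional to
#' metacommunity relative abundance among the drawn taxa. Exposed so that
#' the null process can be sampled directly (e.g. for self-consistency
#' calibration of the index).
#'
#' @param occupancy Per-taxon occupancy frequencies (length = n taxa).
#' @param relabund Per-taxon metacommunity relative abundances.
#' @param richness Number of taxa to draw.
#' @param total Total individuals in the community.
#' @return Integer count vector of length `length(occupancy)` summing to
#'   `total`.
#' @export
rc_null_community <- function(occupancy, relabund, richness, total) {
  if (richness > sum(occupancy > 0)) stop("richness exceeds metacommunity richness")
  taxa <- sample.int(length(occupancy), richness, prob = occupancy)
  x <- numeric(length(occupancy))
  x[taxa] <- 1
  if (total > richness) {
    fill <- taxa[sample.int(length(taxa), total - richness, replace = TRUE,
                            prob = relabund[taxa])]
    x <- x + tabulate(fill, nbins = length(occupancy))
  }
  x
}

#' Partition community-assembly processes from betaNTI and RC values
#'
#' Decision rule per sample pair: `betaNTI > 2` heterogeneous selection;
#' `betaNTI < -2` homogeneous selection; otherwise `RC > 0.95` dispersal
#' limitation, `RC < -0.95` homogenizing dispersal, else undominated
#' (drift). Pairs with missing betaNTI are excluded and reported.
#'
#' @param bnti_mat,rc_mat Aligned symmetric matrices.
#' @param labels Optional per-sample labels (e.g. habitat); when given,
#'   process fractions are reported per unordered label pair.
#' @return List with `pairs` (long data.frame: sample_a, sample_b, bnti,
#'   rc, process), `fractions` (named proportions summing to 1, or a
#'   list per label pair), and `excluded` (pairs without betaNTI).
#' @export
partition_processes <- function(bnti_mat, rc_mat, labels = NULL) {
  if (!all(dim(bnti_mat) == dim(rc_mat))) stop("matrices are not aligned")
  S <- nrow(bnti_mat)
  idx <- which(upper.tri(bnti_mat), arr.ind = TRUE)
  ids <- rownames(bnti_mat)
  if (is.null(ids)) ids <- as.character(seq_len(S))
  df <- data.frame(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
                   bnti = bnti_mat[idx], rc = rc_mat[idx],
                   stringsAsFactors = FALSE)
  df$process <- ifelse(is.na(df$bnti), NA_character_,
                ifelse(df$bnti > 2, "heterogeneous_selection",
                ifelse(df$bnti < -2, "homogeneous_selection",
                ifelse(df$rc > 0.95, "dispersal_limitation",
                ifelse(df$rc < -0.95, "homogenizing_dispersal", "undominated")))))
  excluded <- df[is.na(df$process), c("sample_a", "sample_b")]
  kept <- df[!is.na(df$process), ]
  lv <- c("heterogeneous_selection", "homogeneous_selection",
          "dispersal_limitation", "homogenizing_dispersal", "undominated")
  frac_of <- function(x) {
    tab <- table(factor(x, levels = lv))
    stats::setNames(as.numeric(tab) / length(x), lv)
  }
  fractions <- if (is.null(labels)) {
    frac_of(kept$process)
  } else {
    names(labels) <- ids
    key <- apply(cbind(labels[kept$sample_a], labels[kept$sample_b]), 1,
                 function(x) paste(sort(x), collapse = "-"))
    lapply(split(kept$process, key), frac_of)
  }
  list(pairs = df, fractions = fractions, excluded = excluded)
}

#' Fit the Sloan neutral community model
#'
#' Predicts each taxon's occurrence frequency across local communities
#' from its mean relative abundance `p` in the source pool:
#' `F(p) = 1 - BetaCDF(d; N m p, N m (1 - p))` with detection limit `d`.
#' `N m` is fit by bounded least squares of observed frequency against
#' `F(p)`; `R^2 = 1 - SS_res / SS_tot` may be negative, in which case the
#' neutral model does not describe assembly. Each taxon is classified as
#' neutral, above, or below the 95% Wilson binomial interval around its
#' predicted frequency at the observed number of local samples.
#'
#' @param local Count table of the local communities (samples x OTUs).
#' @param pool Source-pool count table or a named relative-abundance
#'   vector; the pool defines `p`.
#' @param N Local community size (reads per sample); defaults to the mean
#'   row sum of `local`.
#' @param d Detection limit; defaults to `1 / N` (one read).
#' @return List with `m`, `Nm`, `r_squared`, `d`, `N`, and `otu` — a
#'   data.frame (`otu_id`, `pool_p`, `obs_freq`, `pred_freq`, `ci_lo`,
#'   `ci_hi`, `class`).
#' @export
sloan_fit <- function(local, pool, N = NULL, d = NULL) {
  local <- as.matrix(local)
  p_pool <- if (is.matrix(pool)) {
    cs <- colSums(pool)
    cs / sum(cs)
  } else {
    pool / sum(pool)
  }
  if (is.null(names(p_pool))) {
    if (length(p_pool) != ncol(local))
      stop("unnamed pool must align with the local table's columns")
    names(p_pool) <- colnames(local)
  }
  shared <- intersect(colnames(local), names(p_pool))
  shared <- shared[p_pool[shared] > 0 & colSums(local[, shared, drop = FALSE]) > 0]
  if (length(shared) < 5) stop("need at least 5 OTUs shared between pool and local set")
  if (is.null(N)) N <- mean(rowSums(local))
  if (is.null(d)) d <- 1 / N
  p <- p_pool[shared]
  obs <- colMeans(local[, shared, drop = FALSE] > 0)
  pred_fun <- function(Nm) 1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
  sse <- function(logNm) sum((obs - pred_fun(exp(logNm)))^2)
  lo <- log(1e-2); hi <- log(1e9)
  opt <- stats::optimize(sse, c(lo, hi))
  if (min(abs(opt$minimum - c(lo, hi))) < 1e-6)
    warning("fitted Nm pinned at optimization bound")
  Nm <- exp(opt$minimum)
  pred <- pred_fun(Nm)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- 1 - ss_res / ss_tot
  n_loc <- nrow(local)
  z <- stats::qnorm(0.975)
  centre <- (pred + z^2 / (2 * n_loc)) / (1 + z^2 / n_loc)
  half <- z * sqrt(pred * (1 - pred) / n_loc + z^2 / (4 * n_loc^2)) / (1 + z^2 / n_loc)
  ci_lo <- pmax(centre - half, 0)
  ci_hi <- pmin(centre + half, 1)
  cls <- ifelse(obs > ci_hi, "above", ifelse(obs < ci_lo, "below", "neutral"))
  list(m = Nm / N, Nm = Nm, r_squared = r2, d = d, N = N,
       otu = data.frame(otu_id = shared, pool_p = unname(p),
                        obs_freq = unname(obs), pred_freq = unname(pred),
                        ci_lo = unname(ci_lo), ci_hi = unname(ci_hi),
                        class = unname(cls), row.names = NULL,
                        stringsAsFactors = FALSE))
}
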