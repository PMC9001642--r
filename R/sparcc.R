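#' SparCC compositional correlation inference
#'
#' Estimates basis correlations between OTUs from compositional count data.
#' For each of `n_iter` iterations, per-sample fractions are drawn from a
#' Dirichlet posterior (counts + 1 pseudocount), the log-ratio variance
#' matrix `t_ij = var(log(x_i / x_j))` is formed, basis variances are
#' solved from the sparsity-approximation linear system, and correlations
#' `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))` are computed (clamped
#' to `[-1, 1]`). The strongest correlated pairs are iteratively excluded
#' from the basis system (up to `max_exclusions` pairs with `|rho|` above
#' `exclusion_threshold`). The reported matrix is the elementwise median
#' over iterations.
#'
#' OTUs should be pre-filtered to a mean count of at least ~5 reads (the
#' usual working rule for this estimator); see [filter_mean_reads()].
#'
#' @param counts OTU table (samples x OTUs), >= 4 samples, no all-zero OTU.
#' @param n_iter Number of Dirichlet resampling iterations (median taken).
#' @param exclusion_threshold `|rho|` above which a pair may be excluded
#'   from the basis-variance approximation.
#' @param max_exclusions Maximum number of excluded pairs.
#' @param seed Integer seed.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(counts, n_iter = 20, exclusion_threshold = 0.1,
                   max_exclusions = 10, seed = 1) {
  validate_otu_table(counts)
  if (nrow(counts) < 4) stop("SparCC needs at least 4 samples")
  if (any(colSums(counts) == 0))
    stop("all-zero OTU(s) present; filter before calling sparcc: ",
         paste(utils::head(colnames(counts)[colSums(counts) == 0], 5), collapse = ", "))
  set.seed(seed)
  p <- ncol(counts)
  est <- array(NA_real_, c(p, p, n_iter))
  for (it in seq_len(n_iter)) {
    frac <- .dirichlet_fractions(counts)
    est[, , it] <- .sparcc_once(log(frac), exclusion_threshold, max_exclusions)
  }
  rho <- apply(est, c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  rho
}

.dirichlet_fractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow(counts), ncol(counts))
  g / rowSums(g)
}

# single SparCC pass on a log-fraction matrix (samples x OTUs)
.sparcc_once <- function(logx, exclusion_threshold, max_exclusions) {
  p <- ncol(logx)
  v <- apply(logx, 2, stats::var)
  cv <- stats::cov(logx)
  tmat <- outer(v, v, "+") - 2 * cv        # t_ij = var(log x_i - log x_j)
  M <- matrix(1, p, p) + diag(p - 2, p)     # sparsity-approximation system
  trow <- rowSums(tmat)
  excluded <- matrix(FALSE, p, p)
  solve_basis <- function() {
    w <- solve(M, trow)
    w <- pmax(w, .Machine$double.eps)
    r <- (outer(w, w, "+") - tmat) / (2 * sqrt(outer(w, w)))
    pmin(pmax(r, -1), 1)
  }
  rho <- solve_basis()
  for (k in seq_len(max_exclusions)) {
    cand <- abs(rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    top <- which.max(cand)
    if (cand[top] <= exclusion_threshold) break
    ij <- arrayInd(top, dim(cand))
    i <- ij[1]; j <- ij[2]
    # an OTU reduced to a single remaining partner breaks the system; stop
    if (M[i, i] <= 2 || M[j, j] <= 2) break
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, j] <- M[j, i] <- M[i, j] - 1
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    trow[i] <- trow[i] - tmat[i, j]
    trow[j] <- trow[j] - tmat[i, j]
    rho <- solve_basis()
  }
  diag(rho) <- 1
  rho
}

#' Bootstrap pseudo p-values for SparCC correlations
#'
#' The null resamples shuffle every OTU's counts independently across
#' samples (marginals preserved, covariance destroyed), recompute SparCC —
#' at a reduced iteration count by default, for speed — and count how often
#' the null magnitude reaches the observed one:
#' `p_ij = (1 + #{|rho_boot| >= |rho_obs|}) / (n_boot + 1)` (two-sided).
#'
#' @param counts OTU table used for `rho_obs`.
#' @param rho_obs Observed SparCC matrix from [sparcc()].
#' @param n_boot Number of bootstrap resamples (a warning below 10).
#' @param n_iter Dirichlet iterations per bootstrap (default 5).
#' @param seed Integer seed.
#' @return Matrix of pseudo p-values in `(0, 1]` (diagonal 1).
#' @export
sparcc_pvalues <- function(counts, rho_obs, n_boot = 100, n_iter = 5, seed = 1) {
  validate_otu_table(counts)
  if (n_boot < 10) warning("n_boot < 10 gives very coarse p-value resolution")
  if (!all(dim(rho_obs) == ncol(counts))) stop("rho_obs does not match counts")
  set.seed(seed)
  p <- ncol(counts)
  hits <- matrix(0, p, p)
  obs <- abs(rho_obs)
  for (b in seq_len(n_boot)) {
    perm <- apply(counts, 2, sample)
    rownames(perm) <- rownames(counts)
    rb <- sparcc(perm, n_iter = n_iter,
                 seed = sample.int(.Machine$integer.max, 1))
    hits <- hits + (abs(rb) >= obs)
  }
  pv <- (1 + hits) / (n_boot + 1)
  diag(pv) <- 1
  dimnames(pv) <- dimnames(rho_obs)
  pv
}

#' Filter OTUs by mean read count
#'
#' Keeps OTUs whose mean count across samples is at least `min_mean`
#' (default 5, the pre-filter used ahead of SparCC network construction).
#'
#' @param counts OTU table (samples x OTUs).
#' @param min_mean Minimum mean reads per OTU.
#' @return The filtered table.
#' @export
filter_mean_reads <- function(counts, min_mean = 5) {
  counts[, colMeans(counts) >= min_mean, drop = FALSE]
}
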