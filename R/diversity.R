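#' Per-sample alpha diversity
#'
#' Computes observed richness, Pielou evenness (natural-log Shannon divided
#' by `log(richness)`, defined 0 when richness <= 1), and — when a rooted
#' phylogeny is supplied — Faith's phylogenetic diversity including the
#' root-spanning path.
#'
#' @param counts OTU table (samples x OTUs), ideally rarefied to even depth
#'   (a warning is emitted otherwise).
#' @param tree Optional rooted `ape::phylo` whose tips cover all present OTUs.
#' @return data.frame with `sample_id`, `richness`, `evenness`, and `pd`
#'   (NA when no tree is given).
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  validate_otu_table(counts)
  tot <- rowSums(counts)
  if (length(unique(tot)) > 1)
    warning("samples have unequal depth; rarefy before comparing alpha diversity")
  richness <- rowSums(counts > 0)
  shannon <- vegan::diversity(counts, index = "shannon", base = exp(1))
  evenness <- ifelse(richness <= 1, 0, shannon / log(richness))
  pd <- rep(NA_real_, nrow(counts))
  if (!is.null(tree)) {
    present <- colnames(counts)[colSums(counts) > 0]
    missing <- setdiff(present, tree$tip.label)
    if (length(missing))
      stop("OTUs missing from tree: ", paste(missing, collapse = ", "))
    # resolve basal polytomies with zero-length edges so the root-spanning
    # convention applies; total branch length is unchanged
    if (!ape::is.rooted(tree) || !ape::is.binary(tree))
      tree <- ape::multi2di(tree)
    pd <- picante::pd(counts, tree, include.root = TRUE)$PD
  }
  data.frame(sample_id = rownames(counts), richness = richness,
             evenness = evenness, pd = pd, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Coefficient of variation per group
#'
#' CV = sample standard deviation / mean within each group; groups whose
#' mean is zero (or with fewer than two members) yield `NA`.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @return Named numeric vector of CVs, one per group level.
#' @export
group_cv <- function(values, groups) {
  vapply(split(values, groups), function(v) {
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    stats::sd(v) / m
  }, numeric(1))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = 1 - sum_j min(a_j, b_j)` for relative-abundance rows
#' (equivalently the usual count form when row sums are equal).
#'
#' @param relabund Relative-abundance matrix (rows sum to 1) or a rarefied
#'   count table with equal row sums.
#' @return A `dist` object.
#' @export
bray_curtis <- function(relabund) {
  if (anyNA(relabund) || any(relabund < 0)) stop("abundances must be non-negative")
  vegan::vegdist(relabund, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling (Gower double-centering) of a distance matrix.
#' Axes are ordered by eigenvalue; the proportion explained is taken over
#' the positive eigenvalues only, negative eigenvalues are reported but
#' their axes discarded.
#'
#' @param d A `dist` or symmetric matrix of dissimilarities.
#' @return List with `coordinates` (samples x positive axes), `eigenvalues`
#'   (all, sorted decreasing), and `proportion_explained`.
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(m)
  # cmdscale warns when semi-metric input yields negative eigenvalues; we
  # report those eigenvalues ourselves, so the warning is redundant
  res <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- res$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- res$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- sprintf("PCoA%d", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = eig[pos] / sum(eig[pos]))
}

#' ANOSIM permutation test
#'
#' Analysis of similarity on a dissimilarity matrix: the R statistic
#' contrasts mean between- and within-group ranks of the pairwise
#' distances, and the p-value is `(b + 1) / (n_perm + 1)` over label
#' permutations.
#'
#' @param d `dist` or symmetric matrix.
#' @param labels Group labels (>= 2 groups, each of size >= 2).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `statistic` (R), `p`, `n_perm`, `seed`.
#' @export
anosim_test <- function(d, labels, n_perm = 999, seed = 1) {
  .check_groups(labels)
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(as.matrix(d)), grouping = factor(labels),
                       permutations = n_perm)
  list(statistic = unname(fit$statistic), p = fit$signif,
       n_perm = n_perm, seed = seed)
}

#' PERMANOVA permutation test
#'
#' Permutational multivariate analysis of variance (Anderson's partition of
#' squared dissimilarities) giving a pseudo-F, an R-squared
#' (`SS_between / SS_total`), and a permutation p-value.
#'
#' @inheritParams anosim_test
#' @return List with `statistic` (pseudo-F), `r_squared`, `p`, `n_perm`,
#'   `seed`.
#' @export
permanova_test <- function(d, labels, n_perm = 999, seed = 1) {
  .check_groups(labels)
  set.seed(seed)
  df <- data.frame(grp = factor(labels))
  fit <- vegan::adonis2(stats::as.dist(as.matrix(d)) ~ grp, data = df,
                        permutations = n_perm)
  list(statistic = fit$F[1], r_squared = fit$R2[1], p = fit$`Pr(>F)`[1],
       n_perm = n_perm, seed = seed)
}

.check_groups <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 samples")
  invisible(tab)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (elementwise >= the raw values).
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Within-group dispersion (distance to group centroid)
#'
#' Distances from each sample to its group centroid in the full principal
#' coordinate space, with the imaginary correction for negative-eigenvalue
#' axes (the `betadisper` convention). Singleton groups yield `NA` with a
#' warning.
#'
#' @param d `dist` or symmetric matrix.
#' @param labels Group labels.
#' @return data.frame with `sample_id`, `group`, `dist_to_centroid`.
#' @export
group_dispersion <- function(d, labels) {
  m <- as.matrix(d)
  tab <- table(labels)
  if (any(tab < 2))
    warning("singleton group(s): ", paste(names(tab)[tab < 2], collapse = ", "))
  fit <- vegan::betadisper(stats::as.dist(m), group = factor(labels), type = "centroid")
  dist_c <- fit$distances
  dist_c[labels %in% names(tab)[tab < 2]] <- NA_real_
  data.frame(sample_id = rownames(m), group = as.character(labels),
             dist_to_centroid = unname(dist_c), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson correlations between taxon abundances and metadata covariates
#'
#' For every (taxon, covariate) pair, the Pearson r and its two-sided
#' t-test p-value over paired complete observations; pairs with zero
#' variance (or fewer than 3 complete observations) are `NA`.
#'
#' @param abundances Matrix (samples x taxa) of abundances.
#' @param covariates data.frame or matrix (samples x covariates), numeric.
#' @return List of matrices `r` and `p` (taxa x covariates).
#' @export
correlate_with_metadata <- function(abundances, covariates) {
  abundances <- as.matrix(abundances)
  covariates <- as.matrix(covariates)
  if (nrow(abundances) != nrow(covariates)) stop("sample counts differ")
  bad <- colSums(!is.na(covariates)) == 0
  if (any(bad))
    stop("all-missing covariate(s): ", paste(colnames(covariates)[bad], collapse = ", "))
  r <- p <- matrix(NA_real_, ncol(abundances), ncol(covariates),
                   dimnames = list(colnames(abundances), colnames(covariates)))
  for (j in seq_len(ncol(covariates))) {
    y <- covariates[, j]
    for (i in seq_len(ncol(abundances))) {
      x <- abundances[, i]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p)
}
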