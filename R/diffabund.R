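#' Simplified negative-binomial Wald test for differential abundance
#'
#' A deliberately lightweight two-condition differential-abundance test in
#' the negative-binomial family: median-of-ratios size factors, per-OTU
#' moment dispersion estimates shrunk 50% toward a `a0 + a1/mu` trend, and
#' a Wald z on the log2 fold change with normal p-values and BH adjustment.
#' It is an approximation of the DESeq2-style workflow, not a clone — there
#' is no outlier replacement and no independent filtering.
#'
#' @param counts OTU table (samples x OTUs), raw counts for one habitat.
#' @param condition Two-level factor (or vector) over samples; the fold
#'   change is level 2 over level 1.
#' @param alpha FDR threshold for calling direction (default 0.05).
#' @param pseudo Pseudo-mean added to normalized condition means before
#'   taking logs (stabilizes OTUs absent from one arm).
#' @return data.frame with `otu_id`, `base_mean`, `log2fc`, `se`, `p`,
#'   `fdr`, `direction` (`enriched` / `depleted` / `ns`).
#' @export
diff_abundance <- function(counts, condition, alpha = 0.05, pseudo = 0.5) {
  validate_otu_table(counts)
  condition <- factor(condition)
  if (nlevels(condition) != 2) stop("condition must have exactly 2 levels")
  if (any(table(condition) < 2)) stop("each condition needs >= 2 samples")

  sf <- .size_factors(counts)
  q <- sweep(counts, 1, sf, "/")
  a <- q[condition == levels(condition)[1], , drop = FALSE]
  b <- q[condition == levels(condition)[2], , drop = FALSE]
  mu_a <- colMeans(a); mu_b <- colMeans(b)
  n_a <- nrow(a); n_b <- nrow(b)

  # method-of-moments dispersion pooled within conditions, then 50% shrink
  # toward a fitted a0 + a1/mu trend
  pool_var <- (colSums(sweep(a, 2, mu_a)^2) + colSums(sweep(b, 2, mu_b)^2)) /
    (n_a + n_b - 2)
  mu_pool <- (n_a * mu_a + n_b * mu_b) / (n_a + n_b)
  disp_mom <- pmax((pool_var - mu_pool) / mu_pool^2, 0)
  ok <- is.finite(disp_mom) & mu_pool > 0
  disp_trend <- rep(0, ncol(counts))
  use <- ok & disp_mom > 0
  if (sum(use) >= 5) {
    fit <- stats::lm(disp_mom[use] ~ I(1 / mu_pool[use]))
    co <- stats::coef(fit)
    disp_trend <- pmax(co[1] + co[2] / mu_pool, 0)
    disp_trend[!is.finite(disp_trend)] <- 0
  }
  disp <- 0.5 * disp_mom + 0.5 * disp_trend
  disp[!ok] <- 0

  lfc <- log2((mu_b + pseudo) / (mu_a + pseudo))
  # delta method on the log2 condition means under Var(q) = mu + disp * mu^2
  v_a <- (mu_a + disp * mu_a^2) / n_a
  v_b <- (mu_b + disp * mu_b^2) / n_b
  se <- sqrt(v_a / (mu_a + pseudo)^2 + v_b / (mu_b + pseudo)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[se == 0 & lfc == 0] <- 1
  fdr <- bh_adjust(p)
  direction <- ifelse(fdr < alpha & lfc > 0, "enriched",
                      ifelse(fdr < alpha & lfc < 0, "depleted", "ns"))
  data.frame(otu_id = colnames(counts), base_mean = mu_pool, log2fc = lfc,
             se = se, p = p, fdr = fdr, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

# DESeq-style median-of-ratios size factors; reference = OTUs observed in
# every sample, with a positive-counts fallback when none exists
.size_factors <- function(counts) {
  ref <- colSums(counts > 0) == nrow(counts)
  if (!any(ref)) {
    logg <- colMeans(ifelse(counts > 0, log(counts), NA))
    logg[!is.finite(logg)] <- NA
    ratios <- log(counts) - rep(logg, each = nrow(counts))
    sf <- exp(apply(ratios, 1, function(r) stats::median(r[is.finite(r)], na.rm = TRUE)))
  } else {
    logg <- colMeans(log(counts[, ref, drop = FALSE]))
    ratios <- log(counts[, ref, drop = FALSE]) - rep(logg, each = nrow(counts))
    sf <- exp(apply(ratios, 1, stats::median))
  }
  if (anyNA(sf) || any(sf <= 0)) stop("size factors undefined; too many zero counts")
  sf / exp(mean(log(sf)))
}
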