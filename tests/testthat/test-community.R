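test_that("alpha diversity: richness, evenness, and Faith PD behave as defined", {
  m <- matrix(c(5, 5, 5, 5), 1, dimnames = list("s1", sprintf("otu%d", 1:4)))
  a <- alpha_diversity(m)
  expect_equal(a$richness, 4)
  expect_equal(a$evenness, 1)
  expect_true(is.na(a$pd))

  single <- matrix(c(9, 0, 0, 0), 1, dimnames = list("s1", sprintf("otu%d", 1:4)))
  expect_equal(alpha_diversity(single)$evenness, 0)

  tr <- star_tree(4)
  m3 <- matrix(c(1, 1, 1, 0), 1, dimnames = list("s1", sprintf("otu%d", 1:4)))
  expect_equal(alpha_diversity(m3, tree = tr)$pd, 3)

  m_bad <- matrix(1, 1, 5, dimnames = list("s1", sprintf("otu%d", 1:5)))
  expect_error(alpha_diversity(m_bad, tree = tr), "otu5")
})

test_that("coefficient of variation is sd/mean and scale invariant", {
  expect_equal(unname(group_cv(c(10, 10, 10), rep("g", 3))), 0)
  expect_equal(unname(group_cv(c(8, 12), rep("g", 2))), 2 * sqrt(2) / 10)
  v <- c(3, 9, 4, 8, 2)
  expect_equal(group_cv(v, rep("g", 5)), group_cv(7.3 * v, rep("g", 5)))
  expect_true(is.na(group_cv(c(-1, 1), rep("g", 2))))
  expect_true(is.na(group_cv(5, "g")))
})

test_that("Bray-Curtis matches the min-sum form", {
  m <- rbind(s1 = c(0.5, 0.5, 0), s2 = c(0, 0.5, 0.5), s3 = c(0.5, 0.5, 0))
  colnames(m) <- paste0("o", 1:3)
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 0)
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.matrix(bray_curtis(disj))["a", "b"], 1)
})

test_that("PCoA reproduces Euclidean configurations and degenerate symmetries", {
  set.seed(2)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  d <- dist(pts)
  ord <- pcoa_ordination(d)
  expect_equal(as.matrix(dist(ord$coordinates)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(ord$proportion_explained), 1)

  # three equidistant points: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(paste0("s", 1:3), paste0("s", 1:3))
  orde <- pcoa_ordination(eq)
  pos <- orde$eigenvalues[orde$eigenvalues > 1e-10]
  expect_equal(pos[1], pos[2])

  # duplicated sample lands on coincident coordinates
  pts2 <- rbind(pts, s7 = pts[1, ])
  ord2 <- pcoa_ordination(dist(pts2))
  expect_equal(ord2$coordinates["s7", ], ord2$coordinates["s1", ],
               tolerance = 1e-8)
  ns <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa_ordination(ns), "symmetric")
})

test_that("ANOSIM and PERMANOVA detect separation and validate groups", {
  set.seed(5)
  a <- matrix(rnorm(5 * 3, 0), 5, 3)
  b <- matrix(rnorm(5 * 3, 12), 5, 3)
  x <- rbind(a, b)
  rownames(x) <- paste0("s", 1:10)
  d <- dist(x)
  lab <- rep(c("A", "B"), each = 5)
  an <- anosim_test(d, lab, n_perm = 199, seed = 1)
  expect_equal(an$statistic, 1)
  expect_lte(an$p, 0.05)
  pm <- permanova_test(d, lab, n_perm = 199, seed = 1)
  expect_gt(pm$r_squared, 0.95)
  expect_lte(pm$p, 0.05)
  # reordering samples leaves R^2 unchanged
  perm <- sample(10)
  pm2 <- permanova_test(as.matrix(d)[perm, perm], lab[perm], n_perm = 49, seed = 1)
  expect_equal(pm2$r_squared, pm$r_squared)
  expect_error(anosim_test(d, c("A", rep("B", 9)), seed = 1), "at least 2")
})

test_that("BH adjustment follows step-up with monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.001, 0.2, 0.9, 0.04)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("group dispersion: centroid distances honor geometry", {
  m <- rbind(s1 = c(10, 0, 0), s2 = c(10, 0, 0), s3 = c(10, 0, 0),
             s4 = c(0, 6, 4), s5 = c(0, 2, 8))
  colnames(m) <- paste0("o", 1:3)
  d <- bray_curtis(relative_abundance(m))
  disp <- group_dispersion(d, c("A", "A", "A", "B", "B"))
  expect_equal(disp$dist_to_centroid[1:3], rep(0, 3), tolerance = 1e-10)
  d45 <- as.matrix(d)["s4", "s5"]
  expect_equal(disp$dist_to_centroid[4:5], rep(d45 / 2, 2), tolerance = 1e-10)
})

test_that("metadata correlations recover exact linear relations", {
  set.seed(3)
  ab <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("o", 1:3)))
  cov <- data.frame(up = ab[, 1], down = -ab[, 2], noise = rnorm(10))
  res <- correlate_with_metadata(ab, cov)
  expect_equal(res$r["o1", "up"], 1)
  expect_equal(res$r["o2", "down"], -1)
  expect_lt(res$p["o1", "up"], 1e-8)
  flat <- cbind(ab, o4 = 1)
  expect_true(is.na(correlate_with_metadata(flat, cov)$r["o4", "up"]))
  expect_error(correlate_with_metadata(ab, data.frame(x = rep(NA_real_, 10))),
               "all-missing")
})
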