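test_that("betaMNTD matches hand cases and the brute-force double loop", {
  tiny <- ape::read.tree(text = "(A:2,B:2);")
  xa <- c(A = 5, B = 0); xb <- c(A = 0, B = 3)
  expect_equal(beta_mntd(xa, xb, tiny), 4)      # two singletons, distance 4
  expect_equal(beta_mntd(xa, xa, tiny), 0)      # identical communities

  set.seed(9)
  tr <- ape::rphylo(20, 1, 0)
  tr$tip.label <- paste0("t", 1:20)
  D <- ape::cophenetic.phylo(tr)
  cm <- t(rmultinom(6, 200, rep(1 / 20, 20)))
  colnames(cm) <- tr$tip.label; rownames(cm) <- paste0("s", 1:6)
  impl <- beta_mntd_matrix(cm, D)
  f <- cm / rowSums(cm)
  brute <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6) {
    pa <- which(cm[a, ] > 0); pb <- which(cm[b, ] > 0)
    s1 <- sum(vapply(pa, function(i) f[a, i] * min(D[i, pb]), numeric(1)))
    s2 <- sum(vapply(pb, function(j) f[b, j] * min(D[j, pa]), numeric(1)))
    brute[a, b] <- 0.5 * (s1 + s2)
  }
  expect_equal(unname(impl), brute, tolerance = 1e-10)

  # independent cross-check against the comdistnt implementation
  ref <- as.matrix(picante::comdistnt(cm, D, abundance.weighted = TRUE))
  expect_equal(unname(impl), unname(ref), tolerance = 1e-8)
  expect_error(beta_mntd(c(Z = 1), c(A = 1, Z = 0), tiny), "missing")
})

test_that("betaNTI is invariant to branch-length scaling and flags sd = 0", {
  set.seed(10)
  tr <- ape::rphylo(25, 1, 0); tr$tip.label <- paste0("t", 1:25)
  D <- ape::cophenetic.phylo(tr)
  cm <- t(rmultinom(5, 150, rep(1 / 25, 25)))
  colnames(cm) <- tr$tip.label; rownames(cm) <- paste0("s", 1:5)
  b1 <- suppressWarnings(bnti(cm, D, n_null = 99, seed = 3))
  b2 <- suppressWarnings(bnti(cm, D * 7.3, n_null = 99, seed = 3))
  expect_equal(b1, b2, tolerance = 1e-10)
  expect_true(isSymmetric(b1))
  # identical presence everywhere -> null sd 0 -> NA with warning
  cm_id <- rbind(a = rep(5, 25), b = rep(7, 25))
  colnames(cm_id) <- tr$tip.label
  expect_warning(bna <- bnti(cm_id, D, n_null = 19, seed = 1), "sd is 0")
  expect_true(is.na(bna[1, 2]))
})

test_that("Raup-Crick hits its extremes and symmetry contract", {
  set.seed(11)
  w <- rlnorm(40); p <- w / sum(w)
  base <- t(rmultinom(10, 400, p))
  colnames(base) <- paste0("o", 1:40); rownames(base) <- paste0("s", 1:10)
  dup <- rbind(base, dup1 = base[1, ])
  rc <- rc_bray(dup[c(1, 11), ], n_null = 99, seed = 2)
  expect_equal(rc[1, 2], -1)           # identical pair below every null
  rc_all <- rc_bray(base[1:4, ], n_null = 49, seed = 5)
  expect_true(isSymmetric(rc_all))
  expect_true(all(abs(rc_all) <= 1))
  expect_error(rc_bray(base / 2), "integer")
})

test_that("the null community generator honors richness and total", {
  set.seed(12)
  occ <- c(5, 3, 1, 4, 2, 0)
  relab <- c(0.3, 0.2, 0.1, 0.25, 0.15, 0)
  x <- rc_null_community(occ, relab, richness = 3, total = 100)
  expect_equal(sum(x), 100)
  expect_equal(sum(x > 0), 3)
  expect_equal(x[6], 0)                # zero-occupancy taxon never drawn
  expect_error(rc_null_community(occ, relab, richness = 6, total = 10),
               "exceeds")
})

test_that("process partitioning follows the decision rules exactly", {
  bn <- matrix(c(0, 3, 0, 0,
                 3, 0, -3, 0,
                 0, -3, 0, 0.5,
                 0, 0, 0.5, 0), 4, 4,
               dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  rc <- matrix(c(0, -0.99, 0, 0.99,
                 -0.99, 0, 0.99, -0.99,
                 0, 0.99, 0, 0.2,
                 0.99, -0.99, 0.2, 0), 4, 4,
               dimnames = dimnames(bn))
  pp <- partition_processes(bn, rc)
  get <- function(a, b) pp$pairs$process[pp$pairs$sample_a == a & pp$pairs$sample_b == b]
  expect_equal(get("s1", "s2"), "heterogeneous_selection") # bnti 3 beats rc
  expect_equal(get("s2", "s3"), "homogeneous_selection")
  expect_equal(get("s1", "s4"), "dispersal_limitation")    # |bnti|<2, rc>0.95
  expect_equal(get("s2", "s4"), "homogenizing_dispersal")
  expect_equal(get("s3", "s4"), "undominated")
  expect_equal(sum(pp$fractions), 1)
  bn[1, 3] <- bn[3, 1] <- NA
  pp2 <- partition_processes(bn, rc)
  expect_equal(nrow(pp2$excluded), 1)
  expect_equal(sum(pp2$fractions), 1)
})

test_that("Sloan fit recovers a known Nm from model-generated frequencies", {
  set.seed(13)
  p <- sort(rlnorm(60, -5, 1.5)); p <- p / sum(p)   # pool shares (simplex)
  names(p) <- paste0("o", 1:60)
  N <- 1000; Nm_true <- 120; d <- 1 / N
  freq <- 1 - pbeta(d, Nm_true * p, Nm_true * (1 - p))
  # build a local table whose occurrence frequencies equal freq exactly
  n_loc <- 200
  occ_n <- round(freq * n_loc)
  local <- sapply(seq_along(p), function(j) {
    x <- numeric(n_loc); if (occ_n[j] > 0) x[seq_len(occ_n[j])] <- 1
    x
  })
  colnames(local) <- names(p); rownames(local) <- paste0("s", 1:n_loc)
  fit <- sloan_fit(local, p, N = N, d = d)
  expect_lt(abs(fit$Nm - Nm_true) / Nm_true, 0.1)
  expect_gt(fit$r_squared, 0.95)
  expect_true(all(fit$otu$pred_freq >= 0 & fit$otu$pred_freq <= 1))
  expect_true(all(fit$otu$class %in% c("neutral", "above", "below")))
  # monotone limits of the occurrence curve
  expect_lt(1 - pbeta(d, 50 * 1e-6, 50 * (1 - 1e-6)), 0.01)
  expect_gt(1 - pbeta(d, 50 * 0.999, 50 * 0.001), 0.99)
  expect_error(sloan_fit(local[, 1:3], p[1:3], N = N), "at least 5")
})
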