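test_that("multihabitat generator honors the unbalanced design and is deterministic", {
  sim <- simulate_multihabitat_experiment(seed = 7)
  tab <- table(sim$metadata$group, sim$metadata$habitat)
  expect_equal(unname(tab["CK", "water"]), 4)
  expect_equal(unname(tab["CK", "biofloc"]), 2)
  expect_equal(unname(tab["CN15", "gut"]), 6)
  expect_equal(nrow(sim$counts), sum(tab))
  sim2 <- simulate_multihabitat_experiment(seed = 7)
  expect_identical(sim$counts, sim2$counts)
  expect_error(simulate_multihabitat_experiment(
    replicates = matrix(0, 3, 3, dimnames = list(c("CK", "CN10", "CN15"),
                                                 c("water", "biofloc", "gut")))),
    "replicate")
  expect_error(simulate_multihabitat_experiment(kappa = 1.2), "kappa")
})

test_that("kappa = 1 collapses habitat structure; kappa = 0 separates habitats", {
  s1 <- simulate_multihabitat_experiment(kappa = 1, seed = 3)
  d1 <- as.matrix(bray_curtis(relative_abundance(s1$counts)))
  hb <- s1$metadata$habitat
  within <- mean(d1[outer(hb, hb, "==") & upper.tri(d1)])
  between <- mean(d1[outer(hb, hb, "!=") & upper.tri(d1)])
  expect_lt(abs(between - within), 0.05)

  s0 <- simulate_multihabitat_experiment(kappa = 0, seed = 3)
  an <- anosim_test(bray_curtis(relative_abundance(s0$counts)),
                    s0$metadata$habitat, n_perm = 199, seed = 1)
  expect_gt(an$statistic, 0.8)
  expect_lt(an$p, 0.05)
})

test_that("intended core OTUs are recovered exactly by the classifier", {
  sim <- simulate_multihabitat_experiment(seed = 7)
  cl <- classify_otus(sim$counts, sim$metadata)
  truth_core <- names(sim$truth$class)[sim$truth$class == "core"]
  expect_setequal(names(cl$class)[cl$class == "core"], truth_core)
})

test_that("neutral dynamics reduce to metacommunity sampling at m = 1", {
  set.seed(1)
  w <- rlnorm(50, 0, 1)
  p <- w / sum(w)
  sim <- simulate_neutral_community(p, N = 500, m = 1, n_samples = 20, seed = 2)
  expect_true(all(rowSums(sim$counts) == 500))
  expect_gt(cor(colMeans(sim$counts) / 500, p), 0.98)
  sim2 <- simulate_neutral_community(p, N = 500, m = 1, n_samples = 20, seed = 2)
  expect_identical(sim$counts, sim2$counts)
  expect_error(simulate_neutral_community(p, m = 0), "m must")
  expect_error(simulate_neutral_community(p * 2, m = 0.5), "sum to 1")
  expect_error(simulate_neutral_community(p, N = 5, m = 0.5), "N must")
})

test_that("selection generator respects limits and shapes", {
  sel <- simulate_selected_communities(n_tips = 30, optima = c(A = 0),
                                       sigma = 1e6, N = 2000,
                                       n_samples_per_habitat = 5, seed = 4)
  # sigma -> Inf: habitat weights collapse to the base abundances
  expect_lt(max(abs(sel$truth$weights[1, ] - sel$truth$base)), 1e-6)
  expect_s3_class(sel$tree, "phylo")
  expect_true(all(rowSums(sel$counts) == 2000))
  expect_error(simulate_selected_communities(n_tips = 3), "n_tips")
  expect_error(simulate_selected_communities(sigma = 0), "sigma")
})

test_that("compositional generator validates the basis and hits the depth", {
  R <- diag(5)
  sim <- simulate_compositional_counts(R, n_samples = 10, depth = 1000, seed = 1)
  expect_true(all(rowSums(sim$counts) == 1000))
  bad <- matrix(0.99, 3, 3); diag(bad) <- 1; bad[1, 2] <- -0.99
  expect_error(simulate_compositional_counts(bad), "symmetric")
  notpsd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(simulate_compositional_counts(notpsd), "positive-semidefinite")
})

test_that("source/sink generator produces identifiable mixtures", {
  prof <- rbind(a = c(0.5, 0.5, 0, 0), b = c(0, 0, 0.5, 0.5))
  colnames(prof) <- paste0("t", 1:4)
  pure <- simulate_source_sinks(prof, pi = c(1, 0, 0), depth = 500,
                                n_sinks = 2, seed = 1)
  sink_support <- colnames(pure$sinks)[colSums(pure$sinks) > 0]
  expect_true(all(sink_support %in% c("t1", "t2")))
  unk <- simulate_source_sinks(prof, pi = c(0, 0, 1), depth = 500,
                               n_sinks = 1, seed = 1)
  expect_true(all(unk$sinks[, colnames(prof)] == 0))
  expect_error(simulate_source_sinks(prof, pi = c(0.5, 0.5)), "unknown")
  expect_error(simulate_source_sinks(prof, pi = c(0.7, 0.6, -0.3)), "sum to 1")
})

test_that("planted network generator validates probabilities", {
  expect_error(simulate_planted_network(c(10, 10), p_within = 0.1,
                                        p_between = 0.3), "exceed")
  expect_error(simulate_planted_network(c(10, 10), p_within = 1.3,
                                        p_between = 0.1), "probabilities")
  pn <- simulate_planted_network(c(8, 8, 8), p_within = 0.5, p_between = 0.05,
                                 seed = 3)
  expect_equal(igraph::vcount(pn$graph), 24)
  expect_equal(unname(table(pn$truth$membership)[1]), 8)
  pn2 <- simulate_planted_network(c(8, 8, 8), p_within = 0.5, p_between = 0.05,
                                  seed = 3)
  expect_true(igraph::identical_graphs(pn$graph, pn2$graph))
})
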