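test_that("edge selection respects inclusive thresholds and monotonicity", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.6    # exactly at threshold -> included
  rho[3, 4] <- rho[4, 3] <- -0.7
  rho[1, 3] <- rho[3, 1] <- 0.45
  dimnames(rho) <- list(paste0("o", 1:4), paste0("o", 1:4))
  p <- matrix(0.01, 4, 4, dimnames = dimnames(rho)); diag(p) <- 1

  g <- build_network(rho, p, rho_min = 0.6)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2)
  expect_true(any(el[, 1] == "o1" & el[, 2] == "o2"))
  expect_setequal(igraph::E(g)$sign, c("positive", "negative"))

  g_none <- build_network(rho, p, rho_min = 1.01, keep_isolated = TRUE)
  expect_equal(igraph::ecount(g_none), 0)
  g_low <- build_network(rho, p, rho_min = 0.4)
  expect_true(igraph::ecount(g_low) >= igraph::ecount(g))
  expect_error(build_network(rho, p[1:3, 1:3]), "aligned")
})

test_that("topology metrics match hand-enumerated graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  tm <- topology_metrics(tri)
  expect_equal(tm$summary$avg_clustering, 1)
  expect_equal(tm$summary$avg_path_length, 1)

  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  ts <- topology_metrics(star)
  expect_equal(ts$nodes$degree[ts$nodes$otu_id == "hub"], 3)
  expect_equal(sort(unique(ts$nodes$degree)), c(1, 3))
  expect_equal(ts$nodes$betweenness[ts$nodes$otu_id == "hub"], 3)

  g2 <- two_cliques(5)
  planted <- setNames(rep(1:2, each = 5), igraph::V(g2)$name)
  tq <- topology_metrics(g2, modules = planted)
  expect_equal(tq$summary$modularity, 0.5)
  expect_error(topology_metrics(igraph::make_empty_graph(0)), "empty")
})

test_that("greedy module detection recovers planted blocks", {
  pn <- simulate_planted_network(c(20, 20, 20), p_within = 0.4, p_between = 0,
                                 seed = 6)
  tm <- topology_metrics(pn$graph)
  q_planted <- igraph::modularity(pn$graph,
                                  pn$truth$membership[igraph::V(pn$graph)$name])
  expect_gte(tm$summary$modularity, q_planted - 0.02)
  # with no between-block edges the detected partition cuts no edge
  cross <- igraph::crossing(igraph::make_clusters(
    pn$graph, as.integer(factor(tm$modules))), pn$graph)
  expect_equal(sum(cross), 0)
})

test_that("Zi-Pi roles follow their analytic definitions", {
  pn <- simulate_planted_network(rep(12, 4), p_within = 0.4, p_between = 0.05,
                                 connectors = list(list(block = 1, degree = 8)),
                                 seed = 2)
  zp <- zipi(pn$graph, pn$truth$membership)
  conn_row <- zp[zp$otu_id == pn$truth$connectors, ]
  expect_equal(conn_row$pi, 0.75)   # 1 - 4 * (1/4)^2
  expect_equal(conn_row$role, "connector")

  # a node with all edges inside its own module has Pi = 0
  g2 <- two_cliques(4)
  planted <- setNames(rep(1:2, each = 4), igraph::V(g2)$name)
  zp2 <- zipi(g2, planted)
  expect_equal(zp2$pi, rep(0, 8))
  expect_true(all(zp2$zi == 0))     # degree-uniform modules

  hub <- simulate_planted_network(rep(15, 3), p_within = 0.25, p_between = 0.02,
                                  hubs = list(list(block = 1, degree = 14)),
                                  seed = 4)
  zph <- suppressWarnings(zipi(hub$graph, hub$truth$membership))
  hrow <- zph[zph$otu_id == hub$truth$hubs, ]
  expect_gt(hrow$zi, 2.5)
  expect_true(hrow$role %in% c("module_hub", "network_hub"))

  iso <- igraph::make_empty_graph(2, directed = FALSE) + igraph::edges(integer(0))
  igraph::V(iso)$name <- c("a", "b")
  expect_warning(zpi <- zipi(iso, c(a = 1, b = 1)), "isolated")
  expect_true(all(zpi$role == "peripheral"))
})
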