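# fixtures shared across test files; everything is generated in code

toy_counts <- function(nr = 3, nc = 4, seed = 1, max = 20) {
  set.seed(seed)
  m <- matrix(rpois(nr * nc, max), nr, nc,
              dimnames = list(sprintf("s%d", seq_len(nr)),
                              sprintf("otu%d", seq_len(nc))))
  storage.mode(m) <- "double"
  m
}

write_tsv_table <- function(m, path = tempfile(fileext = ".tsv")) {
  write_otu_table(m, path)
  path
}

# unit-branch star tree over n tips
star_tree <- function(n = 4) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- sprintf("otu%d", seq_len(n))
  tr
}

# two disconnected cliques of size k, named nodes
two_cliques <- function(k = 5) {
  g <- igraph::disjoint_union(igraph::make_full_graph(k), igraph::make_full_graph(k))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(2 * k))
  g
}

closed_form_nc_complete <- function(n) log((exp(n - 1) + (n - 1) * exp(-1)) / n)
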