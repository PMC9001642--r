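test_that("occurrence-pattern classification follows the definitions", {
  md <- expand.grid(group = c("G1", "G2", "G3"), habitat = c("w", "b", "g"),
                    rep = 1:2, stringsAsFactors = FALSE)
  md$sample_id <- sprintf("%s_%s_%d", md$group, md$habitat, md$rep)
  n <- nrow(md)
  counts <- matrix(0, n, 5,
                   dimnames = list(md$sample_id,
                                   c("core1", "grpspec1", "sampspec1",
                                     "precedence", "diag")))
  counts[, "core1"] <- 1                             # everywhere
  counts[md$group == "G2", "grpspec1"] <- 2          # all habitats of one group
  counts[md$habitat == "w", "sampspec1"] <- 3        # one habitat, all groups
  counts[md$group == "G1" & md$habitat %in% c("w", "b"), "precedence"] <- 1
  # the ambiguous diagonal: all habitats overall, no complete group
  counts[md$group == "G1" & md$habitat == "w", "diag"] <- 1
  counts[md$group == "G2" & md$habitat == "b", "diag"] <- 1
  counts[md$group == "G3" & md$habitat == "g", "diag"] <- 1

  cl <- classify_otus(counts, md)$class
  expect_equal(unname(cl["core1"]), "core")
  expect_equal(unname(cl["grpspec1"]), "group_specific")
  expect_equal(unname(cl["sampspec1"]), "sample_specific")
  # habitat-subset rule takes precedence over the group rule
  expect_equal(unname(cl["precedence"]), "sample_specific")
  expect_equal(unname(cl["diag"]), "group_specific")
  # partition is exhaustive over detected OTUs
  expect_equal(length(cl), 5)
})

test_that("classification errors on missing cells and respects detection floor", {
  md <- data.frame(sample_id = c("a", "b"), group = c("G1", "G1"),
                   habitat = c("w", "w"), stringsAsFactors = FALSE)
  md2 <- rbind(md, data.frame(sample_id = "c", group = "G2", habitat = "g"))
  counts <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), c("x", "y")))
  expect_error(classify_otus(counts, md2), "empty cell")

  sim <- simulate_multihabitat_experiment(seed = 2)
  cl <- classify_otus(sim$counts, sim$metadata)
  detected <- sum(colSums(sim$counts) > 0)
  expect_equal(length(cl$class), detected)
  cl2 <- classify_otus(sim$counts, sim$metadata, min_samples = 2)
  expect_lte(sum(cl2$class == "core"), sum(cl$class == "core"))
})

test_that("Venn regions are exact set algebra", {
  v <- venn_regions(list(A = c("x", "y"), B = c("p", "q")))
  expect_equal(unname(v["A&B"]), 0)
  v2 <- venn_regions(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(unname(v2["A&B"]), 2)
  expect_equal(unname(v2["A"]), 0)
  shared <- sprintf("s%02d", 1:10)
  v3 <- venn_regions(list(A = c(shared, "a1"), B = c(shared, "b1", "b2"),
                          C = shared))
  expect_equal(unname(v3["A&B&C"]), 10)
  expect_equal(unname(v3["A&B"]), 0)
  expect_equal(unname(v3["B"]), 2)
  expect_equal(sum(v3), 13)
  expect_error(venn_regions(list(A = "x")), "at least 2")
})

test_that("Levins niche breadth spans [1, n] with the expected extremes", {
  m <- rbind(s1 = c(1, 2, 0), s2 = c(1, 2, 0), s3 = c(1, 0, 5))
  colnames(m) <- c("even", "two", "single")
  m["s3", "even"] <- 1
  b <- niche_breadth(m)
  expect_equal(unname(b["even"]), 3)       # equal share in all 3 samples
  expect_equal(unname(b["single"]), 1)     # present in exactly one sample
  expect_equal(unname(b["two"]), 2)        # shares (0.5, 0.5, 0)
  m0 <- cbind(m, absent = 0)
  expect_true(is.na(niche_breadth(m0)["absent"]))
  grp <- niche_breadth(m, groups = c("g1", "g1", "g2"))
  expect_equal(dim(grp), c(2, 3))
  expect_equal(unname(grp["g1", "two"]), 2)
})
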