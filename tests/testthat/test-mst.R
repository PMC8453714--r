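# Maximum spanning tree construction and tree topology metrics.

test_that("the 4-node worked example picks the strongest chain", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.9; m[2, 3] <- 0.8; m[3, 4] <- 0.7
  m[1, 3] <- 0.1; m[1, 4] <- 0.2; m[2, 4] <- 0.3
  m <- m + t(m)
  tree <- max_spanning_tree(m)
  got <- tree$edges[order(tree$edges$i, tree$edges$j), ]
  expect_equal(got$i, c(1, 2, 3))
  expect_equal(got$j, c(2, 3, 4))
  expect_equal(sum(got$weight), 2.4)
  # independent check: exhaustive enumeration over all edge subsets
  expect_equal(sum(tree$edges$weight), exhaustive_mst_weight(m))
})

test_that("Kruskal trees are optimal for exhaustive enumeration, N <= 6", {
  set.seed(61)
  for (rep in 1:100) {
    n <- sample(4:6, 1)
    m <- random_sym_matrix(n)
    tree <- max_spanning_tree(m)
    expect_equal(nrow(tree$edges), n - 1)
    expect_equal(sum(tree$edges$weight), exhaustive_mst_weight(m),
                 tolerance = 1e-12)
  }
})

test_that("any valid input yields a connected acyclic N-1 edge tree", {
  set.seed(62)
  for (n in c(2, 5, 20, 90)) {
    m <- random_sym_matrix(n)
    tree <- max_spanning_tree(m)
    expect_equal(nrow(tree$edges), n - 1)
    # connectivity via union-find over the returned edges
    parent <- seq_len(n)
    find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
    for (k in seq_len(n - 1)) {
      a <- find(tree$edges$i[k]); b <- find(tree$edges$j[k])
      expect_false(a == b)  # acyclic: no edge closes a cycle
      parent[a] <- b
    }
    expect_length(unique(vapply(seq_len(n), find, integer(1))), 1)
  }
})

test_that("a star-dominant matrix yields the star on the hub", {
  n <- 8
  hub <- 3
  m <- matrix(0.1, n, n)
  m[hub, ] <- 0.9; m[, hub] <- 0.9
  diag(m) <- 0
  tree <- max_spanning_tree(m)
  expect_true(all(tree$edges$i == hub | tree$edges$j == hub))
  expect_equal(unname(tree_degrees(tree)[hub]), n - 1)
})

test_that("monotone weight transforms leave the tree edge set unchanged", {
  set.seed(63)
  m <- random_sym_matrix(12)
  key <- function(tree) paste(tree$edges$i, tree$edges$j, sep = "-")
  t0 <- max_spanning_tree(m)
  for (f in list(function(w) w^3, function(w) exp(2 * w),
                 function(w) 5 * w + 1)) {
    mf <- f(m); diag(mf) <- 0
    expect_setequal(key(max_spanning_tree(mf)), key(t0))
  }
  # reciprocal reporting keeps the edge set, inverts the weights
  tr <- max_spanning_tree(m, weight_transform = "reciprocal")
  expect_setequal(key(tr), key(t0))
  expect_equal(sort(tr$edges$weight), sort(1 / t0$edges$weight))
})

test_that("an isolated node is reported by name", {
  m <- random_sym_matrix(5)
  m[4, ] <- 0; m[, 4] <- 0
  rownames(m) <- colnames(m) <- paste0("roi", 1:5)
  expect_error(max_spanning_tree(m), "roi4")
})

test_that("tree betweenness matches hand values and the path-walking oracle", {
  bc_path <- tree_betweenness(path_tree(5))
  expect_equal(bc_path, c(0, 3 / 6, 4 / 6, 3 / 6, 0))
  bc_star <- tree_betweenness(star_tree(7))
  expect_equal(bc_star, c(1, rep(0, 6)))
  set.seed(64)
  for (rep in 1:100) {
    tr <- random_tree(8)
    expect_equal(tree_betweenness(tr), brute_tree_betweenness(tr))
  }
})

test_that("leaf fraction, degree divergence and hierarchy match closed forms", {
  p5 <- path_tree(5)
  s5 <- star_tree(5)
  expect_equal(leaf_fraction(p5), 2 / 5)
  expect_equal(leaf_fraction(s5), 4 / 5)
  expect_equal(leaf_fraction(path_tree(2)), 1)
  expect_equal(leaf_fraction(p5, denominator = "m"), 2 / 4)

  expect_equal(degree_divergence(p5), (14 / 5) / (8 / 5))
  expect_equal(degree_divergence(s5), (20 / 5) / (8 / 5))

  expect_equal(tree_hierarchy(s5), 4 / (2 * 4 * 1))
  expect_equal(tree_hierarchy(p5), 2 / (2 * 4 * (4 / 6)))
  expect_equal(tree_hierarchy(s5, formula = "literal"), 4)
  # star of any size has Boersma hierarchy exactly 1/2
  for (n in c(4, 9, 30)) expect_equal(tree_hierarchy(star_tree(n)), 0.5)
})

test_that("degree divergence is bounded below by the mean degree", {
  set.seed(65)
  for (rep in 1:50) {
    tr <- random_tree(sample(3:15, 1))
    deg <- tree_degrees(tr)
    expect_equal(sum(deg), 2 * (tr$n_nodes - 1))
    expect_gte(degree_divergence(tr), mean(deg))
  }
})

test_that("diameter matches trivial cases and the all-pairs BFS oracle", {
  expect_equal(tree_diameter(path_tree(5)), 4L)
  expect_equal(tree_diameter(star_tree(9)), 2L)
  expect_equal(tree_diameter(path_tree(6), normalize = TRUE), 1)
  set.seed(66)
  for (rep in 1:50) {
    tr <- random_tree(sample(4:10, 1))
    expect_equal(tree_diameter(tr), brute_tree_diameter(tr))
  }
})

test_that("tree metrics agree with igraph on random trees", {
  set.seed(67)
  for (rep in 1:20) {
    tr <- random_tree(10)
    g <- igraph::graph_from_edgelist(as.matrix(tr$edges[, c("i", "j")]),
                                     directed = FALSE)
    expect_equal(tree_betweenness(tr),
                 unname(igraph::betweenness(g, normalized = TRUE)))
    expect_equal(tree_diameter(tr), igraph::diameter(g, weights = NA))
    expect_equal(tree_degrees(tr), unname(igraph::degree(g)))
  }
})

test_that("sum of betweenness equals the mean interior path length identity", {
  # every (s,t) path of hop length L contributes L - 1 interior nodes
  set.seed(68)
  for (rep in 1:20) {
    tr <- random_tree(9)
    n <- tr$n_nodes
    g <- igraph::graph_from_edgelist(as.matrix(tr$edges[, c("i", "j")]),
                                     directed = FALSE)
    d <- igraph::distances(g, weights = NA)
    interior_total <- sum(d[upper.tri(d)] - 1)
    expect_equal(sum(tree_betweenness(tr)) * ((n - 1) * (n - 2) / 2),
                 interior_total)
  }
})

test_that("epoch averaging of metrics is the arithmetic mean", {
  # path MST (leaf fraction 2/5) and star MST (leaf fraction 4/5)
  path_m <- matrix(0.1, 5, 5)
  for (k in 1:4) path_m[k, k + 1] <- path_m[k + 1, k] <- 0.9
  diag(path_m) <- 0
  star_m <- matrix(0.1, 5, 5)
  star_m[1, ] <- star_m[, 1] <- 0.9
  diag(star_m) <- 0
  avg <- metrics_for_band(list(path_m, star_m))
  expect_equal(avg$leaf_fraction, (2 / 5 + 4 / 5) / 2)
  expect_equal(avg$diameter, (4 + 2) / 2)
  one <- metrics_for_band(list(path_m))
  rep3 <- metrics_for_band(list(path_m, path_m, path_m))
  for (f in c("leaf_fraction", "degree_divergence", "tree_hierarchy",
              "diameter", "degree", "betweenness")) {
    expect_equal(rep3[[f]], one[[f]])
  }
})
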