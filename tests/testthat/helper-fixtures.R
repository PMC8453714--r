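# Shared fixtures and independent oracles, all built in code.

# Direct spanning_tree construction (bypasses Kruskal) for metric tests.
make_tree <- function(n, edges_ij, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(edges_ij))
  structure(list(n_nodes = n, labels = NULL,
                 edges = data.frame(i = edges_ij[, 1], j = edges_ij[, 2],
                                    weight = weights)),
            class = "spanning_tree")
}

path_tree <- function(n) make_tree(n, cbind(1:(n - 1), 2:n))
star_tree <- function(n) make_tree(n, cbind(rep(1, n - 1), 2:n))

# Random labelled tree via a random Pruefer-like attachment.
random_tree <- function(n) {
  edges <- matrix(0L, n - 1, 2)
  perm <- sample(n)
  for (k in 2:n) {
    edges[k - 1, ] <- c(perm[sample(k - 1, 1)], perm[k])
  }
  make_tree(n, edges)
}

# Random symmetric connectivity matrix with distinct positive weights.
random_sym_matrix <- function(n) {
  m <- matrix(0, n, n)
  w <- sample(seq(0.01, 0.99, length.out = n * (n - 1) / 2))
  m[upper.tri(m)] <- w
  m + t(m)
}

# ---- independent oracles ----------------------------------------------

# Exhaustive maximum spanning tree: try all (n-1)-subsets of edges.
exhaustive_mst_weight <- function(mat) {
  n <- nrow(mat)
  pairs <- which(upper.tri(mat), arr.ind = TRUE)
  combos <- utils::combn(nrow(pairs), n - 1)
  best <- -Inf
  for (c in seq_len(ncol(combos))) {
    sel <- pairs[combos[, c], , drop = FALSE]
    parent <- seq_len(n)
    find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
    ok <- TRUE
    for (e in seq_len(nrow(sel))) {
      a <- find(sel[e, 1]); b <- find(sel[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- max(best, sum(mat[sel]))
  }
  best
}

# Tree betweenness by walking the unique path of every node pair.
brute_tree_betweenness <- function(tree) {
  n <- tree$n_nodes
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(tree$edges))) {
    i <- tree$edges$i[k]; j <- tree$edges$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  path_between <- function(s, t) {
    prev <- rep.int(0L, n); prev[s] <- s
    queue <- s
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[u]]) if (prev[w] == 0L) {
        prev[w] <- u
        queue <- c(queue, w)
      }
    }
    p <- t
    path <- t
    while (p != s) { p <- prev[p]; path <- c(p, path) }
    path
  }
  counts <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    inner <- setdiff(path_between(s, t), c(s, t))
    counts[inner] <- counts[inner] + 1
  }
  counts / ((n - 1) * (n - 2) / 2)
}

# All-pairs BFS diameter.
brute_tree_diameter <- function(tree) {
  n <- tree$n_nodes
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(tree$edges))) {
    i <- tree$edges$i[k]; j <- tree$edges$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  best <- 0L
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n); d[s] <- 0L
    queue <- s
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[u]]) if (is.na(d[w])) { d[w] <- d[u] + 1L; queue <- c(queue, w) }
    }
    best <- max(best, max(d))
  }
  best
}

# Naive O(T^2) discrete-Fourier PLM.
naive_plm <- function(x_phase, y_phase, fs, B = 0.5,
                      dc_policy = "exclude") {
  z <- exp(1i * (x_phase - y_phase))
  n <- length(z)
  ks <- 0:(n - 1)
  pow <- vapply(ks, function(k) {
    Mod(sum(z * exp(-2i * pi * k * (0:(n - 1)) / n)))^2
  }, numeric(1))
  f <- ifelse(ks <= n / 2, ks, ks - n) * fs / n
  keep <- if (dc_policy == "exclude") ks != 0 else rep(TRUE, n)
  num <- sum(pow[keep & abs(f) <= B + 1e-12])
  den <- sum(pow[keep])
  if (den < 1e-12) 0 else num / den
}

# Exact Wilcoxon signed-rank two-sided p by sign-pattern enumeration.
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  min(1, mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9))
}

# Exact Friedman permutation p (k = 3) by direct enumeration.
enum_friedman_p <- function(values) {
  n <- nrow(values)
  ords <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  chisq <- function(R) 12 / (n * 12) * sum(colSums(R)^2) - 12 * n
  obs <- chisq(t(apply(values, 1, rank)))
  grid <- as.matrix(expand.grid(rep(list(1:6), n)))
  stats <- apply(grid, 1, function(ix) chisq(ords[ix, , drop = FALSE]))
  mean(stats >= obs - 1e-9)
}

# Small fast generator configuration for repeated-run studies.
fast_config <- function(seed, ...) {
  generator_config(n_subjects = 8, n_nodes = 20, seed = seed, ...)
}
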