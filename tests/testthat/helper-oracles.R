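# Independent oracles and fixture builders used across the suite.

# Exhaustive double-loop beta-MNTD: enumerate every (i, j) distance and take
# explicit minima. Deliberately naive and independent of the package kernel.
oracle_beta_mntd <- function(x_k, x_m, D) {
  f_k <- x_k / sum(x_k)
  f_m <- x_m / sum(x_m)
  ik <- which(f_k > 0)
  im <- which(f_m > 0)
  s1 <- 0
  for (i in ik) {
    best <- Inf
    for (j in im) best <- min(best, D[i, j])
    s1 <- s1 + f_k[i] * best
  }
  s2 <- 0
  for (j in im) {
    best <- Inf
    for (i in ik) best <- min(best, D[j, i])
    s2 <- s2 + f_m[j] * best
  }
  unname(0.5 * (s1 + s2))
}

# Patristic distances by explicit root-path walking over the edge list,
# independent of stats::cophenetic: d(i,j) = depth_i + depth_j - 2*depth_mrca.
oracle_cophenetic <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1
  parent <- integer(max(tree$edge))
  plen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- node
    while (node != root) {
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + plen[node]
      node <- parent[node]
    }
    d
  }
  D <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  depths <- vapply(seq_len(n_tip), depth, numeric(1))
  paths <- lapply(seq_len(n_tip), path_to_root)
  for (i in seq_len(n_tip - 1)) {
    for (j in seq(i + 1, n_tip)) {
      mrca <- intersect(paths[[i]], paths[[j]])[1]
      D[i, j] <- D[j, i] <- depths[i] + depths[j] - 2 * depth(mrca)
    }
  }
  D
}

# Random small instance: a tree with branch lengths, its cophenetic matrix,
# and a 2-site count table with guaranteed non-empty sites.
random_instance <- function(n_taxa, seed, max_count = 5L) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$tip.label <- paste0("T", seq_len(n_taxa))
  D <- stats::cophenetic(tr)[tr$tip.label, tr$tip.label]
  repeat {
    x <- matrix(rpois(2 * n_taxa, 1.2), nrow = 2,
                dimnames = list(c("S1", "S2"), tr$tip.label))
    if (all(rowSums(x) > 0) && all(colSums(x) > 0)) break
  }
  list(tree = tr, D = D, counts = x)
}

# Small community + tree fixture written as text files in a temp dir.
write_fixture_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:0.5):0.5);")
  comm <- matrix(c(5, 0, 2, 1,
                   1, 3, 0, 2,
                   0, 2, 4, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("S1", "S2", "S3"), c("A", "B", "C", "D")))
  table_path <- file.path(dir, "table.tsv")
  tree_path <- file.path(dir, "tree.nwk")
  assemproc::write_community_table(comm, table_path)
  ape::write.tree(tr, tree_path)
  list(comm = comm, tree = tr, table = table_path, tree_file = tree_path)
}
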