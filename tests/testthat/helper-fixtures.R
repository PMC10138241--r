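# Shared fixtures: randomized cohorts, planted-block configs, and the
# brute-force spanning-tree oracle used against mst_filter().

# A small mixed-type cohort with reproducible random content.
random_cohort <- function(seed, n = 10, with_missing = FALSE) {
  set.seed(seed)
  vars <- list(
    variable_spec("meth_a", "continuous", tissue = "placenta", units = "%",
                  valid_range = c(0, 100)),
    variable_spec("conc_b", "continuous", units = "mg/kg",
                  valid_range = c(0, Inf)),
    variable_spec("smoke", "binary", levels = c("yes", "no")),
    variable_spec("context", "binary", levels = c("rural", "urban")))
  data <- data.frame(
    meth_a = round(runif(n, 0, 100), 3),
    conc_b = round(rexp(n, 10), 6),
    smoke = sample(c("yes", "no"), n, replace = TRUE),
    context = sample(c("rural", "urban"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (with_missing && n >= 3) {
    data$meth_a[2] <- NA
    data$smoke[3] <- NA
  }
  cohort_table(data, vars, subjects = sprintf("subj%02d", seq_len(n)))
}

# Twelve identically-distributed continuous marginals in three latent
# blocks of four.
block_margins <- function(k = 12) {
  lapply(sprintf("node%02d", seq_len(k)), function(nm)
    marginal_spec(nm, "continuous", mean = 50, sd = 10,
                  valid_range = c(0, 100)))
}

block_dependence <- function(r = 0.9, blocks = 3, size = 4) {
  dependence_spec(lapply(seq_len(blocks) - 1, function(b)
    list(members = sprintf("node%02d", b * size + seq_len(size)),
         correlation = r)))
}

# Do the members induce a connected subtree of the edge list?
subtree_connected <- function(edges, members) {
  sub <- edges[edges$node_a %in% members & edges$node_b %in% members, ]
  parent <- stats::setNames(members, members)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (k in seq_len(nrow(sub))) {
    parent[[find(sub$node_a[k])]] <- find(sub$node_b[k])
  }
  length(unique(vapply(members, find, character(1)))) == 1L
}

# Decode a Pruefer sequence into the edge matrix of a labeled tree.
prufer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_along(seq)) {
    leaf <- which(degree == 1L)[1]
    edges[k, ] <- c(leaf, seq[k])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[k]] <- degree[seq[k]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# Maximum total SA over every labeled spanning tree (Cayley enumeration).
max_sa_tree_bruteforce <- function(sa) {
  n <- nrow(sa)
  if (n == 2) return(sa[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- -Inf
  for (i in seq_len(nrow(seqs))) {
    e <- prufer_to_edges(seqs[i, ], n)
    best <- max(best, sum(sa[e]))
  }
  best
}

# Random symmetric SA matrix with labels.
random_sa <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  m
}
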