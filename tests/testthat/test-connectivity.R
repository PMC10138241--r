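test_that("weights translate to a symmetric, clipped, zero-diagonal SA", {
  m <- autocm_init(3, autocm_config(C = 10), nodes = c("a", "b", "c"))
  m$w <- matrix(0, 3, 3, dimnames = list(m$nodes, m$nodes))
  m$w[1, 2] <- 8; m$w[2, 1] <- 6   # 0.8C and 0.6C -> mean 0.7
  m$w[1, 3] <- 10; m$w[3, 1] <- 10 # saturation -> 1
  sa <- weights_to_sa(m)
  expect_equal(sa[1, 2], 0.7)
  expect_equal(sa[2, 1], 0.7)
  expect_equal(sa[1, 3], 1)
  expect_identical(diag(sa), c(a = 0, b = 0, c = 0))
  expect_true(all(sa >= 0 & sa <= 1))

  m$w[] <- 0
  expect_warning(sa0 <- weights_to_sa(m), "untrained")
  expect_true(all(sa0 == 0))
})

test_that("the spanning-tree filter finds the unique optimum on 3 nodes", {
  sa <- matrix(c(0, .9, .1, .9, 0, .8, .1, .8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  edges <- mst_filter(sa)
  expect_identical(nrow(edges), 2L)
  got <- paste(pmin(edges$node_a, edges$node_b),
               pmax(edges$node_a, edges$node_b))
  expect_setequal(got, c("A B", "B C"))
  expect_error(mst_filter(sa[1, 1, drop = FALSE]), "at least 2")
})

test_that("the filter attains the brute-force optimum on random matrices", {
  for (seed in 1:100) {
    n <- 3L + as.integer(seed %% 4) # 3..6 nodes
    sa <- random_sa(n, seed)
    edges <- mst_filter(sa)
    expect_identical(nrow(edges), n - 1L)
    expect_equal(sum(edges$sa), max_sa_tree_bruteforce(sa),
                 tolerance = 1e-12)
  }
})

test_that("tree edges are invariant to a constant shift of all distances", {
  for (seed in 1:20) {
    sa <- random_sa(6, seed) / 2        # room to shift within [0,1]
    shifted <- sa + 0.3
    diag(shifted) <- 0
    e1 <- mst_filter(sa)
    e2 <- mst_filter(shifted)
    expect_identical(e1[, c("node_a", "node_b")],
                     e2[, c("node_a", "node_b")])
  }
})

test_that("ties break lexicographically and reproducibly", {
  sa <- matrix(0.5, 4, 4,
               dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  diag(sa) <- 0
  e <- mst_filter(sa)
  expect_identical(paste(e$node_a, e$node_b),
                   c("a b", "a c", "a d"))
  expect_identical(mst_filter(sa), e)
})

test_that("hub detection returns all maximal-degree nodes", {
  star <- data.frame(node_a = rep("hub", 4),
                     node_b = c("a", "b", "c", "d"),
                     sa = rep(0.5, 4))
  expect_identical(find_hubs(star), "hub")

  path <- data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "d"),
                     sa = rep(0.5, 3))
  expect_setequal(find_hubs(path), c("b", "c"))

  two <- data.frame(node_a = c("x", "x", "x", "y", "y", "y", "x"),
                    node_b = c(paste0("a", 1:3), paste0("b", 1:3), "y"),
                    sa = rep(0.5, 7))
  expect_setequal(find_hubs(two), c("x", "y")) # both degree 4
})

test_that("maps carry the tree contract: N-1 edges, connected, acyclic", {
  set.seed(4)
  x <- matrix(runif(40 * 7), 40, 7,
              dimnames = list(NULL, paste0("n", 1:7)))
  fit <- autocm_train(x, autocm_config(max_epochs = 500))
  map <- connectivity_map(fit)
  expect_identical(nrow(map$edges), 6L)
  expect_true(subtree_connected(map$edges, map$nodes))
  expect_true(all(map$edges$sa >= 0 & map$edges$sa <= 1))
  expect_true(all(map$hubs %in% map$nodes))
  # each edge's sa equals the matrix entry
  for (k in seq_len(nrow(map$edges))) {
    expect_identical(map$edges$sa[k],
                     map$sa[map$edges$node_a[k], map$edges$node_b[k]])
  }
})

test_that("planted blocks separate: within-block SA exceeds between-block SA", {
  co <- simulate_cohort(cohort_sim_config(n_subjects = 200, seed = 8,
                                          marginals = block_margins(),
                                          dependence = block_dependence()))
  fit <- autocm_train(encode_cohort(co))
  sa <- weights_to_sa(fit)
  bid <- rep(1:3, each = 4)
  same <- outer(bid, bid, "==")[upper.tri(sa)]
  vals <- sa[upper.tri(sa)]
  expect_gt(mean(vals[same]), mean(vals[!same]) + 0.02)
})

test_that("map export round-trips GraphML and writes labelled edge CSVs", {
  set.seed(9)
  x <- matrix(runif(30 * 5), 30, 5,
              dimnames = list(NULL, c("a", "b", "c", "d", "e")))
  map <- connectivity_map(autocm_train(x, autocm_config(max_epochs = 300)))

  csv <- withr::local_tempfile(fileext = ".csv")
  export_map(map, csv)
  df <- utils::read.csv(csv, colClasses = "character")
  expect_identical(nrow(df), 4L)
  expect_identical(df$sa_rounded, sprintf("%.2f", map$edges$sa))
  expect_true(all(as.logical(df$is_tree_edge)))
  expect_equal(as.numeric(df$sa_full), map$edges$sa, tolerance = 1e-15)

  all_csv <- withr::local_tempfile(fileext = ".csv")
  export_map(map, all_csv, edges = "all")
  da <- utils::read.csv(all_csv)
  expect_identical(nrow(da), 10L)
  expect_identical(sum(da$is_tree_edge), 4L)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_map(map, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  expect_setequal(igraph::V(g)$name[igraph::V(g)$is_hub], map$hubs)

  dot <- withr::local_tempfile(fileext = ".dot")
  export_map(map, dot, format = "dot")
  expect_gt(length(readLines(dot)), 4L)
})
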