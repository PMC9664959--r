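# Similarity network, Markov clustering, cluster graph, inflation sweep.

fake_hit <- function(q, s, qcov = 0.9, scov = 0.9, ev = 1e-5) {
  data.frame(query_id = q, subject_id = s, raw_score = 100, bit_score = 40,
             e_value = ev, identity = 0.5, query_coverage = qcov,
             subject_coverage = scov, stringsAsFactors = FALSE)
}

test_that("hit filtering enforces both coverages and the E-value cap", {
  hits <- rbind(fake_hit("a", "b", 0.85, 0.85, 0.01),
                fake_hit("a", "c", 0.79, 0.95, 0.01),
                fake_hit("a", "d", 0.85, 0.85, 0.06),
                fake_hit("e", "e", 0.99, 0.99, 1e-9))
  kept <- filter_hits(hits, 0.8, 0.05)
  expect_equal(kept$subject_id, "b")
})

test_that("network construction merges directions into undirected edges", {
  n1 <- build_network(fake_hit("A", "B"))
  expect_equal(n1$edges, data.frame(a = "A", b = "B"))
  n2 <- build_network(rbind(fake_hit("A", "B"), fake_hit("B", "A")))
  expect_equal(nrow(n2$edges), 1)
  expect_equal(nrow(n2$directed_hits), 2)
  n3 <- build_network(fake_hit("A", "B")[0, ], nodes = c("X", "Y"))
  expect_equal(nrow(n3$edges), 0)
  expect_equal(n3$nodes, c("X", "Y"))
})

test_that("MCL separates disjoint triangles at several inflations", {
  net <- triangles_network()
  for (I in c(1.4, 2, 6)) {
    cl <- mcl(net, mcl_params(inflation = I))
    expect_equal(length(cl$sizes), 2)
    expect_equal(sort(cl$sizes), c(3, 3))
    # clusters coincide with the connected components
    expect_equal(length(unique(cl$assignment[c("a1", "a2", "a3")])), 1)
    expect_equal(length(unique(cl$assignment[c("b1", "b2", "b3")])), 1)
  }
  # and agrees with the independent minimal MCL iteration
  adj <- matrix(0, 6, 6)
  idx <- function(x) match(x, net$nodes)
  for (r in seq_len(nrow(net$edges))) {
    i <- idx(net$edges$a[r]); j <- idx(net$edges$b[r])
    adj[i, j] <- adj[j, i] <- 1
  }
  ref <- simple_mcl(adj, 2)
  cl2 <- mcl(net, mcl_params(inflation = 2))
  expect_equal(adjusted_rand_index(unname(cl2$assignment), ref), 1)
})

test_that("an isolated node forms its own cluster", {
  net <- build_network(fake_hit("A", "B"), nodes = c("A", "B", "C"))
  cl <- mcl(net, mcl_params())
  expect_equal(length(cl$sizes), 2)
  expect_equal(sum(cl$sizes), 3)
  expect_equal(unname(cl$assignment[["C"]]), 2)  # smaller cluster -> id 2
})

test_that("clustering is a partition with size-ordered contiguous ids", {
  set.seed(21)
  for (rep in 1:20) {
    net <- random_network(12, 0.25)
    cl <- suppressWarnings(mcl(net, mcl_params(inflation = 2)))
    expect_equal(length(cl$assignment), 12)
    expect_equal(sort(unique(unname(cl$assignment))),
                 seq_along(cl$sizes))
    expect_equal(sum(cl$sizes), 12)
    expect_true(all(diff(cl$sizes) <= 0))
    # clusters never span components of the input network
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    comp <- igraph::components(g)$membership[net$nodes]
    expect_true(all(tapply(comp, cl$assignment[net$nodes],
                           function(x) length(unique(x))) == 1))
  }
})

test_that("planted two-block graphs are recovered and match mclust's ARI", {
  set.seed(22)
  tb <- two_block_network(20, 0.9, 0.05)
  cl <- mcl(tb$net, mcl_params(inflation = 2))
  ari <- adjusted_rand_index(unname(cl$assignment[tb$net$nodes]), tb$truth)
  expect_equal(ari, 1)
  # in-package ARI agrees with the mclust implementation
  set.seed(23)
  for (rep in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 unname(mclust::adjustedRandIndex(x, y)), tolerance = 1e-12)
  }
})

test_that("cluster-graph weights use observed over possible mutual hits", {
  # clusters {A1,A2} and {B1,B2,B3}; 4 directed inter-hits -> 4/(2*2*3)
  hits <- rbind(fake_hit("A1", "A2"), fake_hit("A2", "A1"),
                fake_hit("B1", "B2"), fake_hit("B2", "B3"),
                fake_hit("B3", "B1"),
                fake_hit("A1", "B1"), fake_hit("B1", "A1"),
                fake_hit("A2", "B2"), fake_hit("B3", "A2"))
  net <- build_network(hits)
  clustering <- structure(list(
    assignment = c(A1 = 2L, A2 = 2L, B1 = 1L, B2 = 1L, B3 = 1L),
    sizes = c(3L, 2L), converged = TRUE, n_iter = 1L),
    class = "mcl_clustering")
  cg <- cluster_graph(clustering, net)
  expect_equal(cg$nodes$display_size, log10(c(3, 2)))
  expect_equal(cg$edges$weight, 4 / (2 * 2 * 3))
  # the unordered denominator is exactly twice as large
  cg2 <- cluster_graph(clustering, net, denominator = "unordered")
  expect_equal(cg2$edges$weight, 4 / (2 * 3))
  # no inter-hits -> no edge; full mutual hits -> weight 1
  hits0 <- rbind(fake_hit("A1", "A2"), fake_hit("B1", "B2"))
  cg0 <- cluster_graph(clustering, build_network(hits0, names(clustering$assignment)))
  expect_equal(nrow(cg0$edges), 0)
  full <- NULL
  for (a in c("A1", "A2")) for (b in c("B1", "B2", "B3"))
    full <- rbind(full, fake_hit(a, b), fake_hit(b, a))
  cgf <- cluster_graph(clustering, build_network(full))
  expect_equal(cgf$edges$weight, 1)
})

test_that("inflation sweep is monotone in granularity and flags I = 1", {
  set.seed(24)
  tb <- two_block_network(12, 0.9, 0.08)
  scan <- scan_inflation(tb$net, c(1.0, 1.4, 2, 6))
  expect_equal(nrow(scan), 4)
  # coarser inflation -> larger largest-cluster fraction
  expect_true(all(diff(scan$largest_cluster_fraction) <= 0))
  # I = 1 is degenerate: one cluster per component (or non-convergence)
  row1 <- scan[scan$inflation == 1, ]
  g <- igraph::graph_from_data_frame(tb$net$edges, directed = FALSE,
                                     vertices = tb$net$nodes)
  ncomp <- igraph::components(g)$no
  expect_true(!row1$converged || row1$n_clusters == ncomp)
  # disjoint triangles: two clusters at every usable inflation
  scan2 <- scan_inflation(triangles_network(), c(1.4, 2, 6))
  expect_equal(scan2$n_clusters, c(2, 2, 2))
})

test_that("network and clustering exports are stable TSVs", {
  net <- triangles_network()
  cl <- mcl(net, mcl_params(inflation = 2))
  d <- tempfile(); dir.create(d)
  write_network(net, file.path(d, "net.tsv"))
  write_clustering(cl, file.path(d, "cl.tsv"))
  cg <- cluster_graph(cl, net)
  write_cluster_graph(cg, file.path(d, "nodes.tsv"), file.path(d, "edges.tsv"))
  back <- read.table(file.path(d, "cl.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(back), 6)
  expect_equal(sort(unique(back$cluster)), 1:2)
})
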