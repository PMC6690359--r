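test_that("subnetwork construction keeps candidate-candidate edges above the cutoff", {
  tri <- ppi_network(data.frame(gene_a = c("A", "B", "A"),
                                gene_b = c("B", "C", "C"),
                                confidence = 0.9))
  sub <- build_subnetwork(tri, c("A", "B"), 0.7)
  expect_setequal(sub$nodes, c("A", "B"))
  expect_equal(nrow(sub$edges), 1L)
  expect_length(sub$outer_genes, 0L)

  # low-confidence edge: both candidates retained as isolated nodes
  weak <- ppi_network(data.frame(gene_a = "A", gene_b = "B", confidence = 0.5))
  sub2 <- build_subnetwork(weak, c("A", "B"), 0.7)
  expect_setequal(sub2$nodes, c("A", "B"))
  expect_equal(nrow(sub2$edges), 0L)

  # a candidate absent from the interaction database is kept as a node
  sub3 <- build_subnetwork(tri, c("A", "CRTAM"), 0.7)
  expect_true("CRTAM" %in% sub3$nodes)
})

test_that("subnetwork agrees with an exhaustive pair-scan oracle on random graphs", {
  set.seed(31)
  for (i in 1:25) {
    net <- random_network(sample(10:50, 1))
    cand <- sample(net$nodes, sample(3:8, 1))
    minc <- runif(1, 0.2, 0.8)
    sub <- build_subnetwork(net, cand, minc)
    # oracle: check every unordered node pair against the edge list
    conf <- setNames(net$edges$confidence,
                     paste(net$edges$gene_a, net$edges$gene_b))
    expected <- 0L
    for (a in cand) for (b in cand) if (a < b) {
      cc <- conf[paste(a, b)]
      if (!is.na(cc) && cc >= minc) {
        expected <- expected + 1L
        expect_true(any(sub$edges$gene_a == a & sub$edges$gene_b == b))
      }
    }
    expect_equal(nrow(sub$edges), expected)
    # always a subgraph of the input
    expect_true(all(sub$nodes %in% net$nodes))
    expect_true(all(paste(sub$edges$gene_a, sub$edges$gene_b) %in%
                      paste(net$edges$gene_a, net$edges$gene_b)))
  }
})

test_that("outer extension adds exactly the depth-1 neighborhood", {
  path3 <- ppi_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                                  confidence = 0.9))
  sub <- build_subnetwork(path3, "A", 0.7)
  ext <- extend_outer(path3, sub)
  expect_equal(ext$outer_genes, "B")          # C is two hops away
  expect_equal(ext$core_genes, "A")
  expect_equal(nrow(ext$edges), 1L)

  weak <- ppi_network(data.frame(gene_a = "A", gene_b = "B", confidence = 0.5))
  ext2 <- extend_outer(weak, build_subnetwork(weak, "A", 0.7))
  expect_length(ext2$outer_genes, 0L)
})

test_that("outer genes match an igraph depth-1 search oracle on random graphs", {
  set.seed(33)
  for (i in 1:25) {
    net <- random_network(sample(10:50, 1))
    cand <- sample(net$nodes, sample(2:6, 1))
    minc <- runif(1, 0.2, 0.7)
    ext <- extend_outer(net, build_subnetwork(net, cand, minc))
    # independent oracle: depth-1 ego sets on the confidence-filtered igraph
    keep <- net$edges$confidence >= minc
    g <- igraph::graph_from_data_frame(net$edges[keep, 1:2], directed = FALSE,
                                       vertices = net$nodes)
    nb <- unique(names(unlist(igraph::ego(g, order = 1,
                                          nodes = intersect(cand, net$nodes)))))
    expect_setequal(ext$outer_genes, setdiff(nb, cand))
    # invariants
    expect_length(intersect(ext$core_genes, ext$outer_genes), 0L)
    expect_true(all(ext$edges$confidence >= minc))
    # no retained outer-outer edges by default
    oo <- ext$edges$gene_a %in% ext$outer_genes &
      ext$edges$gene_b %in% ext$outer_genes
    expect_false(any(oo))
    # every outer gene touches a core gene through a retained edge
    touched <- unique(c(ext$edges$gene_a, ext$edges$gene_b))
    expect_true(all(ext$outer_genes %in% touched))
  }
})

test_that("re-extension at depth 1 adds nothing new", {
  set.seed(35)
  net <- random_network(40, edge_prob = 0.2)
  sub <- build_subnetwork(net, sample(net$nodes, 5), 0.4)
  once <- extend_outer(net, sub)
  twice <- extend_outer(net, build_subnetwork(net, once$core_genes,
                                              once$min_confidence))
  expect_setequal(twice$outer_genes, once$outer_genes)
})

test_that("outer-outer edges appear only with the sensitivity flag", {
  square <- ppi_network(data.frame(gene_a = c("A", "A", "B", "C"),
                                   gene_b = c("B", "C", "D", "D"),
                                   confidence = 0.9))
  sub <- build_subnetwork(square, "A", 0.7)
  dflt <- extend_outer(square, sub)
  flag <- extend_outer(square, sub, include_outer_edges = TRUE)
  expect_setequal(dflt$outer_genes, c("B", "C"))
  expect_equal(nrow(dflt$edges), 2L)      # A-B, A-C only
  expect_equal(nrow(flag$edges), 2L)      # B-D/C-D leave the node set; B-C absent
  bc <- ppi_network(data.frame(gene_a = c("A", "A", "B"),
                               gene_b = c("B", "C", "C"),
                               confidence = 0.9))
  flag2 <- extend_outer(bc, build_subnetwork(bc, "A", 0.7),
                        include_outer_edges = TRUE)
  expect_equal(nrow(flag2$edges), 3L)     # B-C retained under the flag
})
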