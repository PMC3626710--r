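test_that("the pathway graph is the bipartite membership graph", {
  net <- metabolic_network(
    edges = tibble::tibble(node = c("g1", "g2", "c1"),
                           node_kind = c("gene", "gene", "compound"),
                           reaction = "r1"),
    pathways = tibble::tibble(
      pathway = c("pw1", "pw1", "pw1"),
      member = c("g1", "g2", "c1"),
      kind = c("gene", "gene", "compound")))
  g <- build_pathway_graph(net)
  expect_equal(nrow(g$edges), 3)  # star with three leaves
  expect_equal(sum(g$nodes$kind == "pathway"), 1)

  net2 <- tiny_network()
  g2 <- build_pathway_graph(net2)
  # c2 belongs to both pathways -> degree 2
  deg_c2 <- sum(g2$edges$a == "c2" | g2$edges$b == "c2")
  expect_equal(deg_c2, 2)
  expect_equal(nrow(g2$edges), nrow(net2$pathways))
  expect_error(build_pathway_graph(metabolic_network()), "no pathway")
})

test_that("the driver subgraph is the union of radius-1 neighborhoods", {
  g <- build_pathway_graph(tiny_network())
  # driver in no pathway stays as an isolated node
  sub <- suppressMessages(driver_subgraph(g, c("g1", "orphan")))
  expect_true("orphan" %in% sub$nodes$id)
  expect_equal(sum(sub$edges$a == "orphan" | sub$edges$b == "orphan"), 0)
  # two drivers sharing a pathway form one 3-node component
  sub2 <- driver_subgraph(g, c("g1", "g2"))
  expect_setequal(sub2$nodes$id, c("g1", "g2", "pwA"))
  expect_equal(nrow(sub2$edges), 2)
  # non-driver genes and compounds never enter
  expect_false(any(sub2$nodes$kind == "compound"))
  expect_false("g3" %in% sub2$nodes$id)
})

test_that("driver subgraphs equal a naive per-driver union on fixtures", {
  for (s in 1:5) {
    net <- random_network(s, n_edges = 30)
    genes <- net$nodes$id[net$nodes$kind == "gene"]
    pw <- withr::with_seed(s, tibble::tibble(
      pathway = sample(paste0("pw", 1:3), 12, replace = TRUE),
      member = sample(genes, 12, replace = TRUE),
      kind = "gene"))
    net <- metabolic_network(edges = net$edges, pathways = pw)
    g <- build_pathway_graph(net)
    drivers <- withr::with_seed(s + 50, sample(genes, 4))
    sub <- suppressMessages(driver_subgraph(g, drivers))
    want_pws <- sort(unique(pw$pathway[pw$member %in% drivers]))
    expect_setequal(sub$nodes$id[sub$nodes$kind == "pathway"], want_pws)
    expect_setequal(sub$nodes$id[sub$nodes$kind == "gene"], drivers)
    # monotone: adding a driver never removes nodes
    sub2 <- suppressMessages(driver_subgraph(g, c(drivers, genes[1])))
    expect_true(all(sub$nodes$id %in% sub2$nodes$id))
  }
})

test_that("the genes-only view removes compounds and is idempotent", {
  g <- build_pathway_graph(tiny_network())
  v <- genes_only_view(g)
  expect_false(any(v$nodes$kind == "compound"))
  expect_false(any(v$edges$a_kind == "compound" |
                     v$edges$b_kind == "compound"))
  expect_equal(nrow(g$nodes) - nrow(v$nodes),
               sum(g$nodes$kind == "compound"))
  v2 <- genes_only_view(v)
  expect_equal(v2$nodes, v$nodes)
  expect_equal(v2$edges, v$edges)
})

test_that("the compound-linked view joins pathway pairs by one edge", {
  # two pathways sharing three compounds -> exactly one linking edge
  net <- metabolic_network(
    edges = tibble::tibble(node = c("g1", "g2"), node_kind = "gene",
                           reaction = c("r1", "r2")),
    pathways = tibble::tibble(
      pathway = rep(c("pw1", "pw2"), each = 4),
      member = c("g1", "s1", "s2", "s3", "g2", "s1", "s2", "s3"),
      kind = rep(c("gene", "compound", "compound", "compound"), 2)))
  g <- build_pathway_graph(net)
  sub <- driver_subgraph(g, c("g1", "g2"))
  v <- compound_linked_view(sub, net)
  pp <- v$edges[v$edges$a_kind == "pathway" & v$edges$b_kind == "pathway", ]
  expect_equal(nrow(pp), 1)
  # shared compounds are retained as linking nodes, each joined to both
  expect_setequal(v$nodes$id[v$nodes$kind == "compound"],
                  c("s1", "s2", "s3"))
  # no shared compounds -> no pathway-pathway edges
  net2 <- tiny_network()
  sub2 <- driver_subgraph(build_pathway_graph(net2), c("g1", "g3"))
  v2 <- compound_linked_view(sub2, net2)
  pp2 <- v2$edges[v2$edges$a_kind == "pathway" &
                    v2$edges$b_kind == "pathway", ]
  expect_equal(nrow(pp2), 1)  # c2 is shared between pwA and pwB
  expect_equal(v2$nodes$id[v2$nodes$kind == "compound"], "c2")
})

test_that("pathway-pair links match a brute-force shared-compound census", {
  for (s in 1:5) {
    pw <- withr::with_seed(s, tibble::tibble(
      pathway = sample(paste0("pw", 1:4), 25, replace = TRUE),
      member = sample(paste0("c", 1:10), 25, replace = TRUE),
      kind = "compound"))
    genes <- tibble::tibble(pathway = paste0("pw", 1:4),
                            member = paste0("g", 1:4), kind = "gene")
    net <- metabolic_network(
      edges = tibble::tibble(node = paste0("g", 1:4), node_kind = "gene",
                             reaction = "r1"),
      pathways = dplyr::bind_rows(pw, genes))
    g <- build_pathway_graph(net)
    sub <- driver_subgraph(g, paste0("g", 1:4))
    v <- compound_linked_view(sub, net)
    got <- v$edges[v$edges$a_kind == "pathway" & v$edges$b_kind == "pathway", ]
    mem <- unique(pw[, c("pathway", "member")])
    want <- 0
    pws <- paste0("pw", 1:4)
    for (i in 1:3) for (j in (i + 1):4) {
      shared <- intersect(mem$member[mem$pathway == pws[i]],
                          mem$member[mem$pathway == pws[j]])
      if (length(shared) > 0) want <- want + 1
    }
    expect_equal(nrow(got), want)
  }
})

test_that("fold changes use unlogged ratios with the negative reciprocal", {
  vals <- rbind(up = c(1, 1, 1, 2, 2, 2),      # log2: treatment 4x
                down = c(3, 3, 3, 2, 2, 2),    # treatment half
                flat = c(5, 5, 5, 5, 5, 5))
  colnames(vals) <- paste0("s", 1:6)
  expr <- expression_data(vals, stats::setNames(
    rep(c("control", "treatment"), each = 3), paste0("s", 1:6)))
  fc <- fold_change(expr)
  expect_equal(fc$fold_change[fc$feature == "up"], 2, tolerance = 1e-12)
  expect_equal(fc$fold_change[fc$feature == "down"], -2, tolerance = 1e-12)
  # a ratio of exactly one maps to the positive branch
  expect_equal(fc$fold_change[fc$feature == "flat"], 1)
  # linear-scale input: ratio without unlogging
  fc2 <- fold_change(expr, unlog = FALSE)
  expect_equal(fc2$fold_change[fc2$feature == "up"], 2)
  expect_error(fold_change(expr, features = "absent"), "unknown")
})

test_that("views preserve driver fold-change attributes", {
  net <- tiny_network()
  vals <- matrix(stats::rnorm(5 * 6, 8), 5, 6,
                 dimnames = list(c("g1", "g2", "g3", "x1", "x2"),
                                 paste0("s", 1:6)))
  vals["g1", 4:6] <- vals["g1", 4:6] + 1
  expr <- expression_data(vals, stats::setNames(
    rep(c("control", "treatment"), each = 3), paste0("s", 1:6)))
  g <- annotate_fold_change(build_pathway_graph(net), expr)
  sub <- driver_subgraph(g, c("g1", "g3"))
  fc_g1 <- sub$nodes$fold_change[sub$nodes$id == "g1"]
  expect_false(is.na(fc_g1))
  for (v in list(genes_only_view(sub), compound_linked_view(sub, net))) {
    expect_equal(v$nodes$fold_change[v$nodes$id == "g1"], fc_g1)
  }
  expect_s3_class(autoplot(sub), "ggplot")
})

test_that("GraphML and SIF exports re-import faithfully", {
  net <- tiny_network()
  sub <- driver_subgraph(build_pathway_graph(net), c("g1", "g2", "g3"))
  v <- compound_linked_view(sub, net)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(v, gml)
  gi <- read_graphml(gml)
  expect_equal(igraph::vcount(gi), nrow(v$nodes))
  expect_equal(igraph::ecount(gi), nrow(v$edges))
  expect_setequal(igraph::vertex_attr(gi, "label"), v$nodes$id)
  expect_setequal(igraph::vertex_attr(gi, "kind"), v$nodes$kind)

  sif <- withr::local_tempfile(fileext = ".sif")
  attrs <- withr::local_tempfile(fileext = ".tsv")
  write_sif(v, sif, attrs)
  back <- read_sif(sif, attrs)
  expect_equal(nrow(back$edges), nrow(v$edges))
  expect_setequal(back$nodes$id, v$nodes$id)

  # network exports too
  write_graphml(net, gml)
  gn <- read_graphml(gml)
  expect_equal(igraph::ecount(gn), nrow(net$edges))
})
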