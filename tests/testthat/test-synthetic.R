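test_that("generated networks satisfy the declared counts and invariants", {
  spec <- synthetic_spec(seed = 3)
  net <- generate_network(spec)
  nodes <- net$nodes
  expect_equal(sum(nodes$kind == "gene"),
               spec$n_modules * spec$genes_per_module)
  truth0 <- attr(net, "module_assignment")
  # reaction/compound counts match the generator's declared ground truth
  # (sizes vary deterministically around the nominal per-module counts)
  expect_equal(sum(nodes$kind == "reaction"),
               sum(truth0$kind == "reaction"))
  expect_equal(mean(table(truth0$module[truth0$kind == "reaction"])),
               spec$reactions_per_module)
  expect_equal(sum(nodes$kind == "compound"),
               sum(truth0$kind == "compound"))
  expect_true(all(net$edges$node_kind %in% c("gene", "compound")))
  expect_equal(dplyr::n_distinct(net$pathways$pathway), spec$n_modules)
  truth <- attr(net, "module_assignment")
  expect_equal(nrow(truth), nrow(nodes))
})

test_that("module connectivity reflects the compound bridges", {
  one <- generate_network(synthetic_spec(n_modules = 1, planted_modules = 1,
                                       seed = 1,
                                       inter_module_compound_links = 0))
  expect_equal(igraph::count_components(network_igraph(one)), 1)
  two <- generate_network(synthetic_spec(n_modules = 2, planted_modules = 1,
                                       seed = 1,
                                       inter_module_compound_links = 0))
  expect_equal(igraph::count_components(network_igraph(two)), 2)
  linked <- generate_network(synthetic_spec(n_modules = 2, planted_modules = 1,
                                          seed = 1,
                                          inter_module_compound_links = 1))
  expect_equal(igraph::count_components(network_igraph(linked)), 1)
})

test_that("generation is deterministic given the spec seed", {
  s <- synthetic_spec(seed = 9)
  n1 <- generate_network(s)
  n2 <- generate_network(s)
  expect_identical(n1$edges, n2$edges)
  m <- generate_probe_mapping(n1, probes_per_gene = 2)
  e1 <- generate_expression(s, n1, m)
  e2 <- generate_expression(s, n1, m)
  expect_identical(e1$values, e2$values)
})

test_that("the planted shift has the requested size and direction", {
  spec <- synthetic_spec(seed = 5, n_control = 40, n_treatment = 40)
  net <- generate_network(spec)
  expr <- generate_expression(spec, net)
  planted <- attr(expr, "differential_genes")
  expect_equal(length(planted),
               length(spec$planted_modules) * spec$genes_per_module)
  v <- expr$values
  diffs <- rowMeans(v[, expr$classes == "treatment"]) -
    rowMeans(v[, expr$classes == "control"])
  expect_equal(mean(diffs[planted]), spec$effect_size * spec$noise_sd,
               tolerance = 0.1)
  expect_equal(mean(diffs[setdiff(rownames(v), planted)]), 0,
               tolerance = 0.1)
  # zero effect leaves no systematic difference
  null_spec <- synthetic_spec(seed = 5, effect_size = 1e-9,
                              n_control = 40, n_treatment = 40)
  null_expr <- generate_expression(null_spec, generate_network(null_spec))
  expect_lt(max(abs(rowMeans(
    null_expr$values[, null_expr$classes == "treatment"]) -
      rowMeans(null_expr$values[, null_expr$classes == "control"]))), 1)
})

test_that("mixed-sign planting shifts half the module down", {
  spec <- synthetic_spec(seed = 7, mixed_sign = TRUE,
                         n_control = 30, n_treatment = 30)
  net <- generate_network(spec)
  expr <- generate_expression(spec, net)
  planted <- attr(expr, "differential_genes")
  diffs <- rowMeans(expr$values[planted, expr$classes == "treatment"]) -
    rowMeans(expr$values[planted, expr$classes == "control"])
  expect_gt(sum(diffs > 0.5), 0)
  expect_gt(sum(diffs < -0.5), 0)
})

test_that("probe mappings are deterministic and complete", {
  net <- generate_network(synthetic_spec(seed = 2))
  m <- generate_probe_mapping(net, probes_per_gene = 3)
  genes <- net$nodes$id[net$nodes$kind == "gene"]
  expect_equal(nrow(m), 3 * length(genes))
  expect_setequal(unique(m$gene), genes)
  expect_equal(anyDuplicated(m$probeset), 0)
})

test_that("early components resolve the planted module structure", {
  spec <- synthetic_spec(n_modules = 4, seed = 13,
                         inter_module_compound_links = 0)
  net <- generate_network(spec)
  truth <- attr(net, "module_assignment")
  model <- pca_of_laplacian(build_laplacian(net))
  module_of <- stats::setNames(truth$module, truth$id)
  # with disconnected modules every strong component support must sit in
  # a single module
  n_checked <- 0
  for (k in 1:40) {
    strong <- abs(model$scores[, k]) >= 1
    if (sum(strong) >= 2) {
      mods <- module_of[model$node_order$id[strong]]
      expect_equal(length(unique(mods)), 1)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 5)
})

test_that("fixtures written to disk feed the readers back unchanged", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_modules = 3, seed = 4)
  paths <- write_fixture(spec, dir)
  expect_true(all(file.exists(unlist(paths))))
  net <- parse_edgelist(paths$network)
  orig <- generate_network(spec)
  expect_equal(net$edges, orig$edges)
  expect_equal(net$pathways, orig$pathways)
  expr <- read_expression(paths$expression, paths$classes)
  mapping <- read_probe_mapping(paths$mapping)
  orig_expr <- generate_expression(spec, orig, mapping)
  expect_equal(expr$values, orig_expr$values, tolerance = 1e-9)
})

test_that("the pipeline recovers planted drivers with few false calls", {
  recov <- vapply(1:3, function(s) {
    spec <- synthetic_spec(seed = s)
    net <- generate_network(spec)
    mapping <- generate_probe_mapping(net)
    expr <- generate_expression(spec, net, mapping)
    res <- suppressWarnings(suppressMessages(
      run_lapgsa(net, expr, mapping = mapping, thresholds = 1:10,
                 nperms = 1000, seed = s)))
    planted <- attr(expr, "differential_genes")
    drv <- res$driver_genes
    c(mean(planted %in% drv),
      if (length(drv)) mean(!drv %in% planted) else 0)
  }, numeric(2))
  # the bulk of the planted subnetwork is recovered, and calls are
  # overwhelmingly inside the planted modules
  expect_gt(mean(recov[1, ]), 0.4)
  expect_lt(mean(recov[2, ]), 0.2)
})
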