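#' Pathway-context graphs
#'
#' A pathway-context graph holds the visualisation-oriented view of
#' results: pathway nodes, gene nodes (with an optional `fold_change`
#' attribute) and, in the compound-linked variant, compound nodes that tie
#' pathways together.
#'
#' @param nodes Tibble `id`, `kind` (`pathway`/`gene`/`compound`) and
#'   optionally `fold_change`.
#' @param edges Tibble `a`, `a_kind`, `b`, `b_kind` (undirected).
#' @param variant One of `"full"`, `"driver"`, `"genes_only"`,
#'   `"compound_linked"`.
#' @return A `pathway_context` object.
#' @export
pathway_context <- function(nodes, edges, variant = "full") {
  nodes <- tibble::as_tibble(nodes)
  if (!"fold_change" %in% names(nodes)) nodes$fold_change <- NA_real_
  nodes <- dplyr::distinct(
    dplyr::arrange(nodes[, c("id", "kind", "fold_change")],
                   .data$kind, .data$id))
  edges <- tibble::as_tibble(edges)[, c("a", "a_kind", "b", "b_kind")]
  # canonical undirected form: endpoints ordered by (kind, id)
  flip <- paste(edges$b_kind, edges$b) < paste(edges$a_kind, edges$a)
  edges[flip, ] <- edges[flip, c("b", "b_kind", "a", "a_kind")]
  edges <- dplyr::arrange(dplyr::distinct(edges),
                          .data$a_kind, .data$a, .data$b_kind, .data$b)
  structure(list(nodes = nodes, edges = edges, variant = variant),
            class = "pathway_context")
}

#' @export
print.pathway_context <- function(x, ...) {
  k <- table(factor(x$nodes$kind, c("pathway", "gene", "compound")))
  cat("<pathway_context:", x$variant, "> ", k[["pathway"]], " pathways, ",
      k[["gene"]], " genes, ", k[["compound"]], " compounds; ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Build the pathway-centric bipartite graph of a metabolic network
#'
#' One node per pathway, connected to each gene and compound associated
#' with it; no reaction nodes. This graph is the substrate for the
#' driver-seeded context views.
#'
#' @param network A [metabolic_network()] with pathway membership.
#' @return A `pathway_context` (variant `"full"`).
#' @export
build_pathway_graph <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  pw <- network$pathways
  if (nrow(pw) == 0) stop("network has no pathway membership", call. = FALSE)
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = unique(pw$pathway), kind = "pathway"),
    dplyr::distinct(tibble::tibble(id = pw$member, kind = pw$kind))
  )
  edges <- tibble::tibble(a = pw$pathway, a_kind = "pathway",
                          b = pw$member, b_kind = pw$kind)
  pathway_context(nodes, edges, "full")
}

#' Driver-seeded radius-1 context subgraph
#'
#' Each driver gene seeds a breadth-first search of radius one on the
#' pathway-centric graph (the driver and its pathways); the union over
#' drivers is returned. Non-driver genes and all compounds are excluded;
#' a driver belonging to no pathway is kept as an isolated node.
#'
#' @param graph A `pathway_context` from [build_pathway_graph()].
#' @param drivers Character vector of driver gene ids.
#' @return A `pathway_context` (variant `"driver"`).
#' @export
driver_subgraph <- function(graph, drivers) {
  stopifnot(inherits(graph, "pathway_context"))
  drivers <- unique(as.character(drivers))
  known <- graph$nodes$id[graph$nodes$kind == "gene"]
  outside <- setdiff(drivers, known)
  if (length(outside)) {
    message(length(outside),
            " driver(s) not in the pathway graph; kept as isolated nodes")
  }
  ed <- graph$edges
  # undirected edges may carry the pathway on either endpoint
  pg <- (ed$a_kind == "pathway" & ed$b_kind == "gene" & ed$b %in% drivers) |
    (ed$a_kind == "gene" & ed$b_kind == "pathway" & ed$a %in% drivers)
  ed <- ed[pg, , drop = FALSE]
  pathways <- unique(ifelse(ed$a_kind == "pathway", ed$a, ed$b))
  gene_nodes <- graph$nodes[graph$nodes$kind == "gene", , drop = FALSE]
  fc <- gene_nodes$fold_change[match(drivers, gene_nodes$id)]
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = drivers, kind = "gene", fold_change = fc),
    tibble::tibble(id = pathways, kind = "pathway",
                   fold_change = NA_real_)
  )
  pathway_context(nodes, ed, "driver")
}

#' Genes-only view of a context graph
#'
#' Removes compound nodes and every edge incident to a compound;
#' idempotent, and driver genes keep their fold-change attributes.
#'
#' @param graph A `pathway_context`.
#' @return A `pathway_context` (variant `"genes_only"`).
#' @export
genes_only_view <- function(graph) {
  stopifnot(inherits(graph, "pathway_context"))
  nodes <- graph$nodes[graph$nodes$kind != "compound", , drop = FALSE]
  edges <- graph$edges[graph$edges$a_kind != "compound" &
                         graph$edges$b_kind != "compound", , drop = FALSE]
  pathway_context(nodes, edges, "genes_only")
}

#' Compound-linked view of a context graph
#'
#' Adds the connectivity context that compounds provide: compounds
#' belonging to at least two of the pathways present are retained as
#' linking nodes (compounds of degree < 2 are pruned), and any two
#' pathways sharing one or more compounds are joined by exactly one
#' pathway-pathway edge, however many compounds they share.
#'
#' @param graph A `pathway_context` (typically the driver subgraph).
#' @param network The [metabolic_network()] supplying pathway membership.
#' @return A `pathway_context` (variant `"compound_linked"`).
#' @export
compound_linked_view <- function(graph, network) {
  stopifnot(inherits(graph, "pathway_context"),
            inherits(network, "metabolic_network"))
  present <- graph$nodes$id[graph$nodes$kind == "pathway"]
  mem <- network$pathways
  mem <- mem[mem$kind == "compound" & mem$pathway %in% present, , drop = FALSE]
  deg <- dplyr::count(dplyr::distinct(mem), .data$member)
  linking <- deg$member[deg$n >= 2]

  cpd_edges <- mem[mem$member %in% linking, , drop = FALSE]
  pw_pairs <- if (nrow(cpd_edges)) {
    dplyr::distinct(
      dplyr::inner_join(cpd_edges, cpd_edges, by = "member",
                        relationship = "many-to-many",
                        suffix = c("", ".y")) |>
        dplyr::filter(.data$pathway < .data$pathway.y) |>
        dplyr::select(a = "pathway", b = "pathway.y")
    )
  } else {
    tibble::tibble(a = character(), b = character())
  }

  nodes <- dplyr::bind_rows(
    graph$nodes[graph$nodes$kind != "compound", , drop = FALSE],
    tibble::tibble(id = linking, kind = "compound", fold_change = NA_real_)
  )
  edges <- dplyr::bind_rows(
    graph$edges[graph$edges$a_kind != "compound" &
                  graph$edges$b_kind != "compound", , drop = FALSE],
    tibble::tibble(a = cpd_edges$pathway, a_kind = "pathway",
                   b = cpd_edges$member, b_kind = "compound"),
    tibble::tibble(a = pw_pairs$a, a_kind = "pathway",
                   b = pw_pairs$b, b_kind = "pathway")
  )
  pathway_context(nodes, edges, "compound_linked")
}

#' Signed fold change between treatment and control
#'
#' The ratio of average expression in treatment to control samples, with
#' the negative reciprocal taken for ratios below one, so that a halving
#' reads as -2 rather than 0.5 and colour scales are symmetric. A ratio
#' of exactly one maps to +1. Because the package's expression inputs are
#' log2, values are unlogged (2^x) before averaging by default; set
#' `unlog = FALSE` when the values are already on the linear scale.
#'
#' @param expr An [expression_data()] object.
#' @param features Features to compute (default all).
#' @param unlog Unlog (2^x) before averaging (default TRUE).
#' @return Tibble `feature`, `ratio` (raw treatment/control ratio) and
#'   `fold_change` (signed). A non-positive control mean yields NA with a
#'   warning.
#' @export
fold_change <- function(expr, features = NULL, unlog = TRUE) {
  stopifnot(inherits(expr, "expression_data"))
  v <- expr$values
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(v))
    if (length(miss)) stop("unknown feature(s): ",
                           paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    v <- v[features, , drop = FALSE]
  }
  if (unlog) v <- 2^v
  mt <- unname(rowMeans(v[, expr$classes == "treatment", drop = FALSE]))
  mc <- unname(rowMeans(v[, expr$classes == "control", drop = FALSE]))
  bad <- mc <= 0
  if (any(bad)) warning(sum(bad), " feature(s) with non-positive control ",
                        "mean; fold change undefined", call. = FALSE)
  r <- ifelse(bad, NA_real_, mt / mc)
  fc <- ifelse(is.na(r), NA_real_, ifelse(r >= 1, r, -1 / r))
  tibble::tibble(feature = rownames(v), ratio = r, fold_change = fc)
}

#' Attach fold-change attributes to gene nodes of a context graph
#'
#' @param graph A `pathway_context`.
#' @param expr An [expression_data()] object (gene-level features) or a
#'   tibble with columns `feature` and `fold_change`.
#' @param ... Passed to [fold_change()] when `expr` is expression data.
#' @return The graph with `fold_change` filled for matching gene nodes.
#' @export
annotate_fold_change <- function(graph, expr, ...) {
  stopifnot(inherits(graph, "pathway_context"))
  fc <- if (inherits(expr, "expression_data")) {
    fold_change(expr, ...)
  } else {
    tibble::as_tibble(expr)
  }
  idx <- graph$nodes$kind == "gene"
  m <- match(graph$nodes$id[idx], fc$feature)
  graph$nodes$fold_change[idx] <- fc$fold_change[m]
  graph
}

context_igraph <- function(graph) {
  vs <- prefixed_ids(graph$nodes$id, graph$nodes$kind)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(vs), name = vs,
                            label = graph$nodes$id, kind = graph$nodes$kind,
                            fold_change = graph$nodes$fold_change)
  if (nrow(graph$edges)) {
    ep <- rbind(prefixed_ids(graph$edges$a, graph$edges$a_kind),
                prefixed_ids(graph$edges$b, graph$edges$b_kind))
    g <- igraph::add_edges(g, as.vector(ep))
  }
  g
}

#' Plot a pathway-context graph
#'
#' @param object A `pathway_context`.
#' @param ... Unused.
#' @return A ggplot: force-directed layout, node shape by kind, gene
#'   nodes coloured by signed fold change (blue down, red up).
#' @method autoplot pathway_context
#' @export
autoplot.pathway_context <- function(object, ...) {
  g <- context_igraph(object)
  xy <- igraph::layout_with_fr(g)
  nd <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  ed <- object$edges
  ia <- match(prefixed_ids(ed$a, ed$a_kind),
              prefixed_ids(nd$id, nd$kind))
  ib <- match(prefixed_ids(ed$b, ed$b_kind),
              prefixed_ids(nd$id, nd$kind))
  seg <- tibble::tibble(x = nd$x[ia], y = nd$y[ia],
                        xend = nd$x[ib], yend = nd$y[ib])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(.data$x, .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(.data$x, .data$y,
                                     shape = .data$kind,
                                     fill = .data$fold_change),
                        size = 3, stroke = 0.3, colour = "grey30") +
    ggplot2::scale_shape_manual(values = c(pathway = 22, gene = 21,
                                           compound = 24)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::theme_void() +
    ggplot2::labs(shape = "kind", fill = "fold change")
}
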