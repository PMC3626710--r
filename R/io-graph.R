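#' Export networks and context graphs for Cytoscape-style viewers
#'
#' `write_graphml()` writes GraphML with typed node attributes (`id`,
#' `kind` and, for context graphs, `fold_change`); `read_graphml()` reads
#' it back as an igraph graph. `write_sif()` writes the simple
#' interaction format, one edge per line (`node  relation  node`, the
#' relation being the joined endpoint kinds, e.g. `gene-reaction`), with
#' isolated nodes as single-field lines; node attributes go to an
#' optional TSV sidecar. `read_sif()` returns the edge and node tables.
#'
#' @param x A [metabolic_network()] or `pathway_context`.
#' @param path Output (or input) file path.
#' @param attributes_path Optional sidecar TSV path for node attributes.
#' @return Writers return `path` invisibly. `read_graphml()` returns an
#'   igraph graph; `read_sif()` a list with tibbles `edges`
#'   (`a`, `relation`, `b`) and `nodes` (from the sidecar, or inferred
#'   ids).
#' @export
write_graphml <- function(x, path) {
  g <- as_export_igraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

as_export_igraph <- function(x) {
  if (inherits(x, "metabolic_network")) {
    network_igraph(x)
  } else if (inherits(x, "pathway_context")) {
    context_igraph(x)
  } else if (inherits(x, "igraph")) {
    x
  } else {
    stop("cannot export object of class ", class(x)[1], call. = FALSE)
  }
}

export_tables <- function(x) {
  if (inherits(x, "metabolic_network")) {
    list(
      edges = tibble::tibble(a = x$edges$node,
                             relation = paste(x$edges$node_kind, "reaction",
                                              sep = "-"),
                             b = x$edges$reaction),
      nodes = tibble::tibble(id = x$nodes$id, kind = x$nodes$kind)
    )
  } else if (inherits(x, "pathway_context")) {
    list(
      edges = tibble::tibble(a = x$edges$a,
                             relation = paste(x$edges$a_kind, x$edges$b_kind,
                                              sep = "-"),
                             b = x$edges$b),
      nodes = x$nodes
    )
  } else {
    stop("cannot export object of class ", class(x)[1], call. = FALSE)
  }
}

#' @rdname write_graphml
#' @export
write_sif <- function(x, path, attributes_path = NULL) {
  tabs <- export_tables(x)
  connected <- unique(c(tabs$edges$a, tabs$edges$b))
  isolated <- setdiff(tabs$nodes$id, connected)
  lines <- c(paste(tabs$edges$a, tabs$edges$relation, tabs$edges$b,
                   sep = "\t"),
             isolated)
  writeLines(lines, path)
  if (!is.null(attributes_path)) {
    readr::write_tsv(tabs$nodes, attributes_path)
  }
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_sif <- function(path, attributes_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  ed <- parts[n_fields >= 3]
  edges <- if (length(ed)) {
    dplyr::bind_rows(lapply(ed, function(f) {
      tibble::tibble(a = f[1], relation = f[2], b = f[-(1:2)])
    }))
  } else {
    tibble::tibble(a = character(), relation = character(), b = character())
  }
  iso <- unlist(parts[n_fields == 1])
  nodes <- if (!is.null(attributes_path)) {
    readr::read_tsv(attributes_path, show_col_types = FALSE,
                    progress = FALSE)
  } else {
    tibble::tibble(id = sort(unique(c(edges$a, edges$b, iso))))
  }
  list(edges = edges, nodes = nodes)
}
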