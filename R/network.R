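#' Construct a tripartite metabolic network
#'
#' A metabolic network is an undirected, simple graph over three node kinds:
#' genes, reactions and compounds. Edges are only permitted between a gene
#' and a reaction (the gene catalyses or is otherwise involved in the
#' reaction) or between a compound and a reaction (substrate or product).
#' Pathways are not graph nodes; they are carried separately as membership
#' annotations of genes and compounds.
#'
#' @param edges A data frame with columns `node`, `node_kind`
#'   (`"gene"` or `"compound"`) and `reaction`: one row per
#'   gene-reaction or compound-reaction edge.
#' @param nodes Optional data frame with columns `id` and `kind`
#'   (`"gene"`, `"reaction"` or `"compound"`) listing additional nodes,
#'   e.g. isolated genes. Nodes implied by `edges` are added automatically.
#' @param pathways Optional data frame with columns `pathway`, `member`
#'   and `kind` (`"gene"` or `"compound"`) recording pathway membership.
#'
#' @return An object of class `metabolic_network`: a list with tibbles
#'   `nodes` (id, kind), `edges` (node, node_kind, reaction) and
#'   `pathways` (pathway, member, kind). Duplicate edges are collapsed.
#' @examples
#' net <- metabolic_network(
#'   edges = data.frame(
#'     node = c("g1", "c1", "c2"),
#'     node_kind = c("gene", "compound", "compound"),
#'     reaction = "r1"
#'   )
#' )
#' net
#' @export
metabolic_network <- function(edges = NULL, nodes = NULL, pathways = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(node = character(), node_kind = character(),
                            reaction = character())
  }
  edges <- tibble::as_tibble(edges)[, c("node", "node_kind", "reaction")]
  edges <- dplyr::mutate(edges, dplyr::across(dplyr::everything(), as.character))
  bad <- !edges$node_kind %in% c("gene", "compound")
  if (any(bad)) {
    stop("forbidden edge kind at row(s) ", paste(which(bad), collapse = ", "),
         ": edges may only join a gene or a compound to a reaction",
         call. = FALSE)
  }
  self <- edges$node == edges$reaction
  if (any(self)) {
    stop("self-loop at row(s) ", paste(which(self), collapse = ", "),
         call. = FALSE)
  }
  edges <- dplyr::distinct(edges)

  implied <- dplyr::bind_rows(
    tibble::tibble(id = edges$node, kind = edges$node_kind),
    tibble::tibble(id = edges$reaction, kind = "reaction")
  )
  if (!is.null(nodes)) {
    nodes <- tibble::as_tibble(nodes)[, c("id", "kind")]
    nodes <- dplyr::mutate(nodes, dplyr::across(dplyr::everything(), as.character))
    if (!all(nodes$kind %in% c("gene", "reaction", "compound"))) {
      stop("node kind must be gene, reaction or compound", call. = FALSE)
    }
    implied <- dplyr::bind_rows(implied, nodes)
  }
  nodes <- dplyr::arrange(dplyr::distinct(implied), .data$kind, .data$id)
  # an id reused across kinds is allowed (disambiguated internally by
  # kind-prefixing); the same id twice within a kind is just one node
  if (is.null(pathways)) {
    pathways <- tibble::tibble(pathway = character(), member = character(),
                               kind = character())
  }
  pathways <- tibble::as_tibble(pathways)[, c("pathway", "member", "kind")]
  pathways <- dplyr::mutate(pathways, dplyr::across(dplyr::everything(), as.character))
  if (!all(pathways$kind %in% c("gene", "compound"))) {
    stop("pathway members must be genes or compounds", call. = FALSE)
  }
  pathways <- dplyr::arrange(dplyr::distinct(pathways),
                             .data$pathway, .data$kind, .data$member)

  structure(
    list(nodes = nodes, edges = canonical_edges(edges), pathways = pathways),
    class = "metabolic_network"
  )
}

canonical_edges <- function(edges) {
  dplyr::arrange(edges, .data$node_kind, .data$node, .data$reaction)
}

#' @export
print.metabolic_network <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, c("gene", "reaction", "compound")))
  cat("<metabolic_network> ",
      kinds[["gene"]], " genes, ",
      kinds[["reaction"]], " reactions, ",
      kinds[["compound"]], " compounds; ",
      nrow(x$edges), " edges; ",
      dplyr::n_distinct(x$pathways$pathway), " pathways\n", sep = "")
  invisible(x)
}

# internal: unique kind-prefixed vertex names, immune to id collisions
# across kinds
prefixed_ids <- function(ids, kinds) paste(kinds, ids, sep = ":")

#' Convert a metabolic network to an igraph graph
#'
#' Vertices carry `kind` and `label` (raw id) attributes; vertex
#' names are
#' kind-prefixed (`"gene:YAL001C"`) so that a compound and a gene sharing
#' a raw identifier stay distinct.
#'
#' @param network A [metabolic_network()].
#' @return An undirected [igraph::igraph] object.
#' @export
network_igraph <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  vs <- prefixed_ids(network$nodes$id, network$nodes$kind)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(vs), name = vs,
                            kind = network$nodes$kind, label = network$nodes$id)
  if (nrow(network$edges) > 0) {
    ep <- rbind(prefixed_ids(network$edges$node, network$edges$node_kind),
                prefixed_ids(network$edges$reaction, "reaction"))
    g <- igraph::add_edges(g, as.vector(ep))
  }
  g
}

#' Parse KGML pathway XML documents into one merged metabolic network
#'
#' Reads pathway files in the KGML dialect. `entry` elements of type
#' `gene` or `ortholog` become gene nodes (an entry naming several genes
#' yields several nodes); `reaction` elements become reaction nodes with
#' compound nodes for their substrates and products; gene entries are
#' joined to the reactions listed in their `reaction` attribute. Entries
#' of type `map` are skipped (they reference other pathways), and any
#' other entry type is skipped with a warning. The same identifier
#' appearing in several documents becomes a single node, so the result is
#' one merged network. Each document also contributes a pathway-membership
#' record (its genes and compounds) under the document's `title`
#' attribute (falling back to `name`).
#'
#' @param paths Character vector of file paths, or a list of XML strings.
#' @return A [metabolic_network()].
#' @export
parse_kgml <- function(paths) {
  docs <- lapply(paths, function(p) {
    tryCatch(xml2::read_xml(p), error = function(e) {
      stop("malformed XML in ", if (file.exists(p)) p else "document",
           ": ", conditionMessage(e), call. = FALSE)
    })
  })
  edge_rows <- list()
  node_rows <- list()
  pw_rows <- list()
  for (doc in docs) {
    root <- xml2::xml_find_first(doc, "/pathway")
    if (is.na(root)) stop("not a KGML document: missing <pathway> root",
                          call. = FALSE)
    pw_name <- xml2::xml_attr(root, "title")
    if (is.na(pw_name) || pw_name == "") pw_name <- xml2::xml_attr(root, "name")

    for (entry in xml2::xml_find_all(doc, ".//entry")) {
      type <- xml2::xml_attr(entry, "type")
      if (is.na(type)) type <- ""
      if (type %in% c("gene", "ortholog")) {
        genes <- strsplit(trimws(xml2::xml_attr(entry, "name")), "\\s+")[[1]]
        genes <- genes[nzchar(genes)]
        node_rows[[length(node_rows) + 1]] <-
          tibble::tibble(id = genes, kind = "gene")
        pw_rows[[length(pw_rows) + 1]] <-
          tibble::tibble(pathway = pw_name, member = genes, kind = "gene")
        rxn_attr <- xml2::xml_attr(entry, "reaction")
        if (!is.na(rxn_attr) && nzchar(trimws(rxn_attr))) {
          rxns <- strsplit(trimws(rxn_attr), "\\s+")[[1]]
          grid <- expand.grid(node = genes, reaction = rxns,
                              stringsAsFactors = FALSE)
          edge_rows[[length(edge_rows) + 1]] <-
            tibble::tibble(node = grid$node, node_kind = "gene",
                           reaction = grid$reaction)
        }
      } else if (type == "compound") {
        cpds <- strsplit(trimws(xml2::xml_attr(entry, "name")), "\\s+")[[1]]
        cpds <- cpds[nzchar(cpds)]
        node_rows[[length(node_rows) + 1]] <-
          tibble::tibble(id = cpds, kind = "compound")
        pw_rows[[length(pw_rows) + 1]] <-
          tibble::tibble(pathway = pw_name, member = cpds, kind = "compound")
      } else if (type == "map") {
        # cross-references to other pathway maps: not graph material
      } else {
        warning("skipping entry of unknown type '", type, "'", call. = FALSE)
      }
    }

    for (rxn in xml2::xml_find_all(doc, ".//reaction")) {
      rids <- strsplit(trimws(xml2::xml_attr(rxn, "name")), "\\s+")[[1]]
      rids <- rids[nzchar(rids)]
      cpds <- xml2::xml_attr(
        xml2::xml_find_all(rxn, "./substrate | ./product"), "name")
      cpds <- unique(cpds[!is.na(cpds)])
      for (rid in rids) {
        node_rows[[length(node_rows) + 1]] <-
          tibble::tibble(id = rid, kind = "reaction")
        if (length(cpds)) {
          edge_rows[[length(edge_rows) + 1]] <-
            tibble::tibble(node = cpds, node_kind = "compound", reaction = rid)
          pw_rows[[length(pw_rows) + 1]] <-
            tibble::tibble(pathway = pw_name, member = cpds, kind = "compound")
        }
      }
    }
  }
  metabolic_network(
    edges = dplyr::bind_rows(edge_rows),
    nodes = if (length(node_rows)) {
      nr <- dplyr::bind_rows(node_rows); names(nr) <- c("id", "kind"); nr
    } else NULL,
    pathways = dplyr::bind_rows(pw_rows)
  )
}

#' Read and write the plain tripartite edge-list format
#'
#' A TSV with header `node_a  kind_a  node_b  kind_b`. Edge rows join a
#' gene or compound (`node_a`) to a reaction (`node_b`, `kind_b ==
#' "reaction"`). Membership rows use `kind_b == "pathway"`: `node_a` (a
#' gene or compound) is recorded as a member of the pathway named
#' `node_b`, without creating a graph edge. Any other kind pair is a
#' validation error. `write_edgelist()` emits the canonical sorted form
#' (UTF-8, LF, header row), so write-after-parse is byte-stable.
#'
#' @param path File path (or, for `parse_edgelist`, a literal string
#'   containing TSV text with at least one newline).
#' @param network A [metabolic_network()].
#' @return `parse_edgelist()` returns a [metabolic_network()];
#'   `write_edgelist()` returns `path` invisibly.
#' @export
parse_edgelist <- function(path) {
  txt <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    readr::read_file(path)
  } else {
    paste(path, collapse = "\n")
  }
  if (!nzchar(trimws(txt))) return(metabolic_network())
  df <- utils::read.table(text = txt, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("node_a", "kind_a", "node_b", "kind_b")
  if (!all(need %in% names(df))) {
    stop("edge list must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  is_member <- df$kind_b == "pathway"
  ed <- df[!is_member, , drop = FALSE]
  ok <- ed$kind_a %in% c("gene", "compound") & ed$kind_b == "reaction"
  if (any(!ok)) {
    stop("forbidden edge kind pair (", ed$kind_a[!ok][1], "-",
         ed$kind_b[!ok][1], ") at data row ",
         which(!is_member)[which(!ok)[1]], call. = FALSE)
  }
  mem <- df[is_member, , drop = FALSE]
  if (nrow(mem) && !all(mem$kind_a %in% c("gene", "compound"))) {
    stop("pathway membership rows must name a gene or compound",
         call. = FALSE)
  }
  metabolic_network(
    edges = tibble::tibble(node = ed$node_a, node_kind = ed$kind_a,
                           reaction = ed$node_b),
    pathways = if (nrow(mem)) {
      tibble::tibble(pathway = mem$node_b, member = mem$node_a,
                     kind = mem$kind_a)
    } else NULL
  )
}

#' @rdname parse_edgelist
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  ed <- tibble::tibble(node_a = network$edges$node,
                       kind_a = network$edges$node_kind,
                       node_b = network$edges$reaction,
                       kind_b = "reaction")
  mem <- tibble::tibble(node_a = network$pathways$member,
                        kind_a = network$pathways$kind,
                        node_b = network$pathways$pathway,
                        kind_b = "pathway")
  out <- dplyr::arrange(dplyr::bind_rows(ed, mem),
                        .data$kind_b, .data$kind_a, .data$node_a, .data$node_b)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Size of the unconstrained gene-set search space
#'
#' The number of distinct sets of `setsize` genes drawn from `genes`
#' candidates is the binomial coefficient `choose(genes, setsize)`. For a
#' genome-scale `genes` this overflows double precision, so the
#' coefficient is computed exactly in arbitrary precision; it is the
#' motivation for constrained, network-guided set generation rather than
#' enumeration.
#'
#' @param genes Number of genes (positive integer).
#' @param setsize Set size (non-negative integer, at most `genes`).
#' @return An object of class `set_space`: the exact coefficient as a
#'   decimal string (`$exact`) with a double approximation (`$approx`).
#' @examples
#' binomial_set_space(12, 5)    # 792
#' binomial_set_space(6000, 8)  # ~4.1e25 possible 8-gene sets in yeast
#' @export
binomial_set_space <- function(genes, setsize) {
  stopifnot(length(genes) == 1, length(setsize) == 1)
  if (genes < 1 || genes != floor(genes)) {
    stop("genes must be a positive integer", call. = FALSE)
  }
  if (setsize < 0 || setsize != floor(setsize)) {
    stop("setsize must be a non-negative integer", call. = FALSE)
  }
  if (setsize > genes) stop("setsize must not exceed genes", call. = FALSE)
  k <- min(setsize, genes - setsize)
  # exact product formula; each intermediate prod_{i<=j}(n-k+i)/i is an
  # integer, so small-divisor division stays exact in the bignum
  big <- bignum_one()
  for (i in seq_len(k)) {
    big <- bignum_mul_small(big, genes - k + i)
    big <- bignum_div_small(big, i)
  }
  exact <- bignum_format(big)
  structure(list(exact = exact, approx = as.numeric(exact)),
            class = "set_space")
}

#' @export
print.set_space <- function(x, ...) {
  cat("<set_space> ", x$exact, " (~", format(x$approx, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' @export
format.set_space <- function(x, ...) x$exact

# --- minimal non-negative bignum: little-endian base-1e4 digit vector ----
BIGNUM_BASE <- 10000L

bignum_one <- function() 1L

bignum_mul_small <- function(x, m) {
  # m must stay below ~2^31 / base
  stopifnot(m < 214748L)
  prod <- as.double(x) * m
  carry <- 0
  for (i in seq_along(prod)) {
    v <- prod[i] + carry
    prod[i] <- v %% BIGNUM_BASE
    carry <- v %/% BIGNUM_BASE
  }
  while (carry > 0) {
    prod <- c(prod, carry %% BIGNUM_BASE)
    carry <- carry %/% BIGNUM_BASE
  }
  as.integer(prod)
}

bignum_div_small <- function(x, d) {
  out <- integer(length(x))
  rem <- 0
  for (i in rev(seq_along(x))) {
    cur <- rem * BIGNUM_BASE + x[i]
    out[i] <- cur %/% d
    rem <- cur %% d
  }
  stopifnot(rem == 0)  # callers guarantee exact division
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

bignum_format <- function(x) {
  digits <- rev(x)
  paste0(digits[1],
         paste(sprintf("%04d", digits[-1]), collapse = ""))
}
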