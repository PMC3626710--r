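#' All-against-all overlap census of a set collection
#'
#' Compares every unordered pair of sets (self-pairs excluded) by set
#' intersection. A semi-exhaustive collection shows many small overlaps
#' but mostly empty intersections: the sets tile local neighbourhoods of
#' the network without becoming redundant.
#'
#' @param sets A `geneset_collection` with at least 2 sets.
#' @return An `overlap_census` list: `pairs_total`, `pairs_empty`,
#'   `size_histogram` (tibble `intersection_size`, `n_pairs`) and
#'   `per_set` (tibble `set`, `n_intersecting` = how many other sets it
#'   overlaps).
#' @export
overlap_census <- function(sets) {
  stopifnot(inherits(sets, "geneset_collection"), nrow(sets) >= 2)
  members <- sets$members
  univ <- sort(unique(unlist(members)))
  M <- matrix(0, length(univ), length(members))
  for (i in seq_along(members)) M[match(members[[i]], univ), i] <- 1
  X <- crossprod(M)                     # S x S intersection sizes
  ut <- X[upper.tri(X)]
  hist <- dplyr::count(tibble::tibble(intersection_size = as.integer(ut)),
                       .data$intersection_size, name = "n_pairs")
  per_set <- tibble::tibble(
    set = sets$set,
    n_intersecting = as.integer(colSums(X > 0) - 1)
  )
  structure(list(pairs_total = length(ut),
                 pairs_empty = sum(ut == 0),
                 size_histogram = hist,
                 per_set = per_set),
            class = "overlap_census")
}

#' @export
print.overlap_census <- function(x, ...) {
  cat("<overlap_census> ", x$pairs_total, " pairs, ", x$pairs_empty,
      " empty (", sprintf("%.1f", 100 * x$pairs_empty / x$pairs_total),
      "%)\n", sep = "")
  invisible(x)
}

#' Histogram of pairwise intersection sizes
#'
#' @param object An `overlap_census`.
#' @param ... Unused.
#' @return A ggplot, log10 counts of pairs by intersection size.
#' @method autoplot overlap_census
#' @export
autoplot.overlap_census <- function(object, ...) {
  ggplot2::ggplot(object$size_histogram,
                  ggplot2::aes(.data$intersection_size, .data$n_pairs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "intersection size", y = "set pairs (log10)") +
    ggplot2::theme_minimal()
}

#' How many sets each member belongs to
#'
#' @param sets A `geneset_collection`.
#' @return Tibble `member`, `n_sets`, sorted by decreasing count (rank
#'   order); members in no set are absent.
#' @export
membership_counts <- function(sets) {
  stopifnot(inherits(sets, "geneset_collection"))
  dplyr::arrange(
    dplyr::count(tibble::tibble(member = unlist(sets$members)),
                 .data$member, name = "n_sets"),
    dplyr::desc(.data$n_sets), .data$member)
}

#' Intra-set graph distances of gene sets on the metabolic network
#'
#' Distances are unweighted shortest paths on the full
#' gene-reaction-compound graph; two genes on the same reaction are at
#' distance 2, genes on adjacent reactions sharing a compound at
#' distance 4. Small per-set means relative to the all-pairs mean show
#' that sets model local network topology. Disconnected pairs carry no
#' distance and are counted separately.
#'
#' @param sets A gene-level `geneset_collection` (members are matched to
#'   gene node ids; probeset-level collections cannot be placed on the
#'   graph).
#' @param network The [metabolic_network()].
#' @return A list: `per_set` (tibble `set`, `mean_distance`,
#'   `n_pairs_connected`, `n_pairs_disconnected`), `global_mean` (mean
#'   over all connected gene pairs in the network) and `all_pairs`
#'   (tibble `distance`, `n_pairs` over all gene pairs).
#' @export
intra_set_distances <- function(sets, network) {
  stopifnot(inherits(sets, "geneset_collection"),
            inherits(network, "metabolic_network"))
  g <- network_igraph(network)
  genes <- network$nodes$id[network$nodes$kind == "gene"]
  vg <- prefixed_ids(genes, "gene")
  D <- igraph::distances(g, v = vg, to = vg)
  rownames(D) <- colnames(D) <- genes
  ut <- D[upper.tri(D)]
  fin <- is.finite(ut)
  all_pairs <- dplyr::count(
    tibble::tibble(distance = ifelse(fin, ut, Inf)),
    .data$distance, name = "n_pairs")
  per_set <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    mem <- intersect(sets$members[[i]], genes)
    if (length(mem) < 2) {
      return(tibble::tibble(set = sets$set[i], mean_distance = NA_real_,
                            n_pairs_connected = 0L,
                            n_pairs_disconnected = 0L))
    }
    d <- D[mem, mem][upper.tri(diag(length(mem)))]
    conn <- is.finite(d)
    tibble::tibble(set = sets$set[i],
                   mean_distance = if (any(conn)) mean(d[conn]) else NA_real_,
                   n_pairs_connected = sum(conn),
                   n_pairs_disconnected = sum(!conn))
  })
  list(per_set = per_set,
       global_mean = mean(ut[fin]),
       all_pairs = all_pairs)
}

#' Classical single-pathway baseline sets
#'
#' One set per pathway, its members being the pathway's genes — the
#' traditional gene-set construction this package's network-wide sets
#' are compared against. Pathways without genes yield no set.
#'
#' @param network A [metabolic_network()] with pathway membership.
#' @return A `geneset_collection` (method `"pathway"`).
#' @export
single_pathway_sets <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  pw <- network$pathways[network$pathways$kind == "gene", , drop = FALSE]
  if (nrow(pw) == 0) {
    return(gene_set_collection(tibble::tibble(set = character(),
                                              members = list())))
  }
  df <- pw |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(members = list(unique(.data$member)), .groups = "drop")
  gene_set_collection(tibble::tibble(
    set = df$pathway, component = NA_integer_, arm = NA_character_,
    method = "pathway", parameter = NA_character_, members = df$members))
}

#' Compare two gene result lists
#'
#' Set-theoretic partition of two result gene lists (e.g. driver genes
#' from network-wide sets versus genes from single-pathway sets):
#' the shared genes, those found only by the first and those found only
#' by the second.
#'
#' @param result_a,result_b Character vectors of gene ids.
#' @return A list with `shared`, `a_only`, `b_only` (sorted vectors) and
#'   a one-row `counts` tibble.
#' @export
compare_results <- function(result_a, result_b) {
  a <- sort(unique(as.character(result_a)))
  b <- sort(unique(as.character(result_b)))
  out <- list(shared = intersect(a, b),
              a_only = setdiff(a, b),
              b_only = setdiff(b, a))
  out$counts <- tibble::tibble(
    n_shared = length(out$shared),
    n_a_only = length(out$a_only),
    n_b_only = length(out$b_only)
  )
  out
}

#' Write the census tables of a collection as TSV files
#'
#' @param sets A `geneset_collection`.
#' @param dir Output directory (created if needed).
#' @param network Optional [metabolic_network()]; when given, intra-set
#'   distance tables are written too.
#' @return Invisibly, the paths written.
#' @export
write_analytics <- function(sets, dir, network = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  oc <- overlap_census(sets)
  p <- file.path(dir, "overlap_size_histogram.tsv")
  readr::write_tsv(oc$size_histogram, p); paths <- c(paths, p)
  p <- file.path(dir, "overlap_per_set.tsv")
  readr::write_tsv(oc$per_set, p); paths <- c(paths, p)
  p <- file.path(dir, "membership_counts.tsv")
  readr::write_tsv(membership_counts(sets), p); paths <- c(paths, p)
  if (!is.null(network)) {
    dist <- intra_set_distances(sets, network)
    p <- file.path(dir, "intra_set_distances.tsv")
    readr::write_tsv(dist$per_set, p); paths <- c(paths, p)
    p <- file.path(dir, "gene_distance_distribution.tsv")
    readr::write_tsv(dist$all_pairs, p); paths <- c(paths, p)
  }
  invisible(paths)
}
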