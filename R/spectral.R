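#' Build the Laplacian model of a metabolic network
#'
#' Forms the adjacency matrix A, the diagonal degree matrix D and the
#' combinatorial Laplacian L = D - A of the undirected tripartite graph,
#' over the canonical node ordering (lexicographic by kind, then id).
#' The Laplacian is symmetric, its rows sum to zero, and the multiplicity
#' of its zero eigenvalue equals the number of connected components.
#'
#' @param network A [metabolic_network()] with at least one node.
#' @return An object of class `laplacian_model`: node ordering (tibble
#'   `node_order` with `id`, `kind`), matrices `A`, `D`, `L`, and empty
#'   PCA slots to be filled by [pca_of_laplacian()].
#' @seealso [pca_of_laplacian()]
#' @export
build_laplacian <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  nodes <- dplyr::arrange(network$nodes, .data$kind, .data$id)
  n <- nrow(nodes)
  if (n == 0) stop("network has no nodes", call. = FALSE)
  key <- prefixed_ids(nodes$id, nodes$kind)
  A <- matrix(0, n, n, dimnames = list(key, key))
  if (nrow(network$edges) > 0) {
    i <- match(prefixed_ids(network$edges$node, network$edges$node_kind), key)
    j <- match(prefixed_ids(network$edges$reaction, "reaction"), key)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  D <- diag(rowSums(A), n)
  dimnames(D) <- dimnames(A)
  L <- D - A
  structure(
    list(node_order = nodes, A = A, D = D, L = L,
         scores = NULL, loadings = NULL, variance_fraction = NULL,
         center = NULL),
    class = "laplacian_model"
  )
}

#' Principal component analysis of the Laplacian matrix
#'
#' Columns of L are mean-centered (no variance scaling) and decomposed by
#' PCA; each node's score on a component is its projection onto that
#' component. Because eigenvector signs are arbitrary, each component's
#' sign is fixed so that its largest-magnitude loading is positive (ties
#' broken by lowest node index); within blocks of numerically equal
#' variance, components are ordered by their score vectors so the
#' decomposition is fully deterministic. Nearly all metabolic Laplacians
#' need close to n - 1 components to exhaust the variance — the model is
#' not low-rank, which is precisely why individual components isolate
#' small local graph structures usable as gene sets.
#'
#' @param model A `laplacian_model` from [build_laplacian()].
#' @param tol Relative standard-deviation cutoff below which trailing
#'   components are treated as zero-variance and dropped.
#' @return The model with `scores` (node x component), `loadings`,
#'   `variance_fraction` (normalised over retained components) and
#'   `center` filled in.
#' @export
pca_of_laplacian <- function(model, tol = 1e-8) {
  stopifnot(inherits(model, "laplacian_model"))
  n <- nrow(model$L)
  if (n < 2) stop("PCA needs at least 2 nodes", call. = FALSE)
  pc <- stats::prcomp(model$L, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev) * tol
  keep[1] <- TRUE
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  sdev <- pc$sdev[keep]

  # deterministic sign: the largest-|.| loading of each component is
  # positive; ties resolved by the lowest row index
  for (k in seq_len(ncol(scores))) {
    lead <- which.max(abs(loadings[, k]))
    if (loadings[lead, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  # stabilise ordering inside blocks of numerically tied variance
  ord <- seq_len(ncol(scores))
  grp <- cumsum(c(TRUE, diff(sdev) < -max(sdev) * 1e-10))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1) {
      keys <- apply(round(scores[, idx, drop = FALSE], 9), 2, paste,
                    collapse = ",")
      ord[idx] <- idx[order(keys)]
    }
  }
  scores <- scores[, ord, drop = FALSE]
  loadings <- loadings[, ord, drop = FALSE]
  sdev <- sdev[ord]
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(sdev))

  model$scores <- scores
  model$loadings <- loadings
  model$sdev <- sdev
  model$variance_fraction <- sdev^2 / sum(sdev^2)
  model$center <- pc$center
  model
}

#' @export
print.laplacian_model <- function(x, ...) {
  cat("<laplacian_model> ", nrow(x$L), " nodes", sep = "")
  if (!is.null(x$scores)) {
    cat("; ", ncol(x$scores), " principal components (",
        sprintf("%.1f", 100 * max(x$variance_fraction)),
        "% max variance per component)", sep = "")
  } else {
    cat("; PCA not yet computed")
  }
  cat("\n")
  invisible(x)
}

#' Tidy per-component summary of a Laplacian PCA model
#'
#' @param x A `laplacian_model` with PCA computed.
#' @param ... Unused.
#' @return A tibble with one row per principal component: `component`,
#'   `sdev`, `variance_fraction`, `cumulative_variance`.
#' @method tidy laplacian_model
#' @export
tidy.laplacian_model <- function(x, ...) {
  if (is.null(x$variance_fraction)) {
    stop("run pca_of_laplacian() first", call. = FALSE)
  }
  tibble::tibble(
    component = seq_along(x$variance_fraction),
    sdev = x$sdev,
    variance_fraction = x$variance_fraction,
    cumulative_variance = cumsum(x$variance_fraction)
  )
}

#' One-line summary of a Laplacian PCA model
#'
#' @param x A `laplacian_model`.
#' @param ... Unused.
#' @return A one-row tibble: node counts by kind, edge count, number of
#'   retained components, and the largest single-component variance share.
#' @method glance laplacian_model
#' @export
glance.laplacian_model <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$node_order),
    n_genes = sum(x$node_order$kind == "gene"),
    n_reactions = sum(x$node_order$kind == "reaction"),
    n_compounds = sum(x$node_order$kind == "compound"),
    n_components = if (is.null(x$scores)) NA_integer_ else ncol(x$scores),
    max_variance_fraction = if (is.null(x$variance_fraction)) NA_real_
                            else max(x$variance_fraction)
  )
}

#' Long-format PCA scores
#'
#' @param model A `laplacian_model` with PCA computed.
#' @param kinds Node kinds to keep (default all).
#' @return A tibble `id`, `kind`, `component`, `score`.
#' @export
score_table <- function(model, kinds = c("gene", "reaction", "compound")) {
  stopifnot(inherits(model, "laplacian_model"), !is.null(model$scores))
  keep <- model$node_order$kind %in% kinds
  sc <- model$scores[keep, , drop = FALSE]
  tibble::tibble(
    id = rep(model$node_order$id[keep], times = ncol(sc)),
    kind = rep(model$node_order$kind[keep], times = ncol(sc)),
    component = rep(seq_len(ncol(sc)), each = nrow(sc)),
    score = as.vector(sc)
  )
}

#' Scree plot of the Laplacian PCA
#'
#' @param object A `laplacian_model` with PCA computed.
#' @param ... Unused.
#' @return A ggplot: percentage of variance explained per component.
#' @method autoplot laplacian_model
#' @export
autoplot.laplacian_model <- function(object, ...) {
  df <- tibble::tibble(
    component = seq_along(object$variance_fraction),
    pct = 100 * object$variance_fraction
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$pct)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "Principal component",
                  y = "% variance explained",
                  title = "Laplacian PCA scree") +
    ggplot2::theme_minimal()
}

#' Write PCA scores and the scree table as TSV
#'
#' @param model A `laplacian_model` with PCA computed.
#' @param scores_path,scree_path Output file paths (either may be NULL to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_spectral_tables <- function(model, scores_path = NULL,
                                  scree_path = NULL) {
  stopifnot(inherits(model, "laplacian_model"), !is.null(model$scores))
  if (!is.null(scores_path)) {
    df <- dplyr::bind_cols(model$node_order,
                           tibble::as_tibble(model$scores))
    readr::write_tsv(df, scores_path)
  }
  if (!is.null(scree_path)) {
    readr::write_tsv(
      tibble::tibble(component = seq_along(model$variance_fraction),
                     variance_fraction = model$variance_fraction),
      scree_path)
  }
  invisible(c(scores_path, scree_path))
}
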