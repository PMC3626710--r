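#' Translate probe set ids back to genes
#'
#' @param probesets Character vector of probe set ids.
#' @param mapping A tibble `gene`, `probeset`.
#' @return Sorted unique gene ids with at least one listed probe set.
#' @export
probes_to_genes <- function(probesets, mapping) {
  stopifnot(all(c("gene", "probeset") %in% names(mapping)))
  sort(unique(mapping$gene[mapping$probeset %in% probesets]))
}

#' Run the full network-PCA gene set analysis pipeline
#'
#' Chains the stages: Laplacian PCA of the metabolic network, gene set
#' generation (threshold or step-function), max-mean GSA against the
#' expression data, hypergeometric driver enrichment, and the
#' pathway-centric context views of the called drivers with fold-change
#' annotation. With the threshold method, GSA is run separately on each
#' threshold's collection (each threshold is its own analysis, as in the
#' original procedure) and the per-threshold significance calls are
#' pooled into one driver contingency over the whole post-threshold
#' collection. When a probe mapping is supplied, sets are generated at
#' probe level and the driver test is gene-centric (probe sets
#' translated back to genes).
#'
#' @param network A [metabolic_network()].
#' @param expr An [expression_data()] object.
#' @param mapping Optional probe mapping tibble (`gene`, `probeset`).
#' @param method Set generation method: `"threshold"` or `"step"`.
#' @param thresholds Integer thresholds for the threshold method.
#' @param set_minsize Minimum set size after probe substitution (5).
#' @param nperms,gsa_minsize,fdr_cut Passed to [run_gsa()].
#' @param q_cut Driver call cutoff on the Holm-adjusted q (0.1).
#' @param seed Seed for the GSA permutations.
#' @param ndraws Restandardization draws, passed to [run_gsa()].
#' @return A `lapgsa_result` list: `model`, `sets`, `gsa`, `drivers`
#'   (the report), `driver_genes`, `context_genes_only`,
#'   `context_compound_linked` (contexts are NULL when the network has no
#'   pathway membership or no driver was called).
#' @export
run_lapgsa <- function(network, expr, mapping = NULL,
                       method = c("threshold", "step"),
                       thresholds = 1:10, set_minsize = 5,
                       nperms = 1000, gsa_minsize = 2, fdr_cut = 0.05,
                       q_cut = 0.1, seed = NULL, ndraws = 500) {
  method <- match.arg(method)
  model <- pca_of_laplacian(build_laplacian(network))
  sets <- if (method == "threshold") {
    threshold_sets(model, thresholds = thresholds, mapping = mapping,
                   minsize = set_minsize)
  } else {
    step_function_sets(model, mapping = mapping, minsize = set_minsize)
  }
  if (method == "threshold") {
    parts <- lapply(sort(unique(sets$parameter)), function(t) {
      st <- sets[sets$parameter == t, , drop = FALSE]
      tibble::as_tibble(run_gsa(expr, st, nperms = nperms,
                                minsize = gsa_minsize, fdr_cut = fdr_cut,
                                seed = seed, ndraws = ndraws))
    })
    gsa <- new_gsa_result(dplyr::bind_rows(parts), tibble::tibble(),
                          nperms, gsa_minsize, fdr_cut)
  } else {
    gsa <- run_gsa(expr, sets, nperms = nperms, minsize = gsa_minsize,
                   fdr_cut = fdr_cut, seed = seed, ndraws = ndraws)
  }
  report <- driver_enrichment(sets, gsa, q_cut = q_cut, mapping = mapping)
  driver_genes <- call_drivers(report)

  ctx_genes <- ctx_cpds <- NULL
  if (nrow(network$pathways) > 0 && length(driver_genes) > 0) {
    pg <- build_pathway_graph(network)
    gene_feats <- intersect(network$nodes$id[network$nodes$kind == "gene"],
                            rownames(expr$values))
    if (length(gene_feats)) {
      pg <- annotate_fold_change(pg, expr)
    } else if (!is.null(mapping)) {
      fc <- fold_change(expr)
      fc_gene <- fc |>
        dplyr::inner_join(mapping, by = c(feature = "probeset")) |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(fold_change = mean(.data$fold_change),
                         .groups = "drop") |>
        dplyr::rename(feature = "gene")
      pg <- annotate_fold_change(pg, fc_gene)
    }
    ds <- driver_subgraph(pg, driver_genes)
    ctx_genes <- genes_only_view(ds)
    ctx_cpds <- compound_linked_view(ds, network)
  }
  structure(list(model = model, sets = sets, gsa = gsa, drivers = report,
                 driver_genes = driver_genes,
                 context_genes_only = ctx_genes,
                 context_compound_linked = ctx_cpds),
            class = "lapgsa_result")
}

#' @export
print.lapgsa_result <- function(x, ...) {
  cat("<lapgsa_result>\n")
  cat("  components: ", ncol(x$model$scores), "\n", sep = "")
  cat("  sets:       ", nrow(x$sets), "\n", sep = "")
  cat("  significant:", sum(x$gsa$significant), "of", nrow(x$gsa),
      "tested\n")
  cat("  drivers:    ", length(call_drivers(x$drivers)),
      " (", length(x$driver_genes), " genes)\n", sep = "")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `lapgsa_result`.
#' @param ... Unused.
#' @return Tibble with component, set, significant-set and driver counts.
#' @method glance lapgsa_result
#' @export
glance.lapgsa_result <- function(x, ...) {
  tibble::tibble(
    n_components = ncol(x$model$scores),
    n_sets = nrow(x$sets),
    n_sets_tested = nrow(x$gsa),
    n_significant = sum(x$gsa$significant),
    n_driver_members = length(call_drivers(x$drivers)),
    n_driver_genes = length(x$driver_genes)
  )
}
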