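#' Gene set collections
#'
#' A gene set collection is a tibble with one row per set: `set` (unique
#' name), `component` (principal component index or NA), `arm`
#' (`"pos"`/`"neg"`/NA), `method` (`"threshold"`, `"step"`, `"pathway"` or
#' `"custom"`), `parameter` (threshold value or step index, as character)
#' and `members` (list-column of sorted unique member identifiers).
#'
#' @param x A data frame with those columns (missing provenance columns
#'   are filled with NA).
#' @return A `geneset_collection` tibble.
#' @export
gene_set_collection <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("set", "members") %in% names(x))) {
    stop("a collection needs at least `set` and `members` columns",
         call. = FALSE)
  }
  for (col in c("component", "arm", "method", "parameter")) {
    if (!col %in% names(x)) {
      x[[col]] <- if (col == "component") NA_integer_ else NA_character_
    }
  }
  x <- x[, c("set", "component", "arm", "method", "parameter", "members")]
  x$component <- as.integer(x$component)
  x$members <- lapply(x$members, function(m) sort(unique(as.character(m))))
  if (anyDuplicated(x$set)) {
    stop("set names must be unique within a collection", call. = FALSE)
  }
  if (any(lengths(x$members) == 0)) {
    stop("sets must be non-empty", call. = FALSE)
  }
  class(x) <- c("geneset_collection", class(tibble::tibble()))
  x
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("<geneset_collection> ", nrow(x), " sets; member counts ",
      if (nrow(x)) paste0(min(lengths(x$members)), "-",
                          max(lengths(x$members))) else "-",
      "\n", sep = "")
  NextMethod()
}

# threshold/step share this tail: optional probe substitution, then the
# minimum-size filter
finalize_sets <- function(rows, mapping, minsize) {
  if (length(rows) == 0) {
    return(gene_set_collection(tibble::tibble(
      set = character(), component = integer(), arm = character(),
      method = character(), parameter = character(), members = list()
    )))
  }
  df <- dplyr::bind_rows(rows)
  if (!is.null(mapping)) {
    df$members <- lapply(df$members, map_genes_to_probes, mapping = mapping)
  }
  df <- df[lengths(df$members) >= minsize, , drop = FALSE]
  gene_set_collection(df)
}

#' Threshold-based gene set generation from PCA scores
#'
#' For every principal component and every integer threshold t, two
#' candidate sets are formed from the gene nodes only: the positive arm
#' (genes with score strictly greater than t) and the negative arm (genes
#' with score strictly less than -t). If a probe mapping is supplied each
#' gene is replaced by its probe sets (genes without probes drop out)
#' before the size filter. Sets with fewer than `minsize` members are
#' discarded. Within one component arm the sets are nested: raising the
#' threshold can only shrink a set, which gives the collection its
#' zoom-in/zoom-out character.
#'
#' @param model A `laplacian_model` with PCA scores.
#' @param thresholds Positive integer thresholds (default 1:10).
#' @param mapping Optional probe mapping tibble (`gene`, `probeset`), see
#'   [read_probe_mapping()].
#' @param minsize Minimum members a set must retain (default 5).
#' @return A `geneset_collection`; names follow `PC<k>.<pos|neg>.t<t>`.
#' @export
threshold_sets <- function(model, thresholds = 1:10, mapping = NULL,
                           minsize = 5) {
  stopifnot(inherits(model, "laplacian_model"), !is.null(model$scores))
  if (any(thresholds != floor(thresholds)) || any(thresholds <= 0)) {
    stop("thresholds must be positive integers", call. = FALSE)
  }
  is_gene <- model$node_order$kind == "gene"
  ids <- model$node_order$id[is_gene]
  sc <- model$scores[is_gene, , drop = FALSE]
  rows <- list()
  for (k in seq_len(ncol(sc))) {
    s <- sc[, k]
    for (t in thresholds) {
      pos <- ids[s > t]
      if (length(pos)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          set = sprintf("PC%d.pos.t%d", k, t), component = k, arm = "pos",
          method = "threshold", parameter = as.character(t),
          members = list(pos))
      }
      neg <- ids[s < -t]
      if (length(neg)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          set = sprintf("PC%d.neg.t%d", k, t), component = k, arm = "neg",
          method = "threshold", parameter = as.character(t),
          members = list(neg))
      }
    }
  }
  finalize_sets(rows, mapping, minsize)
}

# ranked scores (already restricted to one arm, magnitudes > 1, sorted by
# increasing magnitude) -> list of index groups; a gap of exactly 1 splits
split_score_runs <- function(magnitudes) {
  if (length(magnitudes) == 0) return(list())
  groups <- list()
  current <- 1L
  if (length(magnitudes) > 1) {
    for (i in 2:length(magnitudes)) {
      if (magnitudes[i] - magnitudes[i - 1] < 1) {
        current <- c(current, i)
      } else {
        groups[[length(groups) + 1]] <- current
        current <- i
      }
    }
  }
  groups[[length(groups) + 1]] <- current
  groups
}

#' Step-function gene set generation from PCA scores
#'
#' Scores often cluster in discontinuous ranges within a component. Per
#' component, the gene scores greater than 1 are sorted ascending and
#' swept: a gap between consecutive ranked scores below 1 extends the
#' current score-range set, a gap of 1 or more closes it and opens a new
#' one. Scores below -1 are treated symmetrically (sorted by descending
#' value, gaps taken in absolute value). Probe mapping and the size
#' filter behave exactly as in [threshold_sets()]. Every step set is by
#' construction a subset of the same component arm's threshold-1 set.
#'
#' @inheritParams threshold_sets
#' @return A `geneset_collection`; names follow `PC<k>.<pos|neg>.s<j>`
#'   with `j` numbering the ranges outward from the +-1 boundary.
#' @export
step_function_sets <- function(model, mapping = NULL, minsize = 5) {
  stopifnot(inherits(model, "laplacian_model"), !is.null(model$scores))
  is_gene <- model$node_order$kind == "gene"
  ids <- model$node_order$id[is_gene]
  sc <- model$scores[is_gene, , drop = FALSE]
  rows <- list()
  emit <- function(k, arm, idx_groups, arm_ids) {
    for (j in seq_along(idx_groups)) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        set = sprintf("PC%d.%s.s%d", k, arm, j), component = k, arm = arm,
        method = "step", parameter = as.character(j),
        members = list(arm_ids[idx_groups[[j]]]))
    }
  }
  for (k in seq_len(ncol(sc))) {
    s <- sc[, k]
    pos_i <- which(s > 1)
    ord <- pos_i[order(s[pos_i])]
    emit(k, "pos", split_score_runs(s[ord]), ids[ord])
    neg_i <- which(s < -1)
    ord <- neg_i[order(-s[neg_i])]
    emit(k, "neg", split_score_runs(-s[ord]), ids[ord])
  }
  finalize_sets(rows, mapping, minsize)
}

#' Substitute probe sets for genes
#'
#' @param genes Character vector of gene identifiers.
#' @param mapping A tibble with columns `gene` and `probeset` (one pair
#'   per row). Genes absent from the mapping contribute nothing.
#' @return Sorted unique probe set identifiers.
#' @export
map_genes_to_probes <- function(genes, mapping) {
  stopifnot(all(c("gene", "probeset") %in% names(mapping)))
  sort(unique(mapping$probeset[mapping$gene %in% genes]))
}

#' Read a gene-to-probeset mapping table
#'
#' @param path TSV file with header columns `gene` and `probeset`.
#' @return A tibble (`gene`, `probeset`).
#' @export
read_probe_mapping <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  stopifnot(all(c("gene", "probeset") %in% names(df)))
  df[, c("gene", "probeset")]
}

provenance_string <- function(row) {
  sprintf("component=%s;arm=%s;method=%s;parameter=%s",
          ifelse(is.na(row$component), "NA", row$component),
          ifelse(is.na(row$arm), "NA", row$arm),
          ifelse(is.na(row$method), "NA", row$method),
          ifelse(is.na(row$parameter), "NA", row$parameter))
}

#' Read and write GMT gene set files
#'
#' One set per line: name, description, then the member identifiers, all
#' tab-separated. `write_gmt()` stores the set's provenance (component,
#' arm, method, parameter) in the description field, which `read_gmt()`
#' parses back, so a collection round-trips through GMT unchanged.
#'
#' @param collection A `geneset_collection`.
#' @param path File path.
#' @return `read_gmt()` a `geneset_collection`; `write_gmt()` `path`,
#'   invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  members <- collection$members
  if (any(vapply(members, function(m) any(grepl("\t", m)), logical(1)))) {
    stop("set members must not contain tab characters", call. = FALSE)
  }
  lines <- character(nrow(collection))
  for (i in seq_len(nrow(collection))) {
    lines[i] <- paste(c(collection$set[i],
                        provenance_string(collection[i, ]),
                        members[[i]]), collapse = "\t")
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", ln, call. = FALSE)
    desc <- f[2]
    prov <- list(component = NA_integer_, arm = NA_character_,
                 method = NA_character_, parameter = NA_character_)
    if (grepl("^component=", desc)) {
      kv <- strsplit(strsplit(desc, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      for (p in kv) {
        if (p[1] %in% names(prov) && p[2] != "NA") prov[[p[1]]] <- p[2]
      }
    }
    tibble::tibble(set = f[1],
                   component = as.integer(prov$component),
                   arm = prov$arm, method = prov$method,
                   parameter = prov$parameter,
                   members = list(f[-(1:2)]))
  })
  if (length(rows) == 0) {
    return(gene_set_collection(tibble::tibble(set = character(),
                                              members = list())))
  }
  gene_set_collection(dplyr::bind_rows(rows))
}
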