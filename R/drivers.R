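#' Per-gene driver/passenger contingency counts
#'
#' The semi-exhaustive, overlapping nature of the set collection lets each
#' gene be tested many times; a gene concentrated in the significant sets
#' far beyond its overall frequency is likely driving the set statistics.
#' For each gene appearing in at least one tested set, counts are:
#' `a` = occurrences of the gene in significant sets, `b` = occurrences of
#' all other genes in significant sets, `c` = occurrences of the gene in
#' non-significant sets, `d` = occurrences of all other genes in
#' non-significant sets, with `n = a + b + c + d`. Counting is
#' multiplicity-aware: a gene in 7 significant sets contributes `a = 7`.
#'
#' @param sets The original post-threshold `geneset_collection` used for
#'   the analysis.
#' @param gsa A `gsa_result` (every tested set name must resolve in
#'   `sets`).
#' @return A tibble `gene`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingencies <- function(sets, gsa) {
  stopifnot(inherits(sets, "geneset_collection"))
  miss <- setdiff(gsa$set, sets$set)
  if (length(miss)) {
    stop("GSA result names not found in the collection: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(gsa$set, sets$set)
  long <- tibble::tibble(
    gene = unlist(sets$members[idx]),
    significant = rep(gsa$significant, lengths(sets$members[idx]))
  )
  tot_sig <- sum(long$significant)
  tot_non <- sum(!long$significant)
  counts <- long |>
    dplyr::count(.data$gene, .data$significant) |>
    tidyr::pivot_wider(names_from = "significant", values_from = "n",
                       values_fill = 0L)
  a <- if ("TRUE" %in% names(counts)) counts[["TRUE"]] else
    rep(0L, nrow(counts))
  cc <- if ("FALSE" %in% names(counts)) counts[["FALSE"]] else
    rep(0L, nrow(counts))
  out <- tibble::tibble(gene = counts$gene, a = as.integer(a),
                        b = as.integer(tot_sig - a), c = as.integer(cc),
                        d = as.integer(tot_non - cc))
  out$n <- out$a + out$b + out$c + out$d
  dplyr::arrange(out, .data$gene)
}

#' Two-tailed Fisher exact p-value for a 2x2 contingency table
#'
#' The probability of a table with the observed margins is hypergeometric:
#' `choose(a + b, a) * choose(c + d, c) / choose(n, a + c)`. The
#' two-tailed p-value sums the point probabilities of every table with
#' the same margins whose probability does not exceed the observed
#' table's (the convention of standard Fisher exact implementations).
#' Computation is in log space, so occurrence totals of 1e5 or more are
#' safe.
#'
#' @param a,b,c,d Non-negative integer counts (vectorized).
#' @return Two-tailed p-values in (0, 1].
#' @examples
#' fisher_two_tailed(5, 0, 0, 5)  # 2 / choose(10, 5)
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
    m1 <- a + b   # significant occurrences
    m2 <- c + d
    k <- a + c    # the gene's occurrences
    x <- max(0, k - m2):min(k, m1)
    logp <- stats::dhyper(x, m1, m2, k, log = TRUE)
    obs <- stats::dhyper(a, m1, m2, k, log = TRUE)
    # relative tolerance absorbs floating-point ties, as fisher.test does
    min(1, sum(exp(logp[logp <= obs + 1e-7])))
  }, a, b, c, d)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in the input order:
#'   `q(i) = max_{j <= i} min(1, (m - j + 1) p(j))` over the ascending
#'   ranks.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Hypergeometric driver enrichment over GSA results
#'
#' Runs [build_contingencies()], [fisher_two_tailed()] and
#' [holm_adjust()] and flags drivers at `q <= q_cut`. When the collection
#' has no overlap (every gene occurs in exactly one set) the frequencies
#' carry no information and the test is reported as non-applicable:
#' p and q are NA, no driver is called, and `attr(, "applicable")` is
#' FALSE — the situation of classical single-pathway collections.
#'
#' @inheritParams build_contingencies
#' @param q_cut Holm-adjusted significance cutoff (default 0.1).
#' @param mapping Optional probe mapping (`gene`, `probeset`). The test
#'   is gene-centric: when the sets hold probeset ids, each set's members
#'   are translated back to genes (a gene occurs in a set if any of its
#'   probe sets does) before tallying, so duplicate probe sets of one
#'   gene are not counted as separate hypotheses.
#' @return A `driver_report` tibble: `gene`, `a`, `b`, `c`, `d`, `n`,
#'   `p`, `q`, `driver`, ordered by `q` then gene.
#' @export
driver_enrichment <- function(sets, gsa, q_cut = 0.1, mapping = NULL) {
  if (!is.null(mapping)) {
    sets$members <- lapply(sets$members, probes_to_genes, mapping = mapping)
    keep <- lengths(sets$members) > 0
    sets <- sets[keep, , drop = FALSE]
    gsa <- gsa[gsa$set %in% sets$set, , drop = FALSE]
  }
  ct <- build_contingencies(sets, gsa)
  applicable <- nrow(ct) > 0 && any(ct$a + ct$c > 1)
  if (!applicable) {
    warning("set collection has no overlapping membership; ",
            "driver enrichment is not applicable", call. = FALSE)
    ct$p <- NA_real_
    ct$q <- NA_real_
    ct$driver <- FALSE
  } else {
    ct$p <- fisher_two_tailed(ct$a, ct$b, ct$c, ct$d)
    ct$q <- holm_adjust(ct$p)
    ct$driver <- ct$q <= q_cut
  }
  out <- dplyr::arrange(ct, .data$q, .data$gene)
  structure(out, class = c("driver_report", class(tibble::tibble())),
            applicable = applicable, q_cut = q_cut)
}

#' @export
print.driver_report <- function(x, ...) {
  if (!attr(x, "applicable")) {
    cat("<driver_report> not applicable (no membership overlap)\n")
  } else {
    cat("<driver_report> ", nrow(x), " genes tested, ", sum(x$driver),
        " drivers at q <= ", attr(x, "q_cut"), "\n", sep = "")
  }
  NextMethod()
}

#' @method tidy driver_report
#' @export
tidy.driver_report <- function(x, ...) tibble::as_tibble(x)

#' Summary counts for a driver report
#'
#' @param x A `driver_report`.
#' @param ... Unused.
#' @return One-row tibble with genes tested, drivers called, the
#'   reduction factor (tested / drivers) and applicability.
#' @method glance driver_report
#' @export
glance.driver_report <- function(x, ...) {
  nd <- sum(x$driver, na.rm = TRUE)
  tibble::tibble(
    n_genes_tested = nrow(x),
    n_drivers = nd,
    reduction_factor = if (nd > 0) nrow(x) / nd else NA_real_,
    applicable = attr(x, "applicable"),
    q_cut = attr(x, "q_cut")
  )
}

#' Extract the driver gene calls
#'
#' @param report A `driver_report`.
#' @param q_cut Cutoff on the Holm-adjusted q (default the report's own).
#' @return Character vector of driver genes, ordered by q then gene id.
#' @export
call_drivers <- function(report, q_cut = attr(report, "q_cut")) {
  stopifnot(inherits(report, "driver_report"))
  if (!attr(report, "applicable")) return(character())
  report$gene[!is.na(report$q) & report$q <= q_cut]
}

#' Driver enrichment overview plot
#'
#' @param object A `driver_report`.
#' @param ... Unused.
#' @return A ggplot of each gene's significant-set occurrences against
#'   its non-significant-set occurrences, drivers highlighted.
#' @method autoplot driver_report
#' @export
autoplot.driver_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$c, .data$a,
                                   colour = .data$driver)) +
    ggplot2::geom_jitter(width = 0.15, height = 0.15, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "occurrences in non-significant sets",
                  y = "occurrences in significant sets",
                  colour = "driver") +
    ggplot2::theme_minimal()
}

#' Write a driver report as TSV
#'
#' @param report A `driver_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_driver_report <- function(report, path) {
  readr::write_tsv(tibble::as_tibble(report), path)
  invisible(path)
}
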