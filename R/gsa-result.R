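new_gsa_result <- function(df, skipped, nperms, minsize, fdr_cut) {
  structure(df,
            class = c("gsa_result", class(tibble::tibble())),
            skipped = skipped, nperms = nperms, minsize = minsize,
            fdr_cut = fdr_cut)
}

#' @export
print.gsa_result <- function(x, ...) {
  cat("<gsa_result> ", nrow(x), " sets tested (",
      sum(x$significant), " significant at FDR < ",
      attr(x, "fdr_cut"), "; ", attr(x, "nperms"), " permutations)\n",
      sep = "")
  NextMethod()
}

#' @method tidy gsa_result
#' @export
tidy.gsa_result <- function(x, ...) tibble::as_tibble(x)

#' Summary counts for a GSA run
#'
#' @param x A `gsa_result`.
#' @param ... Unused.
#' @return One-row tibble: sets tested/skipped/significant, permutations
#'   used, and the FDR cutoff.
#' @method glance gsa_result
#' @export
glance.gsa_result <- function(x, ...) {
  tibble::tibble(
    n_sets_tested = nrow(x),
    n_sets_skipped = nrow(attr(x, "skipped")),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$direction == "up"),
    n_down = sum(x$significant & x$direction == "down"),
    nperms = attr(x, "nperms"),
    fdr_cut = attr(x, "fdr_cut")
  )
}

#' Volcano-style overview of GSA results
#'
#' @param object A `gsa_result`.
#' @param ... Unused.
#' @return A ggplot of restandardized max-mean statistic versus FDR, with
#'   significant sets highlighted.
#' @method autoplot gsa_result
#' @export
autoplot.gsa_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$statistic, .data$fdr,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "restandardized max-mean statistic",
                  y = "estimated FDR", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Write GSA results as TSV
#'
#' @param result A `gsa_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gsa_results <- function(result, path) {
  readr::write_tsv(tibble::as_tibble(result), path)
  invisible(path)
}
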