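#' Two-class expression data container
#'
#' Bundles a log2 expression matrix (features x samples) with a two-class
#' design. Values must be complete (no missing entries) and each class
#' needs at least two samples.
#'
#' @param values A data frame whose first column (named `feature`) holds
#'   feature identifiers (probe sets or genes) and whose remaining
#'   columns are samples; or a numeric matrix with rownames = features
#'   and colnames = samples.
#' @param classes A data frame with columns `sample` and `class`
#'   (`"control"` or `"treatment"`), or a named character vector.
#' @return An `expression_data` object (list with `values` matrix and
#'   `classes` factor aligned to its columns).
#' @export
expression_data <- function(values, classes) {
  if (is.data.frame(values)) {
    stopifnot(names(values)[1] == "feature")
    m <- as.matrix(values[, -1, drop = FALSE])
    rownames(m) <- as.character(values$feature)
  } else {
    m <- as.matrix(values)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression values must be complete", call. = FALSE)
  if (anyDuplicated(rownames(m))) {
    stop("feature ids must be unique", call. = FALSE)
  }
  if (is.data.frame(classes)) {
    cl <- stats::setNames(as.character(classes$class),
                          as.character(classes$sample))
  } else {
    cl <- classes
  }
  cl <- cl[colnames(m)]
  if (anyNA(cl)) stop("every sample needs a class label", call. = FALSE)
  if (!all(cl %in% c("control", "treatment"))) {
    stop("classes must be 'control' or 'treatment'", call. = FALSE)
  }
  if (any(table(factor(cl, c("control", "treatment"))) < 2)) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  structure(list(values = m,
                 classes = factor(cl, c("control", "treatment"))),
            class = "expression_data")
}

#' @export
print.expression_data <- function(x, ...) {
  cat("<expression_data> ", nrow(x$values), " features x ",
      ncol(x$values), " samples (",
      sum(x$classes == "control"), " control / ",
      sum(x$classes == "treatment"), " treatment)\n", sep = "")
  invisible(x)
}

#' Read expression values and class labels from TSV
#'
#' @param values_path TSV: header row of sample ids, first column
#'   `feature`.
#' @param classes_path TSV with columns `sample` and `class`.
#' @return An [expression_data()] object.
#' @export
read_expression <- function(values_path, classes_path) {
  vals <- readr::read_tsv(values_path, col_types = readr::cols(
    feature = "c", .default = "d"), progress = FALSE)
  cls <- readr::read_tsv(classes_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  expression_data(vals, cls)
}

# per-feature moderated two-sample z/t scores for B label assignments at
# once. treat_ind: n x B 0/1 matrix (columns = treatment assignments).
# An additive exchangeability constant s0 (a quantile of each column's
# SE distribution) stabilises the denominator at small sample sizes.
gene_score_matrix <- function(values, treat_ind, s0_q = 0.5) {
  n <- ncol(values)
  nt <- colSums(treat_ind)
  nc <- n - nt
  sum_all <- rowSums(values)
  sq_all <- rowSums(values^2)
  st <- values %*% treat_ind                  # p x B treatment sums
  sqt <- (values^2) %*% treat_ind
  mt <- sweep(st, 2, nt, "/")
  mc <- sweep(-st + sum_all, 2, nc, "/")
  sst <- sqt - sweep(mt^2, 2, nt, "*")        # within-treatment SS
  ssc <- (sq_all - sqt) - sweep(mc^2, 2, nc, "*")
  pooled_var <- sweep(sst + ssc, 2, nt + nc - 2, "/")
  pooled_var[pooled_var < 0] <- 0             # numerical guard
  se <- sqrt(pooled_var) * rep(sqrt(1 / nt + 1 / nc), each = nrow(values))
  se <- matrix(se, nrow(values))
  # SAM-style additive exchangeability factor: with few replicates the
  # per-feature SE is unstable, so a catalog quantile is added to every
  # denominator rather than flooring only the smallest
  s0 <- apply(se, 2, stats::quantile, probs = s0_q)
  se <- se + rep(s0, each = nrow(values))
  se[se == 0] <- 1  # all features constant in a column: scores are 0 anyway
  (mt - mc) / se
}

#' Per-feature differential-expression scores
#'
#' Computes an unpaired two-sample t-like z statistic per feature
#' (treatment minus control, pooled variance). An exchangeability
#' constant s0 — a quantile of all features' standard errors — is added
#' to every denominator, as in the significance-analysis-of-microarrays
#' family of scores, so that features with accidentally tiny variance
#' estimates cannot dominate at small sample sizes.
#'
#' @param expr An [expression_data()] object.
#' @param s0_quantile Quantile of the per-feature standard errors used
#'   as the additive s0 constant (default 0.5, the median).
#' @return A tibble `feature`, `score`.
#' @export
gene_scores <- function(expr, s0_quantile = 0.5) {
  stopifnot(inherits(expr, "expression_data"))
  ind <- matrix(as.numeric(expr$classes == "treatment"), ncol = 1)
  sc <- gene_score_matrix(expr$values, ind, s0_quantile)
  tibble::tibble(feature = rownames(expr$values), score = sc[, 1])
}

#' Raw max-mean set statistic
#'
#' For the gene scores of a set, `s_plus` is the mean of the positive
#' parts and `s_minus` the mean of the absolute negative parts (zeros and
#' opposite-signed members count in both denominators). The statistic is
#' `s_plus` if `s_plus >= s_minus`, otherwise `-s_minus`; it targets sets
#' in which only a fraction of members move, in either direction. This is
#' the raw (un-restandardized) form; [run_gsa()] restandardizes it
#' against random sets of equal size.
#'
#' @param scores Named numeric vector of per-feature scores.
#' @param members Character vector of the set's member features; members
#'   absent from `scores` are ignored.
#' @return A single signed statistic (NA if no member is scored).
#' @examples
#' maxmean_statistic(c(a = 3, b = 0, c = -1), c("a", "b", "c"))  # 1.0
#' @export
maxmean_statistic <- function(scores, members) {
  s <- scores[intersect(members, names(scores))]
  if (length(s) == 0) return(NA_real_)
  s_plus <- sum(pmax(s, 0)) / length(s)
  s_minus <- sum(pmax(-s, 0)) / length(s)
  if (s_plus >= s_minus) s_plus else -s_minus
}

# max-mean for every set (columns of 0/1 membership matrix `M`, p x S)
# against every score column (p x B). Returns S x B.
maxmean_matrix <- function(M, sizes, score_mat) {
  P <- pmax(score_mat, 0)
  N <- pmax(-score_mat, 0)
  splus <- crossprod(M, P) / sizes
  sminus <- crossprod(M, N) / sizes
  ifelse(splus >= sminus, splus, -sminus)
}

# label assignments for the permutation null: all distinct treatment
# subsets when few enough, otherwise Monte-Carlo resampling. The observed
# labeling itself is not part of the null (with tiny designs it would
# floor every p-value and FDR).
permutation_indicators <- function(classes, nperms) {
  n <- length(classes)
  nt <- sum(classes == "treatment")
  obs <- sort(which(classes == "treatment"))
  n_distinct <- choose(n, nt)
  if (n_distinct - 1 <= nperms) {
    sets <- utils::combn(n, nt)
    sets <- sets[, colSums(sets == obs) < nt, drop = FALSE]
  } else {
    sets <- replicate(nperms, {
      repeat {
        s <- sort(sample.int(n, nt))
        if (!identical(s, obs)) return(s)
      }
    })
  }
  ind <- matrix(0, n, ncol(sets))
  ind[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = nt))] <- 1
  ind
}

#' Max-mean gene set analysis with a permutation null
#'
#' Two-class unpaired gene set analysis. Per-feature scores
#' ([gene_scores()]) are summarised per set by the max-mean statistic
#' ([maxmean_statistic()]) and restandardized: the raw statistic is
#' centred and scaled by the mean and standard deviation of the raw
#' statistic over `ndraws` random feature sets of the same size, so that
#' set size and the overall score distribution do not confound the set
#' call. The null distribution comes from permuting class labels
#' (`nperms` Monte-Carlo draws, or complete enumeration when fewer
#' distinct labelings exist); permuted statistics are restandardized with
#' their own permutation's constants. Permutation p-values are one-tailed
#' on the side of the observed statistic, with the `(r + 1) / (B + 1)`
#' convention. False discovery rates use the plug-in permutation
#' estimator, computed separately on the positive and negative tails and
#' monotonized from the extreme tail inward.
#'
#' @param expr An [expression_data()] object.
#' @param sets A `geneset_collection`.
#' @param nperms Number of label permutations (default 1000).
#' @param minsize Minimum set members present in the expression data for
#'   a set to be tested (default 2).
#' @param fdr_cut FDR threshold for the significance call (default 0.05).
#' @param seed Integer seed making the run reproducible.
#' @param ndraws Random same-size draws for restandardization (500).
#' @param s0_quantile Passed to the gene-score computation.
#' @return A `gsa_result` tibble: `set`, `n_used`, `statistic`
#'   (restandardized), `p_value`, `fdr`, `direction`, `significant`,
#'   sorted by FDR then descending absolute statistic. Sets skipped for
#'   insufficient overlap are recorded in `attr(, "skipped")`.
#' @export
run_gsa <- function(expr, sets, nperms = 1000, minsize = 2, fdr_cut = 0.05,
                    seed = NULL, ndraws = 500, s0_quantile = 0.5) {
  stopifnot(inherits(expr, "expression_data"),
            inherits(sets, "geneset_collection"))
  runner <- function() {
    run_gsa_impl(expr, sets, nperms, minsize, fdr_cut, ndraws,
                 s0_quantile)
  }
  if (!is.null(seed)) withr::with_seed(seed, runner()) else runner()
}

run_gsa_impl <- function(expr, sets, nperms, minsize, fdr_cut, ndraws,
                         s0_quantile) {
  feats <- rownames(expr$values)
  p <- length(feats)
  used <- lapply(sets$members, intersect, y = feats)
  n_used <- lengths(used)
  keep <- n_used >= minsize
  skipped <- tibble::tibble(set = sets$set[!keep], n_used = n_used[!keep],
                            reason = "fewer members than minsize in data")
  if (!any(keep)) {
    warning("no set passes the minimum-size filter", call. = FALSE)
    out <- tibble::tibble(set = character(), n_used = integer(),
                          statistic = double(), p_value = double(),
                          fdr = double(), direction = character(),
                          significant = logical())
    return(new_gsa_result(out, skipped, nperms, minsize, fdr_cut))
  }
  set_names <- sets$set[keep]
  used <- used[keep]
  n_used <- n_used[keep]

  M <- matrix(0, p, length(used))
  for (i in seq_along(used)) M[match(used[[i]], feats), i] <- 1

  ind_obs <- matrix(as.numeric(expr$classes == "treatment"), ncol = 1)
  ind_perm <- permutation_indicators(expr$classes, nperms)
  B <- ncol(ind_perm)
  scores_all <- gene_score_matrix(expr$values, cbind(ind_obs, ind_perm),
                                  s0_quantile)
  # standardize each catalog of gene scores (observed and per permutation)
  # before forming set statistics: without this, a broad one-sided signal
  # makes every untouched set look spuriously "down" relative to random
  # draws
  scores_all <- scale(scores_all)

  raw <- maxmean_matrix(M, n_used, scores_all)   # S x (B+1)

  # restandardization catalog: per distinct set size, random same-size
  # feature draws shared across the observed and permuted score columns
  sizes <- sort(unique(n_used))
  std <- raw
  for (s in sizes) {
    R <- matrix(0, p, ndraws)
    for (d in seq_len(ndraws)) R[sample.int(p, s), d] <- 1
    rawd <- maxmean_matrix(R, s, scores_all)     # ndraws x (B+1)
    mu <- colMeans(rawd)
    sdv <- apply(rawd, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- Inf
    rows <- which(n_used == s)
    std[rows, ] <- (raw[rows, , drop = FALSE] -
                      rep(mu, each = length(rows))) /
      rep(sdv, each = length(rows))
  }

  obs <- std[, 1]
  perm <- std[, -1, drop = FALSE]

  # two-sided permutation p: tail picked by the observed sign, doubled so
  # the null distribution is uniform on (0, 1]
  pos <- obs >= 0
  p_value <- numeric(length(obs))
  p_value[pos] <- (rowSums(perm[pos, , drop = FALSE] >=
                             obs[pos]) + 1) / (B + 1)
  p_value[!pos] <- (rowSums(perm[!pos, , drop = FALSE] <=
                              obs[!pos]) + 1) / (B + 1)
  p_value <- pmin(1, 2 * p_value)

  fdr <- plugin_fdr(obs, perm)
  direction <- ifelse(pos, "up", "down")
  out <- tibble::tibble(set = set_names, n_used = as.integer(n_used),
                        statistic = obs, p_value = p_value, fdr = fdr,
                        direction = direction,
                        significant = fdr < fdr_cut)
  out <- dplyr::arrange(out, .data$fdr, dplyr::desc(abs(.data$statistic)))
  new_gsa_result(out, skipped, B, minsize, fdr_cut)
}

# plug-in permutation FDR, each tail against its own side of the
# permutation distribution. The expected number of false calls at a cut
# is the MEDIAN across permutations of the per-permutation count (the
# SAM convention); the median is robust to the few relabelings that
# partially align with the true class split in small designs. The
# numerator is scaled by pi0, the estimated fraction of truly null sets
# (observed statistics falling inside the central half of the
# permutation distribution, relative to the 50% expected for nulls).
plugin_fdr <- function(obs, perm) {
  qs <- stats::quantile(perm, c(0.25, 0.75))
  pi0 <- min(1, sum(obs >= qs[1] & obs <= qs[2]) / (0.5 * length(obs)))
  fdr <- rep(1, length(obs))
  for (side in c(1, -1)) {
    idx <- which(sign(obs) == side | (side == 1 & obs == 0))
    if (!length(idx)) next
    cuts <- obs[idx]
    n_obs <- vapply(cuts, function(ct) {
      if (side == 1) sum(obs >= ct) else sum(obs <= ct)
    }, numeric(1))
    n_perm <- vapply(cuts, function(ct) {
      counts <- if (side == 1) colSums(perm >= ct) else colSums(perm <= ct)
      stats::median(counts)
    }, numeric(1))
    est <- pmin(1, pi0 * n_perm / pmax(n_obs, 1))
    # monotone: a more extreme cut never reports a larger FDR than a less
    # extreme one (running min scanning inward from the least extreme cut)
    ord <- order(abs(cuts), decreasing = TRUE)
    est[ord] <- rev(cummin(rev(est[ord])))
    fdr[idx] <- est
  }
  fdr
}
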