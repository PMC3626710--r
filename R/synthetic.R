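#' Specification for synthetic ground-truthed fixtures
#'
#' Describes a modular tripartite metabolic network and a two-class
#' expression experiment with a planted differentially expressed
#' subnetwork. The defaults mirror a small but realistic study: eight
#' pathway-like modules of a dozen genes each, two modules perturbed by a
#' two-standard-deviation shift, and three samples per class — the scale
#' of a typical small treated-versus-control microarray comparison.
#'
#' @param n_modules Number of modules ("pathways").
#' @param genes_per_module,reactions_per_module,compounds_per_module
#'   Node counts per module. The defaults (12 genes, 20 reactions, 10
#'   compounds) give the reaction-rich modules typical of curated
#'   metabolic maps, where reactions outnumber the genes catalysing
#'   them.
#' @param inter_module_compound_links Number of compound bridges placed
#'   between consecutive modules (module i's compound feeding a reaction
#'   of module i + 1, and joining that pathway's membership). With fewer
#'   links than modules the graph stays partly disconnected, as curated
#'   metabolic networks are.
#' @param planted_modules Indices of modules whose genes are shifted in
#'   the treatment class.
#' @param effect_size Shift in units of the within-class standard
#'   deviation.
#' @param noise_sd Within-class standard deviation of log2 expression.
#' @param n_control,n_treatment Samples per class.
#' @param seed Integer seed; all generators are deterministic given the
#'   spec.
#' @param mixed_sign If TRUE, half of each planted module's genes shift
#'   down instead of up (exercises the max-mean statistic's sensitivity
#'   to partially responding sets).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_modules = 8, genes_per_module = 12,
                           reactions_per_module = 20,
                           compounds_per_module = 10,
                           inter_module_compound_links = 2,
                           planted_modules = c(1, 2),
                           effect_size = 2, noise_sd = 0.5,
                           n_control = 3, n_treatment = 3,
                           seed = 1, mixed_sign = FALSE) {
  spec <- list(n_modules = n_modules, genes_per_module = genes_per_module,
               reactions_per_module = reactions_per_module,
               compounds_per_module = compounds_per_module,
               inter_module_compound_links = inter_module_compound_links,
               planted_modules = planted_modules,
               effect_size = effect_size, noise_sd = noise_sd,
               n_control = n_control, n_treatment = n_treatment,
               seed = seed, mixed_sign = mixed_sign)
  counts <- unlist(spec[c("n_modules", "genes_per_module",
                          "reactions_per_module", "compounds_per_module",
                          "n_control", "n_treatment")])
  if (any(counts < 1)) stop("all counts must be positive", call. = FALSE)
  if (!all(planted_modules %in% seq_len(n_modules))) {
    stop("planted_modules must be existing module indices", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

#' Generate a modular tripartite metabolic network
#'
#' Each module is a densely connected gene-reaction-compound cluster
#' emulating a metabolic pathway: the genes form two staggered isoenzyme
#' families, each gene catalysing a contiguous window of roughly 70% of
#' the module's reactions (offset by half the module for the second
#' family) plus one random extra reaction; reactions are chained through
#' shared compounds (substrate of one, product of the next) with two
#' further random substrates/products each. The heavily overlapping
#' gene neighbourhoods are what give the Laplacian PCA components
#' structure at several scales inside a module, as the hub-rich
#' neighbourhoods of real metabolic networks do. Every module is
#' recorded as one pathway (its genes and compounds). Modules are
#' bridged by compound links (a compound of module i also feeding a
#' reaction of module i + 1 and appearing in both pathways), so
#' community structure is known by construction; with fewer links than
#' modules the graph stays partly disconnected, as curated metabolic
#' networks are. Deterministic given the spec's seed; the ground-truth
#' module of every node is attached as `attr(, "module_assignment")`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [metabolic_network()] with attributes `module_assignment`
#'   (tibble `id`, `kind`, `module`) and `spec`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  edges <- list()
  assign_rows <- list()
  pw_rows <- list()
  M <- spec$n_modules
  withr::with_seed(spec$seed, {
  for (m in seq_len(M)) {
    # pathway sizes vary deterministically around the nominal counts:
    # statistically identical modules would give the Laplacian a
    # near-degenerate spectrum whose principal components mix the
    # modules, which real (size-heterogeneous) pathway collections do
    # not exhibit
    R <- max(4, round(spec$reactions_per_module + (m - (M + 1) / 2) * 2))
    C <- max(3, spec$compounds_per_module + ((m %% 3) - 1) * 2)
    genes <- sprintf("g%d_%02d", m, seq_len(spec$genes_per_module))
    rxns <- sprintf("r%d_%02d", m, seq_len(R))
    cpds <- sprintf("c%d_%02d", m, seq_len(C))
    # two staggered isoenzyme families per module: each gene catalyses a
    # contiguous window of ~70% of the module's reactions, family B
    # offset by half a turn, plus one random extra reaction per gene.
    # The windows give genes the heavily overlapping neighbourhoods that
    # make the Laplacian components resolve structure at several scales
    # inside a module.
    span <- max(1, min(R, round(0.7 * R)))
    for (i in seq_along(genes)) {
      fam <- (i - 1) %% 2
      start <- fam * (R %/% 2)
      window <- ((start + 0:(span - 1)) %% R) + 1
      extra <- sample.int(R, 1)
      edges[[length(edges) + 1]] <- tibble::tibble(
        node = genes[i], node_kind = "gene",
        reaction = rxns[unique(c(window, extra))])
    }
    # reactions chained through shared compounds keep the module
    # connected; two further random compounds per reaction
    ri <- seq_along(rxns)
    edges[[length(edges) + 1]] <- tibble::tibble(
      node = c(cpds[(ri - 1) %% C + 1], cpds[ri %% C + 1]),
      node_kind = "compound", reaction = rep(rxns, 2))
    for (j in ri) {
      edges[[length(edges) + 1]] <- tibble::tibble(
        node = cpds[sample.int(C, min(2, C))], node_kind = "compound",
        reaction = rxns[j])
    }
    assign_rows[[length(assign_rows) + 1]] <- tibble::tibble(
      id = c(genes, rxns, cpds),
      kind = rep(c("gene", "reaction", "compound"),
                 c(length(genes), length(rxns), length(cpds))),
      module = m)
    pw_rows[[length(pw_rows) + 1]] <- tibble::tibble(
      pathway = sprintf("pathway_%d", m),
      member = c(genes, cpds),
      kind = rep(c("gene", "compound"), c(length(genes), length(cpds))))
  }
  })
  # compound bridges between consecutive modules; the bridging compound
  # belongs to both pathways (as it would in both KGML files)
  L <- spec$inter_module_compound_links
  if (L > 0 && spec$n_modules > 1) {
    for (l in seq_len(L)) {
      a <- (l - 1) %% spec$n_modules + 1
      b <- a %% spec$n_modules + 1
      ci <- (l - 1) %/% spec$n_modules + 1
      bridge <- sprintf("c%d_%02d", a,
                        (ci - 1) %% spec$compounds_per_module + 1)
      edges[[length(edges) + 1]] <- tibble::tibble(
        node = bridge, node_kind = "compound",
        reaction = sprintf("r%d_%02d", b, (l - 1) %% 4 + 1))
      pw_rows[[length(pw_rows) + 1]] <- tibble::tibble(
        pathway = sprintf("pathway_%d", b), member = bridge,
        kind = "compound")
    }
  }
  net <- metabolic_network(edges = dplyr::bind_rows(edges),
                           pathways = dplyr::bind_rows(pw_rows))
  attr(net, "module_assignment") <- dplyr::bind_rows(assign_rows)
  attr(net, "spec") <- spec
  net
}

#' Generate a two-class expression matrix with a planted signal
#'
#' Log2 expression values with a module-wise planted effect: per-gene
#' baselines are drawn from Normal(8, 1), each sample adds
#' Normal(0, `noise_sd`) biological noise, and the genes of the planted
#' modules are shifted by `effect_size * noise_sd` in the treatment
#' class (all up, or half down when `mixed_sign`) — the effect is
#' planted per module because network-neighbouring genes are the ones
#' expected to be co-regulated. With a probe `mapping`, features are
#' probe sets instead of genes: each probe set reports its gene's
#' per-sample value plus a fixed probe affinity offset (Normal(0, 0.25),
#' cancelling between classes) and Normal(0, `noise_sd` / 2) measurement
#' noise. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param network The network from [generate_network()] (supplies the
#'   gene ids and module assignment).
#' @param mapping Optional probe mapping (`gene`, `probeset`) from
#'   [generate_probe_mapping()]; when given, the matrix is probe-level.
#' @return An [expression_data()] object with attributes
#'   `differential_genes` (gene ids), `differential_features` (matrix
#'   row ids carrying the effect) and `spec`.
#' @export
generate_expression <- function(spec, network, mapping = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(network, "metabolic_network"))
  assign <- attr(network, "module_assignment")
  if (is.null(assign)) stop("network lacks module ground truth",
                            call. = FALSE)
  genes <- assign$id[assign$kind == "gene"]
  modules <- assign$module[assign$kind == "gene"]
  n <- spec$n_control + spec$n_treatment
  samples <- c(sprintf("ctrl_%d", seq_len(spec$n_control)),
               sprintf("trt_%d", seq_len(spec$n_treatment)))
  classes <- stats::setNames(rep(c("control", "treatment"),
                                 c(spec$n_control, spec$n_treatment)),
                             samples)
  planted <- genes[modules %in% spec$planted_modules]
  vals <- withr::with_seed(spec$seed + 1L, {
    baseline <- stats::rnorm(length(genes), 8, 1)
    gene_vals <- baseline + matrix(stats::rnorm(length(genes) * n,
                                                0, spec$noise_sd),
                                   length(genes), n)
    sign_of <- stats::setNames(rep(1, length(planted)), planted)
    if (spec$mixed_sign && length(planted)) {
      sign_of[seq_along(planted) %% 2 == 0] <- -1
    }
    trt <- which(classes == "treatment")
    shift <- spec$effect_size * spec$noise_sd
    for (g in planted) {
      gene_vals[match(g, genes), trt] <-
        gene_vals[match(g, genes), trt] + sign_of[[g]] * shift
    }
    rownames(gene_vals) <- genes
    if (is.null(mapping)) {
      gene_vals
    } else {
      probes <- mapping$probeset
      affinity <- stats::rnorm(length(probes), 0, 0.25)
      probe_vals <- gene_vals[mapping$gene, , drop = FALSE] + affinity +
        matrix(stats::rnorm(length(probes) * n, 0, spec$noise_sd / 5),
               length(probes), n)
      rownames(probe_vals) <- probes
      probe_vals
    }
  })
  colnames(vals) <- samples
  expr <- expression_data(vals, classes)
  attr(expr, "differential_genes") <- planted
  attr(expr, "differential_features") <- if (is.null(mapping)) planted else
    mapping$probeset[mapping$gene %in% planted]
  attr(expr, "spec") <- spec
  expr
}

#' Generate a deterministic gene-to-probeset mapping
#'
#' Emulates an array annotation in which every gene is interrogated by a
#' fixed number of probe sets with derived identifiers.
#'
#' @param network A [metabolic_network()].
#' @param probes_per_gene Probe sets per gene (default 1, as most genes
#'   on a yeast-style expression array are covered by a single probe
#'   set).
#' @return A tibble `gene`, `probeset` usable wherever a probe mapping is
#'   accepted.
#' @export
generate_probe_mapping <- function(network, probes_per_gene = 1) {
  stopifnot(inherits(network, "metabolic_network"), probes_per_gene >= 1)
  genes <- network$nodes$id[network$nodes$kind == "gene"]
  tibble::tibble(
    gene = rep(genes, each = probes_per_gene),
    probeset = paste0(rep(genes, each = probes_per_gene), "_at",
                      rep(seq_len(probes_per_gene), length(genes)))
  )
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the same plain-text formats the analysis functions read: the
#' network edge list (with pathway membership rows), the expression TSV,
#' the class-label TSV and the probe-mapping TSV.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_network(spec)
  mapping <- generate_probe_mapping(net)
  expr <- generate_expression(spec, net, mapping)
  paths <- list(
    network = file.path(dir, "network.tsv"),
    expression = file.path(dir, "expression.tsv"),
    classes = file.path(dir, "classes.tsv"),
    mapping = file.path(dir, "probe_mapping.tsv")
  )
  write_edgelist(net, paths$network)
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(feature = rownames(expr$values)),
                     tibble::as_tibble(expr$values)),
    paths$expression)
  readr::write_tsv(
    tibble::tibble(sample = colnames(expr$values),
                   class = as.character(expr$classes)),
    paths$classes)
  readr::write_tsv(mapping, paths$mapping)
  invisible(paths)
}
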