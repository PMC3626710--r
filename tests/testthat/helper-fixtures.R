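# fixtures shared across test files; everything is built in code

# two genes catalysing one reaction that links two compounds, plus a
# second pathway reusing one compound
tiny_network <- function() {
  metabolic_network(
    edges = tibble::tibble(
      node = c("g1", "g2", "c1", "c2", "g3", "c2", "c3"),
      node_kind = c("gene", "gene", "compound", "compound",
                    "gene", "compound", "compound"),
      reaction = c("r1", "r1", "r1", "r1", "r2", "r2", "r2")
    ),
    pathways = tibble::tibble(
      pathway = c("pwA", "pwA", "pwA", "pwA", "pwB", "pwB", "pwB"),
      member = c("g1", "g2", "c1", "c2", "g3", "c2", "c3"),
      kind = c("gene", "gene", "compound", "compound",
               "gene", "compound", "compound")
    )
  )
}

# random valid tripartite network: every edge joins a gene or compound
# to a reaction
random_network <- function(seed, n_genes = 8, n_rxns = 6, n_cpds = 6,
                           n_edges = 25) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_len(n_genes))
    rxns <- paste0("r", seq_len(n_rxns))
    cpds <- paste0("c", seq_len(n_cpds))
    others <- c(genes, cpds)
    kind <- c(rep("gene", n_genes), rep("compound", n_cpds))
    pick <- sample(length(others), n_edges, replace = TRUE)
    metabolic_network(edges = tibble::tibble(
      node = others[pick], node_kind = kind[pick],
      reaction = sample(rxns, n_edges, replace = TRUE)))
  })
}

# laplacian_model stub with chosen scores (for set-generation tests that
# need exact score patterns)
fake_model <- function(scores, kinds = NULL) {
  ids <- rownames(scores)
  if (is.null(kinds)) kinds <- rep("gene", length(ids))
  structure(
    list(node_order = tibble::tibble(id = ids, kind = kinds),
         scores = scores, variance_fraction = rep(1 / ncol(scores),
                                                  ncol(scores))),
    class = "laplacian_model")
}

random_collection <- function(seed, n_sets = 20, universe = paste0("m", 1:40),
                              min_size = 1, max_size = 12) {
  withr::with_seed(seed, {
    gene_set_collection(tibble::tibble(
      set = sprintf("s%03d", seq_len(n_sets)),
      members = lapply(seq_len(n_sets), function(i) {
        sample(universe, sample(min_size:max_size, 1))
      })
    ))
  })
}

# minimal KGML document text
kgml_doc <- function(title, entries, reactions) {
  paste0(
    '<?xml version="1.0"?>\n<pathway name="path:test" title="', title,
    '">\n', paste(entries, collapse = "\n"), "\n",
    paste(reactions, collapse = "\n"), "\n</pathway>\n")
}

kgml_gene_entry <- function(names, reaction = NULL) {
  paste0('<entry id="1" type="gene" name="', paste(names, collapse = " "),
         '"', if (!is.null(reaction)) {
           paste0(' reaction="', paste(reaction, collapse = " "), '"')
         }, '/>')
}

kgml_reaction <- function(name, substrates = character(),
                          products = character()) {
  paste0('<reaction id="9" name="', name, '" type="irreversible">\n',
         paste0('  <substrate id="s" name="', substrates, '"/>',
                collapse = "\n"),
         if (length(substrates) && length(products)) "\n",
         paste0('  <product id="p" name="', products, '"/>',
                collapse = "\n"),
         '\n</reaction>')
}

# two-class expression matrix with a known up-shifted feature block
toy_expression <- function(seed = 1, n_feats = 40, shifted = character(),
                           shift = 2, n_per_class = 3, sd = 0.5) {
  withr::with_seed(seed, {
    feats <- if (n_feats > 0) paste0("f", seq_len(n_feats)) else character()
    feats <- union(feats, shifted)
    vals <- matrix(stats::rnorm(length(feats) * 2 * n_per_class, 8, sd),
                   length(feats), 2 * n_per_class,
                   dimnames = list(feats, c(paste0("c", seq_len(n_per_class)),
                                            paste0("t", seq_len(n_per_class)))))
    vals[shifted, n_per_class + seq_len(n_per_class)] <-
      vals[shifted, n_per_class + seq_len(n_per_class)] + shift
    expression_data(vals, stats::setNames(
      rep(c("control", "treatment"), each = n_per_class), colnames(vals)))
  })
}
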