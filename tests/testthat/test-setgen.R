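# brute-force oracles used in several blocks: scan every (component,
# arm, threshold) triple / score-run independently of the implementation
oracle_threshold <- function(scores, kinds, thresholds, minsize) {
  out <- list()
  gene_ids <- rownames(scores)[kinds == "gene"]
  for (k in seq_len(ncol(scores))) {
    for (t in thresholds) {
      for (arm in c("pos", "neg")) {
        members <- character()
        for (g in gene_ids) {
          s <- scores[g, k]
          if (arm == "pos" && s > t) members <- c(members, g)
          if (arm == "neg" && s < -t) members <- c(members, g)
        }
        if (length(members) >= minsize) {
          out[[sprintf("PC%d.%s.t%d", k, arm, t)]] <- sort(members)
        }
      }
    }
  }
  out
}

oracle_step <- function(scores, kinds, minsize) {
  out <- list()
  gene_ids <- rownames(scores)[kinds == "gene"]
  for (k in seq_len(ncol(scores))) {
    for (arm in c("pos", "neg")) {
      s <- scores[gene_ids, k]
      sel <- if (arm == "pos") s > 1 else s < -1
      ids <- gene_ids[sel]
      mag <- abs(s[sel])
      ord <- order(mag)
      ids <- ids[ord]; mag <- mag[ord]
      j <- 0; current <- character(); last <- NULL
      flush <- function() {
        if (length(current) >= minsize) {
          j <<- j + 1
          out[[sprintf("PC%d.%s.s%d", k, arm, j)]] <<- sort(current)
        } else if (length(current) > 0) {
          j <<- j + 1  # ranges below minsize still consume an index
        }
      }
      for (i in seq_along(ids)) {
        if (!is.null(last) && mag[i] - last >= 1) {
          flush(); current <- character()
        }
        current <- c(current, ids[i]); last <- mag[i]
      }
      if (length(current)) flush()
    }
  }
  out
}

collection_as_list <- function(col) {
  stats::setNames(col$members, col$set)
}

test_that("threshold arms apply the strict score rule to genes only", {
  scores <- matrix(c(2.5, -3.1, 0.4, 5.0), ncol = 1,
                   dimnames = list(c("g1", "g2", "g3", "r1"), NULL))
  model <- fake_model(scores, kinds = c("gene", "gene", "gene", "reaction"))
  col <- threshold_sets(model, thresholds = 2, minsize = 1)
  expect_equal(collection_as_list(col),
               list(PC1.pos.t2 = "g1", PC1.neg.t2 = "g2"))
  # no arm emitted when nothing crosses the threshold
  col5 <- threshold_sets(model, thresholds = 4, minsize = 1)
  expect_equal(nrow(col5), 0)
  expect_error(threshold_sets(model, thresholds = 1.5), "integer")
})

test_that("boundary scores are excluded: the rule is strictly greater", {
  scores <- matrix(c(1, 1.0001, -1, -2), ncol = 1,
                   dimnames = list(paste0("g", 1:4), NULL))
  col <- threshold_sets(fake_model(scores), thresholds = 1, minsize = 1)
  expect_equal(collection_as_list(col),
               list(PC1.pos.t1 = "g2", PC1.neg.t1 = "g4"))
})

test_that("threshold and step collections match brute-force oracles", {
  for (s in 1:12) {
    scores <- withr::with_seed(s, matrix(
      stats::rnorm(15 * 4, 0, 2), 15, 4,
      dimnames = list(paste0("g", 1:15), NULL)))
    kinds <- rep("gene", 15)
    model <- fake_model(scores, kinds)
    got <- collection_as_list(threshold_sets(model, 1:3, minsize = 2))
    expect_equal(got, oracle_threshold(scores, kinds, 1:3, 2))
    got_s <- collection_as_list(step_function_sets(model, minsize = 2))
    want_s <- oracle_step(scores, kinds, 2)
    expect_setequal(names(got_s), names(want_s))
    expect_equal(got_s[sort(names(got_s))], want_s[sort(names(want_s))])
  }
})

test_that("threshold sets are nested: t+1 is a subset of t", {
  model <- pca_of_laplacian(build_laplacian(random_network(4, n_genes = 12,
                                                           n_edges = 40)))
  col <- threshold_sets(model, 1:10, minsize = 1)
  for (k in unique(col$component)) {
    for (arm in c("pos", "neg")) {
      sub <- col[col$component == k & col$arm == arm, ]
      ts <- as.integer(sub$parameter)
      if (nrow(sub) < 2) next
      for (i in order(ts)[-1]) {
        lower <- sub$members[[which(ts == ts[i] - 1)[1]]]
        if (length(lower)) {
          expect_true(all(sub$members[[i]] %in% lower))
        }
      }
    }
  }
})

test_that("step runs split on gaps of one or more", {
  sc <- matrix(c(1.2, 1.5, 3.0, 3.4), ncol = 1,
               dimnames = list(paste0("g", 1:4), NULL))
  col <- step_function_sets(fake_model(sc), minsize = 1)
  expect_equal(collection_as_list(col),
               list(PC1.pos.s1 = c("g1", "g2"), PC1.pos.s2 = c("g3", "g4")))
  sc2 <- matrix(c(1.1, 1.9, 2.7), ncol = 1,
                dimnames = list(paste0("g", 1:3), NULL))
  col2 <- step_function_sets(fake_model(sc2), minsize = 1)
  expect_equal(lengths(col2$members), 3L, ignore_attr = TRUE)
  # a gap of exactly 1.0 closes the range
  sc3 <- matrix(c(1.5, 2.5), ncol = 1, dimnames = list(c("a", "b"), NULL))
  col3 <- step_function_sets(fake_model(sc3), minsize = 1)
  expect_equal(nrow(col3), 2)
})

test_that("every step set lies inside its component-arm threshold-1 set", {
  model <- pca_of_laplacian(build_laplacian(random_network(9, n_genes = 12,
                                                           n_edges = 45)))
  th1 <- threshold_sets(model, 1, minsize = 1)
  st <- step_function_sets(model, minsize = 1)
  for (i in seq_len(nrow(st))) {
    parent <- th1$members[th1$component == st$component[i] &
                            th1$arm == st$arm[i]]
    expect_length(parent, 1)
    expect_true(all(st$members[[i]] %in% parent[[1]]))
  }
  expect_lte(nrow(st), nrow(th1[lengths(th1$members) > 0, ]) +
               sum(lengths(st$members) == 0))
})

test_that("probe substitution replaces genes before the size filter", {
  mapping <- tibble::tibble(gene = c("g1", "g1", "g2"),
                            probeset = c("p1", "p2", "p3"))
  expect_equal(map_genes_to_probes("g1", mapping), c("p1", "p2"))
  expect_equal(map_genes_to_probes("g_unmapped", mapping), character())
  for (s in 1:5) {
    mp <- withr::with_seed(s, tibble::tibble(
      gene = sample(paste0("g", 1:10), 30, replace = TRUE),
      probeset = paste0("p", sample(40, 30))))
    genes <- paste0("g", 1:6)
    naive <- sort(unique(unlist(lapply(genes, function(g) {
      mp$probeset[mp$gene == g]
    }))))
    expect_equal(map_genes_to_probes(genes, mp), naive)
  }
  # mapped sets below the minimum are discarded
  scores <- matrix(c(3, 3, 3), ncol = 1,
                   dimnames = list(c("g1", "g2", "g3"), NULL))
  col <- threshold_sets(fake_model(scores), 1, mapping = mapping,
                        minsize = 5)
  expect_equal(nrow(col), 0)
  col3 <- threshold_sets(fake_model(scores), 1, mapping = mapping,
                         minsize = 3)
  expect_equal(col3$members[[1]], c("p1", "p2", "p3"))
})

test_that("GMT files round-trip the collection exactly", {
  f <- withr::local_tempfile(fileext = ".gmt")
  empty <- gene_set_collection(tibble::tibble(set = character(),
                                              members = list()))
  write_gmt(empty, f)
  expect_equal(nrow(read_gmt(f)), 0)

  one <- gene_set_collection(tibble::tibble(
    set = "s1", component = 3L, arm = "pos", method = "threshold",
    parameter = "2", members = list(letters[1:5])))
  write_gmt(one, f)
  line <- readLines(f)
  expect_length(line, 1)
  expect_length(strsplit(line, "\t")[[1]], 7)
  expect_equal(read_gmt(f), one)

  for (s in 1:5) {
    col <- random_collection(s, n_sets = 40)
    write_gmt(col, f)
    expect_equal(read_gmt(f), col)
  }

  bad <- gene_set_collection(tibble::tibble(
    set = "s1", members = list(c("a\tb", "c", "d", "e", "f"))))
  expect_error(write_gmt(bad, f), "tab")
})

test_that("collections never contain reaction or compound members", {
  for (s in 1:5) {
    net <- random_network(s, n_edges = 35)
    model <- pca_of_laplacian(build_laplacian(net))
    col <- threshold_sets(model, 1:3, minsize = 1)
    genes <- net$nodes$id[net$nodes$kind == "gene"]
    expect_true(all(unlist(col$members) %in% genes))
    col2 <- step_function_sets(model, minsize = 1)
    expect_true(all(unlist(col2$members) %in% genes))
  }
})

test_that("standard-fixture collections are sparse and overlap decays", {
  spec <- synthetic_spec(seed = 2)
  net <- generate_network(spec)
  mapping <- generate_probe_mapping(net)
  model <- pca_of_laplacian(build_laplacian(net))
  col <- threshold_sets(model, 1, mapping = mapping)
  oc <- overlap_census(col)
  # most pairwise intersections are empty on a modular network
  expect_gte(oc$pairs_empty / oc$pairs_total, 0.5)
  # empty intersection is by far the most common outcome
  h <- oc$size_histogram
  expect_equal(h$intersection_size[which.max(h$n_pairs)], 0L)
  expect_gt(oc$pairs_empty, max(h$n_pairs[h$intersection_size > 0]))
})
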