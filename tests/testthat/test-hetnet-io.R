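test_that("gene network TSV reading handles weights, duplicates and self-loops", {
  p <- write_tmp(c("# comment", "g1\tg2\t1.0", "", "g2\tg3\t1.0"))
  gn <- read_gene_network(p)
  expect_equal(gn$ids, c("g1", "g2", "g3"))
  expect_equal(Matrix::nnzero(gn$adjacency) / 2, 2)
  expect_equal(gn$adjacency["g1", "g2"], 1)
  expect_true(Matrix::isSymmetric(gn$adjacency))
  expect_equal(unname(Matrix::diag(gn$adjacency)), rep(0, 3))

  # self-loop dropped, node retained
  p2 <- write_tmp("g1\tg1\t1.0")
  gn2 <- read_gene_network(p2)
  expect_equal(gn2$ids, "g1")
  expect_equal(Matrix::nnzero(gn2$adjacency), 0)

  # duplicate edges keep the maximum weight, either orientation
  p3 <- write_tmp(c("g1\tg2\t2.0", "g2\tg1\t3.0"))
  expect_equal(read_gene_network(p3)$adjacency["g1", "g2"], 3)

  # missing weight defaults to 1; SIF dialect takes (a, relation, b)
  p4 <- write_tmp("g1\tg2")
  expect_equal(read_gene_network(p4)$adjacency["g1", "g2"], 1)
  p5 <- write_tmp("g1\tpp\tg2")
  expect_equal(read_gene_network(p5, dialect = "sif")$adjacency["g1", "g2"], 1)
})

test_that("malformed or invalid gene network lines fail with a line number", {
  p <- write_tmp(c("g1\tg2\t1.0", "g3"))
  expect_error(read_gene_network(p), "line 2", class = "rwrhnet_parse_error")
  p2 <- write_tmp(c("# header", "g1\tg2\t-1"))
  expect_error(read_gene_network(p2), "negative",
    class = "rwrhnet_validation_error"
  )
  p3 <- write_tmp("g1\tg2\tabc")
  expect_error(read_gene_network(p3), "non-numeric", class = "rwrhnet_parse_error")
  expect_error(read_gene_network("/nonexistent/x.tsv"), "not found",
    class = "rwrhnet_file_error"
  )
})

test_that("top-k similarity filter keeps the union of per-disease choices", {
  # a selects b, b selects a, c selects b => edges {a-b, b-c}
  m <- matrix(
    c(0, 0.9, 0.2,
      0.9, 0, 0.8,
      0.2, 0.8, 0),
    3, 3, byrow = TRUE, dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  dn <- disease_network(m, k_top = 1)
  expect_equal(dn$adjacency["a", "b"], 0.9)
  expect_equal(dn$adjacency["b", "c"], 0.8)
  expect_equal(dn$adjacency["a", "c"], 0)
  expect_true(Matrix::isSymmetric(dn$adjacency))

  # vacuous filter keeps the complete graph
  dn_full <- disease_network(m, k_top = 2)
  expect_equal(Matrix::nnzero(dn_full$adjacency), 6)

  # asymmetric input is averaged before filtering
  m2 <- m
  m2["a", "b"] <- 0.5
  dn2 <- disease_network(m2, k_top = 2)
  expect_equal(dn2$adjacency["a", "b"], 0.7)

  # ties at the cutoff break lexicographically by neighbour id
  mt <- matrix(0.5, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(mt) <- 0
  dnt <- disease_network(mt, k_top = 1)
  # a picks b, b picks a, c picks a: edges a-b and a-c only
  expect_equal(dnt$adjacency["a", "b"], 0.5)
  expect_equal(dnt$adjacency["a", "c"], 0.5)
  expect_equal(dnt$adjacency["b", "c"], 0)
})

test_that("top-k filter property: every kept edge was somebody's choice", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:9, 1)
    ids <- paste0("D", seq_len(n))
    m <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    k <- sample(1:3, 1)
    dn <- disease_network(m, k_top = k)
    # recompute the per-row top-k choices by hand
    chosen <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
      nb <- order(-m[i, ], ids)[seq_len(k)]
      chosen[i, nb] <- TRUE
    }
    kept <- as.matrix(dn$adjacency) > 0
    expect_equal(kept, chosen | t(chosen))
    # every disease keeps at least one edge and its own picks
    expect_true(all(Matrix::rowSums(dn$adjacency > 0) >= 1))
  }
})

test_that("similarity matrix validation rejects bad input", {
  p <- write_tmp(c("a\tb", "a\t0\t0.5", "b\t0.5\t0", "c\t0\t0"))
  expect_error(read_disease_similarity(p, format = "matrix"), "square",
    class = "rwrhnet_validation_error"
  )
  m <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(disease_network(m), "\\[0, 1\\]", class = "rwrhnet_validation_error")
  expect_error(disease_network(m / 2, k_top = 0), "positive",
    class = "rwrhnet_validation_error"
  )
})

test_that("matrix-format similarity file reads and filters like the in-memory matrix", {
  p <- write_tmp(c(
    "a\tb\tc",
    "a\t0\t0.9\t0.2",
    "b\t0.9\t0\t0.8",
    "c\t0.2\t0.8\t0"
  ))
  dn <- read_disease_similarity(p, format = "matrix", k_top = 1)
  expect_equal(dn$adjacency["a", "b"], 0.9)
  expect_equal(dn$adjacency["a", "c"], 0)
})

test_that("bipartite reading applies the default weight and max-duplicate rule", {
  p <- write_tmp(c("MIM114480\tBRCA2", "MIM114480\tBRCA2\t2.0", "MIM114480\tTP53\t0.5"))
  bp <- read_bipartite(p)
  expect_equal(nrow(bp$pairs), 2)
  expect_equal(
    bp$pairs$weight[bp$pairs$gene == "BRCA2"], 2.0
  )
  # empty file gives an empty association set
  p_empty <- write_tmp("# nothing here")
  expect_equal(nrow(read_bipartite(p_empty)$pairs), 0)
})

test_that("assembly aligns indices, drops unresolvable pairs, rejects isolates", {
  net <- micro_net()
  expect_equal(net$genes, c("g1", "g2", "g3"))
  expect_equal(net$diseases, c("d1", "d2"))
  nodes <- hetnet_nodes(net)
  expect_equal(nodes$index, 1:5)
  expect_true(max(nodes$index[nodes$type == "gene"]) <
    min(nodes$index[nodes$type == "disease"]))

  gn <- gene_network(tibble::tibble(from = c("g1", "g2"), to = c("g2", "g3")))
  dn <- disease_network(tibble::tibble(from = "d1", to = "d2", weight = 1))
  bp_bad <- bipartite_assoc(tibble::tibble(
    disease = c("d1", "d1"), gene = c("g1", "gX")
  ))
  expect_message(
    net2 <- assemble_heterogeneous(gn, dn, bp_bad),
    "dropped 1"
  )
  expect_equal(net2$n_dropped_pairs, 1)
  expect_equal(nrow(net2$pairs), 1)

  # isolated gene rejected by name
  gn_iso <- gene_network(
    tibble::tibble(from = c("g1", "g2"), to = c("g2", "g3")),
    ids = "g4"
  )
  bp <- bipartite_assoc(tibble::tibble(disease = "d1", gene = "g1"))
  expect_error(
    assemble_heterogeneous(gn_iso, dn, bp), "g4",
    class = "rwrhnet_validation_error"
  )

  # id collision between namespaces
  gn_cl <- gene_network(tibble::tibble(from = "d1", to = "g1"))
  expect_error(
    assemble_heterogeneous(gn_cl, dn, bp), "collide",
    class = "rwrhnet_validation_error"
  )
})

test_that("write/read round-trips preserve edge sets and weights", {
  for (seed in c(3, 11)) {
    net <- random_hetnet(seed)
    gn <- structure(list(ids = net$genes, adjacency = net$W_G),
      class = c("gene_network", "rwrhnet_subnetwork")
    )
    p <- tempfile(fileext = ".tsv")
    write_gene_network(gn, p)
    gn2 <- read_gene_network(p)
    # re-read ids cover every gene that has an edge
    expect_equal(as.matrix(gn2$adjacency),
      as.matrix(net$W_G[gn2$ids, gn2$ids]),
      tolerance = 1e-12
    )
    bp <- structure(list(pairs = net$pairs), class = "bipartite_assoc")
    p2 <- tempfile(fileext = ".tsv")
    write_bipartite(bp, p2)
    bp2 <- read_bipartite(p2)
    expect_equal(as.data.frame(bp2$pairs), as.data.frame(net$pairs),
      tolerance = 1e-12
    )
  }
})
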