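# Shared fixtures and independent oracles.
#
# The oracles deliberately re-derive every quantity from first principles
# (dense elementwise formulas, direct linear solves, explicit ROC
# integration) so they share no code path with the implementation.

suppressPackageStartupMessages(library(Matrix))

# 5-node worked example: gene chain g1-g2-g3, disease pair d1-d2,
# one association d1-g1.
micro_net <- function() {
  gn <- gene_network(tibble::tibble(
    from = c("g1", "g2"), to = c("g2", "g3")
  ))
  dn <- disease_network(tibble::tibble(from = "d1", to = "d2", weight = 1),
    k_top = 5
  )
  bp <- bipartite_assoc(tibble::tibble(disease = "d1", gene = "g1"))
  assemble_heterogeneous(gn, dn, bp)
}

# Dense elementwise evaluation of the four transition block formulas,
# including the all-mass-across rescue for nodes whose only links are
# bipartite. Loops on dense matrices; independent of the sparse builder.
dense_transition_oracle <- function(W_G, W_D, W_GD, lambda) {
  W_G <- as.matrix(W_G); W_D <- as.matrix(W_D); W_GD <- as.matrix(W_GD)
  ng <- nrow(W_G); nd <- nrow(W_D)
  M <- matrix(0, ng + nd, ng + nd)
  for (i in seq_len(ng)) {
    bip <- sum(W_GD[i, ]); gs <- sum(W_G[i, ])
    if (bip != 0) {
      M[i, ng + seq_len(nd)] <- if (gs != 0) lambda * W_GD[i, ] / bip else W_GD[i, ] / bip
    }
    if (gs != 0) {
      M[i, seq_len(ng)] <- if (bip != 0) (1 - lambda) * W_G[i, ] / gs else W_G[i, ] / gs
    }
  }
  for (i in seq_len(nd)) {
    bip <- sum(W_GD[, i]); ds <- sum(W_D[i, ])
    if (bip != 0) {
      M[ng + i, seq_len(ng)] <- if (ds != 0) lambda * W_GD[, i] / bip else W_GD[, i] / bip
    }
    if (ds != 0) {
      M[ng + i, ng + seq_len(nd)] <- if (bip != 0) (1 - lambda) * W_D[i, ] / ds else W_D[i, ] / ds
    }
  }
  M
}

# Direct steady-state solve: p = gamma * (I - (1-gamma) M^T)^-1 p0.
linear_solve_oracle <- function(M, p0, gamma) {
  M <- as.matrix(M)
  drop(solve(diag(nrow(M)) - (1 - gamma) * t(M), gamma * p0))
}

# Random heterogeneous network with all node types guaranteed degree >= 1
# (nodes without intra-layer edges get a bipartite pair, so the rescue
# branch of the transition builder is exercised).
random_hetnet <- function(seed, n_g = NULL, n_d = NULL) {
  set.seed(seed)
  n_g <- n_g %||% sample(4:10, 1)
  n_d <- n_d %||% sample(2:6, 1)
  genes <- paste0("g", seq_len(n_g))
  diseases <- paste0("D", seq_len(n_d))
  gpairs <- utils::combn(genes, 2)
  gon <- stats::runif(ncol(gpairs)) < 0.4
  ge <- tibble::tibble(
    from = gpairs[1, gon], to = gpairs[2, gon],
    weight = stats::runif(sum(gon), 0.1, 2)
  )
  dpairs <- if (n_d >= 2) utils::combn(diseases, 2) else matrix(character(), 2, 0)
  don <- stats::runif(ncol(dpairs)) < 0.5
  de <- tibble::tibble(
    from = dpairs[1, don], to = dpairs[2, don],
    weight = stats::runif(sum(don), 0.1, 1)
  )
  grid <- expand.grid(gene = genes, disease = diseases, stringsAsFactors = FALSE)
  bon <- stats::runif(nrow(grid)) < 0.3
  bp <- tibble::tibble(
    disease = grid$disease[bon], gene = grid$gene[bon],
    weight = stats::runif(sum(bon), 0.5, 1.5)
  )
  # guarantee positive total degree everywhere
  for (g in setdiff(genes, unique(c(ge$from, ge$to, bp$gene)))) {
    bp <- dplyr::bind_rows(bp, tibble::tibble(
      disease = sample(diseases, 1), gene = g, weight = 1
    ))
  }
  for (d in setdiff(diseases, unique(c(de$from, de$to, bp$disease)))) {
    bp <- dplyr::bind_rows(bp, tibble::tibble(
      disease = d, gene = sample(genes, 1), weight = 1
    ))
  }
  if (nrow(bp) == 0) {
    bp <- tibble::tibble(disease = diseases[1], gene = genes[1], weight = 1)
  }
  assemble_heterogeneous(
    gene_network(ge, ids = genes),
    disease_network(de, k_top = n_d, ids = diseases),
    bipartite_assoc(bp)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Explicit trapezoidal ROC integration for one held-out positive at rank
# `r` among `n` candidates with otherwise distinct scores, pooled by
# averaging across trials.
roc_integration_auc <- function(ranks, ns) {
  one <- function(r, n) {
    scores <- n - seq_len(n)
    labels <- seq_len(n) == r
    ord <- order(scores, decreasing = TRUE)
    tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
    tpr <- c(0, tp / sum(labels))
    fpr <- c(0, fp / sum(!labels))
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  mean(mapply(one, ranks, ns))
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
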