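#' Specification of a synthetic heterogeneous network
#'
#' Describes a seeded generator for gene-disease networks with planted
#' structure: a planted-partition gene network (dense within modules,
#' sparse between), diseases anchored to modules through causal gene sets,
#' a disease similarity network derived from causal-set overlap, and a
#' bipartite layer revealing only part of the truth so held-out
#' associations can be recovered.
#'
#' @param n_genes,n_diseases,n_modules Network dimensions.
#' @param p_in,p_out Within- and between-module edge probabilities
#'   (`p_in >= p_out`; equality removes the planted structure and serves
#'   as a null model).
#' @param genes_per_disease Causal genes drawn per disease from its
#'   module (must not exceed the module size).
#' @param known_fraction Fraction of each disease's causal genes revealed
#'   in the bipartite layer.
#' @param k_top Top-k similarity filter size.
#' @param rng_seed Integer seed driving all randomness.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 200L, n_diseases = 30L, n_modules = 10L,
                           p_in = 0.3, p_out = 0.01, genes_per_disease = 8L,
                           known_fraction = 0.5, k_top = 5L, rng_seed = 42L) {
  stopifnot_scalar_prob(p_in, "p_in", open = FALSE)
  stopifnot_scalar_prob(p_out, "p_out", open = FALSE)
  stopifnot_scalar_prob(known_fraction, "known_fraction")
  if (p_in < p_out) param_error("`p_in` must be >= `p_out`")
  if (n_modules > n_genes) param_error("`n_modules` must be <= `n_genes`")
  min_module <- floor(n_genes / n_modules)
  if (genes_per_disease > min_module) {
    param_error(sprintf(
      "`genes_per_disease` (%d) exceeds the module size (%d)",
      genes_per_disease, min_module
    ))
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_diseases = as.integer(n_diseases),
      n_modules = as.integer(n_modules), p_in = p_in, p_out = p_out,
      genes_per_disease = as.integer(genes_per_disease),
      known_fraction = known_fraction, k_top = as.integer(k_top),
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic heterogeneous network with planted structure
#'
#' The gene network follows a planted-partition model over `n_modules`
#' modules; every disease is assigned a module and draws
#' `genes_per_disease` causal genes from it; disease similarity is the
#' Jaccard index of causal gene sets plus a small uniform noise term in
#' \[0, 0.05\] (so ties in the top-k filter are broken by real numbers,
#' not id order); the bipartite layer reveals a per-disease
#' `ceil(known_fraction * genes_per_disease)` subset of the truth. Genes
#' left with no interaction are re-wired with one uniformly chosen edge so
#' the assembled network has no degree-0 node and `n_genes` stays exact.
#' All randomness derives from `spec$rng_seed`; equal specs give
#' bit-identical networks.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_hetnet`: the assembled `$net` (a `hetnet`), the
#'   full `$truth` and revealed `$revealed` association tibbles, and the
#'   `$spec`.
#' @export
generate_hetnet <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng(spec$rng_seed, {
    gene_ids <- sprintf("g%0*d", nchar(spec$n_genes), seq_len(spec$n_genes))
    disease_ids <- sprintf("d%0*d", nchar(spec$n_diseases), seq_len(spec$n_diseases))
    gene_module <- sort(rep_len(seq_len(spec$n_modules), spec$n_genes))

    # planted-partition gene network
    pr <- utils::combn(spec$n_genes, 2)
    p_edge <- ifelse(gene_module[pr[1, ]] == gene_module[pr[2, ]],
                     spec$p_in, spec$p_out)
    on <- stats::runif(ncol(pr)) < p_edge
    from <- gene_ids[pr[1, on]]
    to <- gene_ids[pr[2, on]]
    # re-wire isolated genes with one uniform edge each
    isolated <- setdiff(gene_ids, c(from, to))
    for (g in isolated) {
      partner <- sample(setdiff(gene_ids, g), 1L)
      from <- c(from, g)
      to <- c(to, partner)
    }
    gn <- gene_network(tibble(from = from, to = to, weight = 1))

    # causal gene sets, one module per disease
    disease_module <- rep_len(seq_len(spec$n_modules), spec$n_diseases)
    truth <- purrr::map(seq_len(spec$n_diseases), function(i) {
      pool <- gene_ids[gene_module == disease_module[i]]
      tibble(
        disease = disease_ids[i],
        gene = sort(sample(pool, spec$genes_per_disease))
      )
    }) |> dplyr::bind_rows()

    # similarity = causal-set Jaccard + uniform noise, then top-k filter
    causal <- split(truth$gene, truth$disease)[disease_ids]
    nd <- spec$n_diseases
    sim <- matrix(0, nd, nd, dimnames = list(disease_ids, disease_ids))
    for (i in seq_len(nd - 1)) {
      for (j in seq(i + 1, nd)) {
        jac <- length(intersect(causal[[i]], causal[[j]])) /
          length(union(causal[[i]], causal[[j]]))
        s <- min(jac + stats::runif(1, 0, 0.05), 1)
        sim[i, j] <- s
        sim[j, i] <- s
      }
    }
    dn <- disease_network(sim, k_top = spec$k_top)

    # reveal part of the truth as the bipartite layer
    n_reveal <- ceiling(spec$known_fraction * spec$genes_per_disease)
    revealed <- truth |>
      dplyr::group_by(.data$disease) |>
      dplyr::slice_sample(n = n_reveal) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$disease, .data$gene)
    bp <- bipartite_assoc(revealed)

    structure(
      list(
        net = assemble_heterogeneous(gn, dn, bp),
        truth = truth, revealed = revealed, spec = spec
      ),
      class = "synthetic_hetnet"
    )
  })
}

#' Degree-preserving shuffle of the bipartite layer (null model)
#'
#' Permutes the disease labels of the revealed disease-gene pairs, so each
#' gene keeps its number of associations while the disease-gene pairing is
#' destroyed. Duplicate pairs created by the permutation are collapsed.
#' The truth map is untouched.
#'
#' @param syn A `synthetic_hetnet`.
#' @param rng_seed Seed for the permutation.
#' @return A new `synthetic_hetnet` with the shuffled bipartite layer.
#' @export
shuffle_bipartite <- function(syn, rng_seed) {
  stopifnot(inherits(syn, "synthetic_hetnet"))
  pairs <- syn$net$pairs
  if (nrow(pairs) == 0) validate_error("bipartite layer is empty")
  with_rng(rng_seed, {
    perm <- sample.int(nrow(pairs))
    shuffled <- pairs |>
      dplyr::mutate(disease = .data$disease[perm]) |>
      dplyr::distinct(.data$disease, .data$gene, .keep_all = TRUE)
    gn <- structure(list(ids = syn$net$genes, adjacency = syn$net$W_G),
                    class = c("gene_network", "rwrhnet_subnetwork"))
    dn <- structure(list(ids = syn$net$diseases, adjacency = syn$net$W_D),
                    class = c("disease_network", "rwrhnet_subnetwork"))
    out <- syn
    out$net <- assemble_heterogeneous(gn, dn, bipartite_assoc(shuffled))
    out$revealed <- shuffled
    out
  })
}

#' @export
print.synthetic_hetnet <- function(x, ...) {
  cat(sprintf(
    "<synthetic_hetnet> seed %d | %d modules | %d/%d associations revealed\n",
    x$spec$rng_seed, x$spec$n_modules, nrow(x$revealed), nrow(x$truth)
  ))
  print(x$net)
  invisible(x)
}

#' Write a synthetic network to the pipeline's text formats
#'
#' Emits `gene_network.tsv`, `disease_similarity.tsv` (edge list of the
#' filtered similarity network), `bipartite.tsv` and `truth.tsv`
#' (`disease<TAB>gene<TAB>revealed{0,1}`) into `dir`, so the file-based
#' pipeline can run end-to-end on generated data.
#'
#' @param syn A `synthetic_hetnet`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_synthetic <- function(syn, dir) {
  stopifnot(inherits(syn, "synthetic_hetnet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene_network = file.path(dir, "gene_network.tsv"),
    disease_similarity = file.path(dir, "disease_similarity.tsv"),
    bipartite = file.path(dir, "bipartite.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_edge_list(syn$net$W_G, paths[["gene_network"]])
  write_edge_list(syn$net$W_D, paths[["disease_similarity"]])
  utils::write.table(
    syn$net$pairs[, c("disease", "gene", "weight")],
    paths[["bipartite"]],
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  truth <- syn$truth |>
    dplyr::mutate(revealed = as.integer(paste(.data$disease, .data$gene) %in%
      paste(syn$revealed$disease, syn$revealed$gene)))
  utils::write.table(truth, paths[["truth"]],
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(paths)
}
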