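#' Build a gene/protein interaction network from an edge table
#'
#' Constructs an undirected, weighted gene network. Self-loops are dropped,
#' duplicate edges keep the maximum weight, and a missing `weight` column
#' defaults to 1.
#'
#' @param edges A data frame with columns `from`, `to` and optionally
#'   `weight` (non-negative; default 1).
#' @param ids Optional character vector of gene ids to include even when
#'   they touch no interaction (e.g. genes linked only through the
#'   bipartite layer); ids appearing in `edges` are always included.
#' @return A `gene_network`: gene ids plus a symmetric sparse adjacency
#'   matrix with zero diagonal.
#' @examples
#' gn <- gene_network(tibble::tibble(from = c("g1", "g2"), to = c("g2", "g3")))
#' gn
#' @export
gene_network <- function(edges, ids = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    param_error("`edges` needs columns `from` and `to`")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (any(edges$weight < 0)) validate_error("edge weights must be non-negative")
  adj <- edge_table_to_adjacency(edges$from, edges$to, edges$weight, ids = ids)
  structure(
    list(ids = rownames(adj), adjacency = adj),
    class = c("gene_network", "rwrhnet_subnetwork")
  )
}

#' Build a disease similarity network, sparsified by a top-k filter
#'
#' For every disease the `k_top` strongest similarities are selected (ties
#' broken lexicographically by neighbour id) and the union of selections is
#' symmetrized: an edge is kept, with its similarity as weight, if either
#' endpoint selected it. An asymmetric input matrix is symmetrized by
#' averaging before filtering.
#'
#' @param similarity Either an edge data frame (`from`, `to`, `weight`) or a
#'   square numeric matrix with disease ids as dimnames, entries in \[0, 1\].
#' @param k_top Number of strongest similarities to keep per disease
#'   (default 5).
#' @param ids Optional disease ids to include even without any similarity
#'   edge (edge-list input only; the matrix format carries its own ids).
#' @return A `disease_network` with the filtered symmetric adjacency.
#' @export
disease_network <- function(similarity, k_top = 5, ids = NULL) {
  if (!is.numeric(k_top) || length(k_top) != 1L || k_top < 1) {
    validate_error("`k_top` must be a positive integer")
  }
  if (is.matrix(similarity)) {
    if (nrow(similarity) != ncol(similarity)) {
      validate_error("similarity matrix must be square")
    }
    if (is.null(rownames(similarity)) || is.null(colnames(similarity))) {
      validate_error("similarity matrix needs disease ids as dimnames")
    }
    if (!identical(rownames(similarity), colnames(similarity))) {
      validate_error("similarity matrix row and column ids must match")
    }
    if (any(similarity < 0) || any(similarity > 1)) {
      validate_error("similarity entries must lie in [0, 1]")
    }
    sim <- (similarity + t(similarity)) / 2  # phenotypic similarity is symmetric
    diag(sim) <- 0
    adj <- as(as(Matrix::Matrix(sim, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    adj <- adj[order(rownames(adj)), order(rownames(adj)), drop = FALSE]
  } else {
    similarity <- as_tibble(similarity)
    if (!"weight" %in% names(similarity)) similarity$weight <- 1
    adj <- edge_table_to_adjacency(similarity$from, similarity$to,
                                   similarity$weight, ids = ids)
  }
  adj <- top_k_filter(adj, k_top)
  structure(
    list(ids = rownames(adj), adjacency = adj, k_top = k_top),
    class = c("disease_network", "rwrhnet_subnetwork")
  )
}

#' Known disease-gene associations (bipartite layer)
#'
#' @param pairs A data frame with columns `disease`, `gene` and optionally
#'   `weight` (positive; default 1). Duplicate pairs keep the maximum weight.
#' @return A `bipartite_assoc` holding the weighted pair table.
#' @export
bipartite_assoc <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    pairs <- tibble(disease = character(), gene = character(), weight = numeric())
  }
  if (!all(c("disease", "gene") %in% names(pairs))) {
    param_error("`pairs` needs columns `disease` and `gene`")
  }
  if (!"weight" %in% names(pairs)) pairs$weight <- 1
  if (nrow(pairs) > 0 && any(pairs$weight <= 0)) {
    validate_error("association weights must be positive")
  }
  if (nrow(pairs) > 0) {
    pairs <- pairs |>
      dplyr::group_by(.data$disease, .data$gene) |>
      dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
      dplyr::arrange(.data$disease, .data$gene)
  }
  structure(list(pairs = pairs), class = "bipartite_assoc")
}

# ---- file readers -----------------------------------------------------------

#' Read a gene/protein network from a TSV edge list or SIF file
#'
#' TSV lines are `gene_a<TAB>gene_b[<TAB>weight]`; SIF lines are
#' `a<TAB>relation<TAB>b` (weight 1). Blank lines and `#` comments are
#' skipped; fields may be separated by tabs or spaces.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"sif"`.
#' @return A [gene_network()].
#' @export
read_gene_network <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  rows <- read_clean_lines(path)
  fields <- split_fields(rows$text)
  edges <- purrr::map2(fields, rows$line, function(f, ln) {
    if (dialect == "sif") {
      if (length(f) != 3L) {
        parse_error(path, ln, sprintf("expected 3 SIF fields, got %d", length(f)))
      }
      list(from = f[[1]], to = f[[3]], weight = 1)
    } else {
      if (length(f) < 2L || length(f) > 3L) {
        parse_error(path, ln, sprintf("expected 2-3 fields, got %d", length(f)))
      }
      w <- if (length(f) == 3L) as_weight(f[[3]], path, ln) else 1
      list(from = f[[1]], to = f[[2]], weight = w)
    }
  })
  gene_network(dplyr::bind_rows(edges))
}

#' Read a disease similarity network and apply the top-k filter
#'
#' The edge-list format is `a<TAB>b<TAB>weight`; the matrix format is a
#' dense TSV with a header row and leading column of disease ids
#' (MimMiner-style), entries in \[0, 1\].
#'
#' @param path Path to the file.
#' @param format `"edgelist"` or `"matrix"`.
#' @inheritParams disease_network
#' @return A [disease_network()].
#' @export
read_disease_similarity <- function(path, format = c("edgelist", "matrix"),
                                    k_top = 5) {
  format <- match.arg(format)
  rows <- read_clean_lines(path)
  if (format == "matrix") {
    fields <- split_fields(rows$text)
    header <- fields[[1]]
    n <- length(header)
    body <- fields[-1]
    if (length(body) != n) {
      validate_error(sprintf(
        "%s: similarity matrix is not square (%d ids, %d rows)",
        path, n, length(body)
      ))
    }
    sim <- matrix(0, n, n, dimnames = list(header, header))
    for (i in seq_len(n)) {
      f <- body[[i]]
      ln <- rows$line[i + 1L]
      if (length(f) != n + 1L) {
        parse_error(path, ln, sprintf("expected %d fields, got %d", n + 1L, length(f)))
      }
      vals <- suppressWarnings(as.numeric(f[-1]))
      if (anyNA(vals)) parse_error(path, ln, "non-numeric similarity value")
      sim[f[[1]], ] <- vals
    }
    disease_network(sim, k_top = k_top)
  } else {
    fields <- split_fields(rows$text)
    edges <- purrr::map2(fields, rows$line, function(f, ln) {
      if (length(f) < 2L || length(f) > 3L) {
        parse_error(path, ln, sprintf("expected 2-3 fields, got %d", length(f)))
      }
      w <- if (length(f) == 3L) as_weight(f[[3]], path, ln) else 1
      list(from = f[[1]], to = f[[2]], weight = w)
    })
    disease_network(dplyr::bind_rows(edges), k_top = k_top)
  }
}

#' Read disease-gene associations from a TSV file
#'
#' Lines are `disease_id<TAB>gene_id[<TAB>weight]`; duplicates keep the
#' maximum weight.
#'
#' @param path Path to the file.
#' @return A [bipartite_assoc()].
#' @export
read_bipartite <- function(path) {
  rows <- read_clean_lines(path)
  fields <- split_fields(rows$text)
  pairs <- purrr::map2(fields, rows$line, function(f, ln) {
    if (length(f) < 2L || length(f) > 3L) {
      parse_error(path, ln, sprintf("expected 2-3 fields, got %d", length(f)))
    }
    w <- if (length(f) == 3L) as_weight(f[[3]], path, ln) else 1
    list(disease = f[[1]], gene = f[[2]], weight = w)
  })
  bipartite_assoc(dplyr::bind_rows(pairs))
}

# ---- writers (round-trip support) -------------------------------------------

#' Write networks back to their text formats
#'
#' `write_gene_network()` and `write_disease_similarity()` emit a TSV edge
#' list (each undirected edge once, endpoints sorted); `write_bipartite()`
#' emits `disease<TAB>gene<TAB>weight` lines.
#'
#' @param x The network object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gene_network <- function(x, path) {
  write_edge_list(x$adjacency, path)
}

#' @rdname write_gene_network
#' @export
write_disease_similarity <- function(x, path) {
  write_edge_list(x$adjacency, path)
}

#' @rdname write_gene_network
#' @export
write_bipartite <- function(x, path) {
  utils::write.table(x$pairs, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

write_edge_list <- function(adj, path) {
  e <- adjacency_to_edges(adj)
  utils::write.table(e, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Edge table of a subnetwork
#'
#' @param x A `gene_network` or `disease_network`.
#' @param ... Unused.
#' @return A tibble with one row per undirected edge (`from` < `to`).
#' @export
as_tibble.rwrhnet_subnetwork <- function(x, ...) adjacency_to_edges(x$adjacency)

# ---- assembly ---------------------------------------------------------------

#' Assemble the heterogeneous gene-disease network
#'
#' Aligns the gene network, the disease similarity network and the bipartite
#' association layer into one indexed graph: genes occupy global indices
#' `1..n_G`, diseases `n_G+1..n_G+n_D`. Bipartite pairs whose gene or disease
#' id does not resolve are dropped (the count is reported in the object and
#' as a message). Every retained node must touch at least one edge across
#' the three layers; the restart term then makes the walk well defined
#' without requiring a single connected component.
#'
#' @param gene_net A [gene_network()].
#' @param disease_net A [disease_network()].
#' @param bipartite A [bipartite_assoc()].
#' @return A `hetnet` with blocks `W_G`, `W_D` and `W_GD` (gene rows,
#'   disease columns).
#' @export
assemble_heterogeneous <- function(gene_net, disease_net, bipartite) {
  stopifnot(
    inherits(gene_net, "gene_network"),
    inherits(disease_net, "disease_network"),
    inherits(bipartite, "bipartite_assoc")
  )
  genes <- gene_net$ids
  diseases <- disease_net$ids
  if (length(genes) == 0 || length(diseases) == 0 || nrow(bipartite$pairs) == 0) {
    validate_error("all three component networks must be non-empty")
  }
  clash <- intersect(genes, diseases)
  if (length(clash) > 0) {
    validate_error(paste0(
      "gene and disease namespaces collide: ",
      paste(utils::head(clash, 5), collapse = ", ")
    ))
  }
  pairs <- bipartite$pairs
  resolved <- pairs$gene %in% genes & pairs$disease %in% diseases
  n_dropped <- sum(!resolved)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d bipartite pair(s) with unresolvable ids", n_dropped))
  }
  pairs <- pairs[resolved, , drop = FALSE]
  W_GD <- Matrix::sparseMatrix(
    i = match(pairs$gene, genes), j = match(pairs$disease, diseases),
    x = pairs$weight, dims = c(length(genes), length(diseases)),
    dimnames = list(genes, diseases)
  )
  deg_g <- Matrix::rowSums(gene_net$adjacency) + Matrix::rowSums(W_GD)
  deg_d <- Matrix::rowSums(disease_net$adjacency) + Matrix::colSums(W_GD)
  isolated <- c(genes[deg_g == 0], diseases[deg_d == 0])
  if (length(isolated) > 0) {
    validate_error(paste0(
      "node(s) with total degree 0 across all layers: ",
      paste(utils::head(isolated, 10), collapse = ", ")
    ))
  }
  structure(
    list(
      genes = genes, diseases = diseases,
      W_G = gene_net$adjacency, W_D = disease_net$adjacency, W_GD = W_GD,
      pairs = pairs, n_dropped_pairs = n_dropped
    ),
    class = "hetnet"
  )
}

#' Node table of a heterogeneous network
#'
#' @param net A `hetnet`.
#' @return A tibble with `id`, `type` and the global `index` (genes first).
#' @export
hetnet_nodes <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  tibble(
    id = c(net$genes, net$diseases),
    type = rep(c("gene", "disease"), c(length(net$genes), length(net$diseases))),
    index = seq_len(length(net$genes) + length(net$diseases))
  )
}

#' @export
print.hetnet <- function(x, ...) {
  cat(sprintf(
    "<hetnet> %d genes (%d interactions), %d diseases (%d similarities), %d associations\n",
    length(x$genes), Matrix::nnzero(x$W_G) / 2,
    length(x$diseases), Matrix::nnzero(x$W_D) / 2,
    nrow(x$pairs)
  ))
  if (x$n_dropped_pairs > 0) {
    cat(sprintf("  (%d unresolvable pairs dropped at assembly)\n", x$n_dropped_pairs))
  }
  invisible(x)
}

#' @export
print.rwrhnet_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<%s> %d nodes, %d edges\n",
    class(x)[1], length(x$ids), Matrix::nnzero(x$adjacency) / 2
  ))
  invisible(x)
}

#' @export
print.bipartite_assoc <- function(x, ...) {
  cat(sprintf(
    "<bipartite_assoc> %d disease-gene pairs (%d diseases, %d genes)\n",
    nrow(x$pairs), dplyr::n_distinct(x$pairs$disease),
    dplyr::n_distinct(x$pairs$gene)
  ))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

# Undirected weighted adjacency from parallel edge vectors: self-loops are
# dropped, duplicates (either orientation) keep the maximum weight, node ids
# are sorted for a reproducible ordering.
edge_table_to_adjacency <- function(from, to, weight, ids = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  ids <- sort(unique(c(from, to, as.character(ids %||% character()))))
  keep <- from != to
  from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  e <- if (length(lo) == 0) {
    tibble(lo = character(), hi = character(), weight = numeric())
  } else {
    tibble(lo = lo, hi = hi, weight = weight) |>
      dplyr::group_by(.data$lo, .data$hi) |>
      dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
      dplyr::filter(.data$weight > 0)
  }
  Matrix::sparseMatrix(
    i = c(match(e$lo, ids), match(e$hi, ids)),
    j = c(match(e$hi, ids), match(e$lo, ids)),
    x = c(e$weight, e$weight),
    dims = c(length(ids), length(ids)), dimnames = list(ids, ids)
  )
}

adjacency_to_edges <- function(adj) {
  m <- as(Matrix::triu(adj), "TsparseMatrix")
  ids <- rownames(adj)
  tibble(from = ids[m@i + 1L], to = ids[m@j + 1L], weight = m@x) |>
    dplyr::filter(.data$weight > 0) |>
    dplyr::arrange(.data$from, .data$to)
}

# Per-node strongest-k selection, union-symmetrized. Ties at the cutoff are
# broken lexicographically by neighbour id so the result is reproducible.
top_k_filter <- function(adj, k) {
  ids <- rownames(adj)
  n <- length(ids)
  sel_i <- integer(0)
  sel_j <- integer(0)
  for (i in seq_len(n)) {
    w <- adj[i, ]
    nz <- which(w > 0)
    if (length(nz) == 0) next
    ord <- nz[order(-w[nz], ids[nz])]
    pick <- ord[seq_len(min(k, length(ord)))]
    sel_i <- c(sel_i, rep.int(i, length(pick)))
    sel_j <- c(sel_j, pick)
  }
  keep <- Matrix::sparseMatrix(
    i = sel_i, j = sel_j, x = 1, dims = c(n, n), dimnames = list(ids, ids)
  )
  keep <- ((keep + t(keep)) > 0) * 1
  out <- adj * keep
  as(as(out, "generalMatrix"), "CsparseMatrix")
}
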