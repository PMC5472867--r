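#' Build the block transition matrix of the heterogeneous network
#'
#' Assembles the row-stochastic transition matrix
#' \deqn{W' = \begin{bmatrix} W'_G & W'_{GD} \\ W'_{DG} & W'_D \end{bmatrix}}
#' from the three adjacency blocks. A walker at a gene with bipartite links
#' jumps to the disease layer with probability `lambda` (mass split
#' proportionally to association weights) and otherwise moves within the
#' gene network (mass `1 - lambda`, split proportionally to interaction
#' weights); a gene without bipartite links spends all its mass inside the
#' gene network. Diseases behave symmetrically. A node whose only links are
#' bipartite sends its entire mass across (the bipartite block is
#' renormalized to 1) so every row remains stochastic.
#'
#' `M[i, j]` is the probability of moving from node `i` to node `j`; rows
#' and columns follow the hetnet index (genes first, then diseases).
#'
#' @param net A `hetnet` from [assemble_heterogeneous()].
#' @param lambda Jumping probability in (0, 1); default 0.6.
#' @return A `transition_matrix`: the sparse `N x N` matrix plus `lambda`
#'   and the gene/disease split.
#' @export
build_transition <- function(net, lambda = 0.6) {
  stopifnot(inherits(net, "hetnet"))
  stopifnot_scalar_prob(lambda, "lambda")
  W_G <- net$W_G
  W_D <- net$W_D
  W_GD <- net$W_GD
  bip_g <- Matrix::rowSums(W_GD)
  bip_d <- Matrix::colSums(W_GD)
  gsum <- Matrix::rowSums(W_G)
  dsum <- Matrix::rowSums(W_D)

  # per-row scale factors implementing the four piecewise block formulas,
  # with lambda promoted to 1 when the intra block is empty (rescue rule)
  scale_rows <- function(mass, denom) {
    ifelse(denom > 0, mass / denom, 0)
  }
  f_gd <- scale_rows(ifelse(gsum > 0, lambda, 1), bip_g)
  f_g <- scale_rows(ifelse(bip_g > 0, 1 - lambda, 1), gsum)
  f_dg <- scale_rows(ifelse(dsum > 0, lambda, 1), bip_d)
  f_d <- scale_rows(ifelse(bip_d > 0, 1 - lambda, 1), dsum)

  Wp_G <- Matrix::Diagonal(x = f_g) %*% W_G
  Wp_GD <- Matrix::Diagonal(x = f_gd) %*% W_GD
  Wp_DG <- Matrix::Diagonal(x = f_dg) %*% Matrix::t(W_GD)
  Wp_D <- Matrix::Diagonal(x = f_d) %*% W_D

  M <- rbind(cbind(Wp_G, Wp_GD), cbind(Wp_DG, Wp_D))
  M <- as(as(M, "generalMatrix"), "CsparseMatrix")
  ids <- c(net$genes, net$diseases)
  dimnames(M) <- list(ids, ids)

  rs <- Matrix::rowSums(M)
  bad <- which(abs(rs - 1) > 1e-12)
  if (length(bad) > 0) {
    validate_error(paste0(
      "non-stochastic transition row(s) for: ",
      paste(utils::head(ids[bad], 10), collapse = ", "),
      " (node with no outgoing edges?)"
    ))
  }
  structure(
    list(M = M, lambda = lambda,
         n_genes = length(net$genes), n_diseases = length(net$diseases)),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf(
    "<transition_matrix> %d x %d (%d genes + %d diseases), lambda = %g, %d non-zeros\n",
    nrow(x$M), ncol(x$M), x$n_genes, x$n_diseases, x$lambda, Matrix::nnzero(x$M)
  ))
  invisible(x)
}

#' Dump a transition matrix as an edge probability table
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return A tibble with `from`, `to` and the transition `probability`.
#' @export
as_tibble.transition_matrix <- function(x, ...) {
  m <- as(x$M, "TsparseMatrix")
  ids <- rownames(x$M)
  tibble(
    from = ids[m@i + 1L], to = ids[m@j + 1L], probability = m@x
  ) |>
    dplyr::arrange(.data$from, .data$to)
}
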