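#' Parameters of the random walk with restart on the heterogeneous network
#'
#' Bundles and validates the propagation parameters. The defaults follow
#' common practice for gene-disease prioritization on heterogeneous
#' networks: back-probability `gamma = 0.5`, jumping probability
#' `lambda = 0.6` and subnetwork importance weight `eta = 0.7`.
#'
#' @param gamma Restart (back) probability in (0, 1): at every step the
#'   walker returns to the seed distribution with this probability.
#' @param lambda Jumping probability in (0, 1): probability of crossing
#'   between the gene and disease layers along bipartite links.
#' @param eta Subnetwork importance weight in (0, 1): fraction of initial
#'   probability placed on the seed disease(s) rather than the seed genes.
#' @param tol L1 convergence threshold of the power iteration.
#' @param max_iter Maximum number of iterations.
#' @return An `rwrh_params` list.
#' @export
rwrh_params <- function(gamma = 0.5, lambda = 0.6, eta = 0.7,
                        tol = 1e-10, max_iter = 1000L) {
  stopifnot_scalar_prob(gamma, "gamma")
  stopifnot_scalar_prob(lambda, "lambda")
  stopifnot_scalar_prob(eta, "eta")
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    param_error("`tol` must be a positive number")
  }
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1) {
    param_error("`max_iter` must be a positive integer")
  }
  structure(
    list(gamma = gamma, lambda = lambda, eta = eta,
         tol = tol, max_iter = as.integer(max_iter)),
    class = "rwrh_params"
  )
}

#' Initial probability vector over the heterogeneous network
#'
#' Seed genes (the known associated genes of the disease of interest) share
#' probability `1 - eta` equally; seed diseases (the disease of interest, or
#' a disease class) share `eta` equally. A disease without known genes is
#' seeded with all mass on the disease side, so prioritization still works
#' for diseases with no known molecular basis.
#'
#' @param net A `hetnet`.
#' @param seed_genes Character vector of seed gene ids (may be empty).
#' @param seed_diseases Non-empty character vector of seed disease ids.
#' @param eta Subnetwork importance weight in (0, 1).
#' @return A named numeric vector of length `N` summing to 1, aligned to
#'   the hetnet index (genes first).
#' @export
build_seed_vector <- function(net, seed_genes, seed_diseases, eta = 0.7) {
  stopifnot(inherits(net, "hetnet"))
  stopifnot_scalar_prob(eta, "eta")
  seed_genes <- unique(as.character(seed_genes))
  seed_diseases <- unique(as.character(seed_diseases))
  if (length(seed_diseases) == 0) {
    param_error("`seed_diseases` must be non-empty")
  }
  bad <- c(setdiff(seed_genes, net$genes), setdiff(seed_diseases, net$diseases))
  if (length(bad) > 0) {
    validate_error(paste0(
      "seed id(s) not present in the network: ", paste(bad, collapse = ", ")
    ))
  }
  ids <- c(net$genes, net$diseases)
  p0 <- stats::setNames(numeric(length(ids)), ids)
  if (length(seed_genes) > 0) {
    p0[seed_genes] <- (1 - eta) / length(seed_genes)
    p0[seed_diseases] <- eta / length(seed_diseases)
  } else {
    p0[seed_diseases] <- 1 / length(seed_diseases)
  }
  p0
}

#' Iterate the random walk with restart to its steady state
#'
#' Runs the update \eqn{P^{t+1} = (1-\gamma)\,W'^{\mathsf T} P^t + \gamma P^0}
#' from \eqn{P^0} until the L1 change falls below `tol`. The transpose of the
#' row-stochastic transition matrix acts on the probability vector so that
#' total mass is conserved at every step; the iteration is a contraction
#' with factor `1 - gamma`, so the fixed point is unique and independent of
#' the starting vector.
#'
#' @param tm A `transition_matrix` from [build_transition()].
#' @param p0 Initial probability vector (sums to 1), e.g. from
#'   [build_seed_vector()].
#' @param gamma Restart probability in (0, 1).
#' @param tol L1 convergence threshold.
#' @param max_iter Iteration cap; exceeding it raises a condition of class
#'   `rwrhnet_no_convergence` carrying the last iterate in its `p_last`
#'   field.
#' @param p_start Optional starting vector for the iteration (defaults to
#'   `p0`); the fixed point does not depend on it.
#' @return A list with the steady-state vector `p` (named, sums to 1), the
#'   number of `iterations` used and `converged = TRUE`.
#' @export
rwrh_steady_state <- function(tm, p0, gamma = 0.5, tol = 1e-10,
                              max_iter = 1000L, p_start = NULL) {
  stopifnot(inherits(tm, "transition_matrix"))
  stopifnot_scalar_prob(gamma, "gamma")
  if (abs(sum(p0) - 1) > 1e-9) {
    param_error("`p0` must sum to 1")
  }
  Mt <- Matrix::t(tm$M)
  p <- if (is.null(p_start)) p0 else p_start
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - gamma) * (Mt %*% p)) + gamma * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      names(p) <- rownames(tm$M)
      return(list(p = p, iterations = it, converged = TRUE))
    }
  }
  names(p) <- rownames(tm$M)
  abort(
    sprintf("power iteration did not converge in %d iterations (last L1 change %.3g)",
            max_iter, delta),
    class = "rwrhnet_no_convergence",
    p_last = p, iterations = max_iter
  )
}

#' Rank candidate genes and diseases by steady-state probability
#'
#' Candidates are sorted by decreasing steady-state score; ties are broken
#' lexicographically by id and ranks are 1-based positions within each
#' list. Candidate sets must not overlap the seed sets.
#'
#' @param net A `hetnet`.
#' @param p_inf Steady-state probability vector (named, hetnet-aligned).
#' @param candidate_genes,candidate_diseases Character vectors of candidate
#'   ids (either may be empty).
#' @param seed_genes,seed_diseases Seed ids used only to reject overlapping
#'   candidates.
#' @return A tibble with `id`, `type`, `score` and `rank` (ranked within
#'   each type).
#' @export
rank_candidates <- function(net, p_inf, candidate_genes, candidate_diseases,
                            seed_genes = character(), seed_diseases = character()) {
  stopifnot(inherits(net, "hetnet"))
  candidate_genes <- unique(as.character(candidate_genes))
  candidate_diseases <- unique(as.character(candidate_diseases))
  overlap <- c(
    intersect(candidate_genes, seed_genes),
    intersect(candidate_diseases, seed_diseases)
  )
  if (length(overlap) > 0) {
    validate_error(paste0(
      "candidate set overlaps the seed set: ", paste(overlap, collapse = ", ")
    ))
  }
  bad <- c(setdiff(candidate_genes, net$genes),
           setdiff(candidate_diseases, net$diseases))
  if (length(bad) > 0) {
    validate_error(paste0(
      "candidate id(s) not in the network: ", paste(bad, collapse = ", ")
    ))
  }
  rank_one <- function(ids, type) {
    if (length(ids) == 0) {
      return(tibble(id = character(), type = character(),
                    score = numeric(), rank = integer()))
    }
    tibble(id = ids, type = type, score = unname(p_inf[ids])) |>
      dplyr::arrange(dplyr::desc(.data$score), .data$id) |>
      dplyr::mutate(rank = dplyr::row_number())
  }
  dplyr::bind_rows(
    rank_one(candidate_genes, "gene"),
    rank_one(candidate_diseases, "disease")
  )
}

#' Prioritize candidate genes and diseases for a disease of interest
#'
#' One-call front end: builds the transition matrix, seeds the walk with
#' the disease (or disease class) and its known associated genes from the
#' bipartite layer, iterates to the steady state and ranks the candidates.
#'
#' @param net A `hetnet`.
#' @param diseases Character vector with the disease of interest (or a
#'   disease class of several ids).
#' @param seed_genes Seed gene ids; by default the genes linked to
#'   `diseases` in the bipartite layer. May be empty for diseases without
#'   known molecular basis.
#' @param params An [rwrh_params()] bundle.
#' @param candidate_genes Candidate gene ids; default all non-seed genes.
#' @param candidate_diseases Candidate disease ids; default all non-seed
#'   diseases.
#' @return An `rwrh_result` holding the ranking tibble (`$ranking`), the
#'   full steady-state vector, the seeds and the convergence record. Use
#'   [generics::tidy()] for per-node scores and [generics::glance()] for a
#'   one-row summary.
#' @examples
#' syn <- generate_hetnet(synthetic_spec(
#'   n_genes = 60, n_diseases = 8, n_modules = 4, rng_seed = 7
#' ))
#' fit <- rwrh_rank(syn$net, diseases = "d1")
#' head(fit$ranking)
#' @export
rwrh_rank <- function(net, diseases, seed_genes = NULL,
                      params = rwrh_params(),
                      candidate_genes = NULL, candidate_diseases = NULL) {
  stopifnot(inherits(net, "hetnet"), inherits(params, "rwrh_params"))
  diseases <- unique(as.character(diseases))
  if (is.null(seed_genes)) {
    seed_genes <- known_genes(net, diseases)
  }
  seed_genes <- unique(as.character(seed_genes))
  if (is.null(candidate_genes)) {
    candidate_genes <- setdiff(net$genes, seed_genes)
  }
  if (is.null(candidate_diseases)) {
    candidate_diseases <- setdiff(net$diseases, diseases)
  }
  tm <- build_transition(net, lambda = params$lambda)
  p0 <- build_seed_vector(net, seed_genes, diseases, eta = params$eta)
  ss <- rwrh_steady_state(tm, p0,
    gamma = params$gamma, tol = params$tol, max_iter = params$max_iter
  )
  ranking <- rank_candidates(net, ss$p, candidate_genes, candidate_diseases,
    seed_genes = seed_genes, seed_diseases = diseases
  )
  structure(
    list(
      ranking = ranking, p_inf = ss$p, p0 = p0,
      seed_genes = seed_genes, seed_diseases = diseases,
      params = params, iterations = ss$iterations, converged = ss$converged,
      n_genes = length(net$genes), n_diseases = length(net$diseases)
    ),
    class = "rwrh_result"
  )
}

#' Genes linked to given diseases in the bipartite layer
#'
#' @param net A `hetnet`.
#' @param diseases Character vector of disease ids.
#' @return Sorted character vector of associated gene ids.
#' @export
known_genes <- function(net, diseases) {
  stopifnot(inherits(net, "hetnet"))
  bad <- setdiff(diseases, net$diseases)
  if (length(bad) > 0) {
    validate_error(paste0("unknown disease id(s): ", paste(bad, collapse = ", ")))
  }
  sub <- net$W_GD[, diseases, drop = FALSE]
  sort(net$genes[Matrix::rowSums(sub) > 0])
}

#' @export
print.rwrh_result <- function(x, ...) {
  cat(sprintf(
    "<rwrh_result> disease(s): %s | %d seed genes | converged in %d iterations\n",
    paste(x$seed_diseases, collapse = ", "), length(x$seed_genes), x$iterations
  ))
  top <- x$ranking |> dplyr::filter(.data$type == "gene") |> utils::head(5)
  if (nrow(top) > 0) {
    cat("top candidate genes:\n")
    print(as.data.frame(top), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy the per-node scores of a prioritization
#'
#' @param x An `rwrh_result`.
#' @param ... Unused.
#' @return A tibble with one row per network node: `id`, `type`,
#'   steady-state `score`, `is_seed`, and the candidate `rank` (`NA` for
#'   non-candidates).
#' @export
tidy.rwrh_result <- function(x, ...) {
  tibble(
    id = names(x$p_inf),
    type = rep(c("gene", "disease"), c(x$n_genes, x$n_diseases)),
    score = unname(x$p_inf),
    is_seed = names(x$p_inf) %in% c(x$seed_genes, x$seed_diseases)
  ) |>
    dplyr::left_join(
      x$ranking |> dplyr::select("id", "rank"),
      by = "id"
    ) |>
    dplyr::arrange(.data$type, dplyr::desc(.data$score), .data$id)
}

#' One-row summary of a prioritization run
#'
#' @param x An `rwrh_result`.
#' @param ... Unused.
#' @return A one-row tibble with the parameters, network size and
#'   convergence record.
#' @export
glance.rwrh_result <- function(x, ...) {
  tibble(
    n_genes = x$n_genes, n_diseases = x$n_diseases,
    n_seed_genes = length(x$seed_genes),
    n_seed_diseases = length(x$seed_diseases),
    gamma = x$params$gamma, lambda = x$params$lambda, eta = x$params$eta,
    iterations = x$iterations, converged = x$converged
  )
}

#' Plot the top-ranked candidates of a prioritization
#'
#' @param object An `rwrh_result`.
#' @param top_n Number of candidates per type to show.
#' @param ... Unused.
#' @return A ggplot object: steady-state scores of the top candidates,
#'   faceted by node type.
#' @export
autoplot.rwrh_result <- function(object, top_n = 15, ...) {
  dat <- object$ranking |>
    dplyr::group_by(.data$type) |>
    dplyr::slice_min(.data$rank, n = top_n) |>
    dplyr::ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$id, .data$score)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~type, scales = "free") +
    ggplot2::labs(
      x = "steady-state probability", y = NULL,
      title = "Top-ranked candidates",
      subtitle = sprintf(
        "seeds: %s + %d genes",
        paste(object$seed_diseases, collapse = ","), length(object$seed_genes)
      )
    )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
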