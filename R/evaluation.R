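#' Leave-one-out cross-validation of gene prioritization
#'
#' For every disease with at least `min_known_genes` known genes in the
#' bipartite layer, each known association is removed in turn; the walk is
#' re-seeded with the disease and its remaining known genes, and the rank
#' of the held-out gene is recorded among the candidate universe of all
#' genes outside the remaining seed set. Tied scores receive their average
#' rank. The association is restored before the next trial, so the network
#' is left untouched.
#'
#' @param net A `hetnet`.
#' @param params An [rwrh_params()] bundle.
#' @param min_known_genes Minimum number of known genes for a disease to
#'   enter the evaluation (>= 2, so at least one seed gene remains after
#'   holding one out).
#' @return A `loo_result`: the per-trial tibble (`disease`, `held_out_gene`,
#'   `rank`, `n_candidates`) and the pooled rank-based `auc`.
#' @export
leave_one_out <- function(net, params = rwrh_params(), min_known_genes = 2L) {
  stopifnot(inherits(net, "hetnet"), inherits(params, "rwrh_params"))
  if (min_known_genes < 2) {
    param_error("`min_known_genes` must be >= 2")
  }
  known_per_disease <- Matrix::colSums(net$W_GD > 0)
  qualifying <- net$diseases[known_per_disease >= min_known_genes]
  if (length(qualifying) == 0) {
    validate_error(sprintf(
      "no disease has >= %d known genes", min_known_genes
    ))
  }
  trials <- purrr::map(qualifying, function(d) {
    genes_d <- known_genes(net, d)
    purrr::map(genes_d, function(g) {
      net_loo <- net
      net_loo$W_GD[g, d] <- 0
      net_loo$W_GD <- Matrix::drop0(net_loo$W_GD)
      seeds <- setdiff(genes_d, g)
      candidates <- setdiff(net$genes, seeds)
      tm <- build_transition(net_loo, lambda = params$lambda)
      p0 <- build_seed_vector(net_loo, seeds, d, eta = params$eta)
      ss <- rwrh_steady_state(tm, p0,
        gamma = params$gamma, tol = params$tol, max_iter = params$max_iter
      )
      s <- ss$p[candidates]
      s_g <- s[[g]]
      # average rank across ties, 1-based
      r <- sum(s > s_g) + (sum(s == s_g) + 1) / 2
      list(disease = d, held_out_gene = g, rank = r,
           n_candidates = length(candidates))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  new_loo_result(trials)
}

new_loo_result <- function(trials) {
  structure(
    list(trials = trials, auc = auc_from_ranks(trials)),
    class = "loo_result"
  )
}

#' Rank-based AUC over held-out trials
#'
#' Each trial contributes the fraction of its candidate negatives ranked
#' below the held-out positive, `(n_candidates - rank) / (n_candidates - 1)`;
#' the AUC is the mean over trials. This equals the trapezoidal area under
#' the pooled ROC curve with one positive versus `n - 1` negatives per
#' trial. A degenerate trial with a single candidate contributes 1.
#'
#' @param trials Data frame with columns `rank` (average rank allowed) and
#'   `n_candidates`.
#' @return The AUC in \[0, 1\].
#' @export
auc_from_ranks <- function(trials) {
  trials <- as_tibble(trials)
  if (nrow(trials) == 0) validate_error("no trials to score")
  if (any(trials$rank < 1 | trials$rank > trials$n_candidates)) {
    validate_error("every rank must lie in [1, n_candidates]")
  }
  per_trial <- ifelse(
    trials$n_candidates == 1, 1,
    (trials$n_candidates - trials$rank) / (trials$n_candidates - 1)
  )
  mean(per_trial)
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(
    "<loo_result> %d trials over %d diseases | AUC = %.4f\n",
    nrow(x$trials), dplyr::n_distinct(x$trials$disease), x$auc
  ))
  invisible(x)
}

#' Per-trial table of a leave-one-out evaluation
#'
#' @param x A `loo_result`.
#' @param ... Unused.
#' @return The trial tibble, with the normalized rank
#'   `(rank - 1) / (n_candidates - 1)` added.
#' @export
tidy.loo_result <- function(x, ...) {
  x$trials |>
    dplyr::mutate(
      normalized_rank = ifelse(
        .data$n_candidates == 1, 0,
        (.data$rank - 1) / (.data$n_candidates - 1)
      )
    )
}

#' One-row summary of a leave-one-out evaluation
#'
#' @param x A `loo_result`.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `n_trials`, `n_diseases`,
#'   `median_rank`.
#' @export
glance.loo_result <- function(x, ...) {
  tibble(
    auc = x$auc,
    n_trials = nrow(x$trials),
    n_diseases = dplyr::n_distinct(x$trials$disease),
    median_rank = stats::median(x$trials$rank)
  )
}

#' ROC-style recovery curve of a leave-one-out evaluation
#'
#' Plots the fraction of held-out genes recovered (sensitivity) against
#' the normalized rank threshold (the fraction of candidate negatives
#' accepted), i.e. the pooled ROC curve of the evaluation.
#'
#' @param object A `loo_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loo_result <- function(object, ...) {
  u <- sort(tidy(object)$normalized_rank)
  dat <- tibble(
    fpr = c(0, u, 1),
    tpr = c(0, seq_along(u) / length(u), 1)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "fraction of candidates accepted",
      y = "fraction of held-out genes recovered",
      title = "Leave-one-out recovery",
      subtitle = sprintf("AUC = %.4f over %d trials", object$auc, nrow(object$trials))
    )
}
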