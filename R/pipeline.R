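#' Load the heterogeneous network from its three input files
#'
#' @param gene_network_path Gene/protein network file.
#' @param disease_similarity_path Disease similarity file.
#' @param bipartite_path Disease-gene association file.
#' @param gene_dialect `"tsv"` or `"sif"`.
#' @param similarity_format `"edgelist"` or `"matrix"`.
#' @param k_top Top-k similarity filter size.
#' @return A `hetnet`.
#' @export
load_hetnet <- function(gene_network_path, disease_similarity_path,
                        bipartite_path, gene_dialect = "tsv",
                        similarity_format = "edgelist", k_top = 5) {
  assemble_heterogeneous(
    read_gene_network(gene_network_path, dialect = gene_dialect),
    read_disease_similarity(disease_similarity_path,
      format = similarity_format, k_top = k_top
    ),
    read_bipartite(bipartite_path)
  )
}

#' Rank candidates from input files and write the result tables
#'
#' File-based front end of [rwrh_rank()]: loads the heterogeneous network,
#' prioritizes for the disease(s) of interest, and writes
#' `gene_ranking.tsv` and `disease_ranking.tsv`
#' (`rank<TAB>id<TAB>type<TAB>score<TAB>is_seed`, scores with 10
#' significant digits, seed nodes listed after the candidates with rank 0)
#' plus `manifest.tsv` recording parameters, input checksums and the
#' iteration count.
#'
#' @inheritParams load_hetnet
#' @param diseases Disease id(s) of interest.
#' @param params An [rwrh_params()] bundle.
#' @param candidate_strategy Candidate gene strategy, see
#'   [candidate_genes()].
#' @param gene_annotations_path Optional gene annotation TSV (chromosome
#'   strategies).
#' @param band_spec,user_list Strategy-specific inputs.
#' @param out_dir Output directory.
#' @return The `rwrh_result`, invisibly.
#' @export
run_rank <- function(gene_network_path, disease_similarity_path, bipartite_path,
                     diseases, gene_dialect = "tsv",
                     similarity_format = "edgelist", k_top = 5,
                     params = rwrh_params(),
                     candidate_strategy = "all_non_training",
                     gene_annotations_path = NULL, band_spec = NULL,
                     user_list = NULL, out_dir = ".") {
  net <- load_hetnet(gene_network_path, disease_similarity_path, bipartite_path,
    gene_dialect = gene_dialect, similarity_format = similarity_format,
    k_top = k_top
  )
  seed_genes <- known_genes(net, diseases)
  annotations <- if (!is.null(gene_annotations_path)) {
    read_gene_annotations(gene_annotations_path)
  }
  cand_genes <- candidate_genes(net, seed_genes,
    strategy = candidate_strategy,
    annotations = annotations, band_spec = band_spec, user_list = user_list
  )
  fit <- rwrh_rank(net, diseases,
    seed_genes = seed_genes, params = params,
    candidate_genes = cand_genes
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ranking_file(fit, "gene", file.path(out_dir, "gene_ranking.tsv"))
  write_ranking_file(fit, "disease", file.path(out_dir, "disease_ranking.tsv"))
  write_manifest(
    file.path(out_dir, "manifest.tsv"),
    inputs = c(gene_network_path, disease_similarity_path, bipartite_path),
    values = c(
      diseases = paste(diseases, collapse = ","),
      n_seed_genes = length(seed_genes),
      candidate_strategy = candidate_strategy,
      gamma = fit$params$gamma, lambda = fit$params$lambda,
      eta = fit$params$eta, tol = fit$params$tol,
      k_top = k_top, iterations = fit$iterations
    )
  )
  invisible(fit)
}

#' Leave-one-out evaluation from input files
#'
#' Loads the heterogeneous network, runs [leave_one_out()] and writes
#' `cv_report.tsv` (`disease<TAB>gene<TAB>rank<TAB>n_candidates`, with an
#' AUC summary line as a trailing comment) plus a manifest.
#'
#' @inheritParams run_rank
#' @param min_known_genes Minimum known genes per evaluated disease.
#' @return The `loo_result`, invisibly.
#' @export
run_evaluate <- function(gene_network_path, disease_similarity_path,
                         bipartite_path, gene_dialect = "tsv",
                         similarity_format = "edgelist", k_top = 5,
                         params = rwrh_params(), min_known_genes = 2L,
                         out_dir = ".") {
  net <- load_hetnet(gene_network_path, disease_similarity_path, bipartite_path,
    gene_dialect = gene_dialect, similarity_format = similarity_format,
    k_top = k_top
  )
  res <- leave_one_out(net, params = params, min_known_genes = min_known_genes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(out_dir, "cv_report.tsv")
  utils::write.table(res$trials, report,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  cat(sprintf("# AUC\t%.10g\n", res$auc), file = report, append = TRUE)
  write_manifest(
    file.path(out_dir, "manifest.tsv"),
    inputs = c(gene_network_path, disease_similarity_path, bipartite_path),
    values = c(
      gamma = params$gamma, lambda = params$lambda, eta = params$eta,
      min_known_genes = min_known_genes,
      n_trials = nrow(res$trials), auc = res$auc
    )
  )
  invisible(res)
}

#' Shared-annotation evidence report for a prior ranking
#'
#' Reads `disease_ranking.tsv` from `out_dir` (as written by
#' [run_rank()]), computes the shared-annotation table for the top
#' candidate diseases against the disease of interest, annotates the top
#' candidate genes, and writes `disease_evidence.tsv` and
#' `gene_annotations.tsv`.
#'
#' @param disease_of_interest Disease id the candidates are compared
#'   with.
#' @param disease_genes_path Disease-to-gene TSV.
#' @param pathways_path,complexes_path Optional GMT files.
#' @param do_terms_path Optional disease-to-ontology-term TSV.
#' @param top_n Number of top candidates to report.
#' @param out_dir Directory holding the prior ranking; reports are
#'   written next to it.
#' @return The evidence tibble, invisibly.
#' @export
run_evidence <- function(disease_of_interest, disease_genes_path,
                         pathways_path = NULL, complexes_path = NULL,
                         do_terms_path = NULL, top_n = 20, out_dir = ".") {
  ranking_path <- file.path(out_dir, "disease_ranking.tsv")
  gene_ranking_path <- file.path(out_dir, "gene_ranking.tsv")
  if (!file.exists(ranking_path)) {
    abort(
      paste0(
        "no ranking found at ", ranking_path,
        "; run the rank step (run_rank) first"
      ),
      class = "rwrhnet_file_error"
    )
  }
  ranking <- read_ranking_file(ranking_path)
  disease_genes <- read_membership_tsv(disease_genes_path, kind = "disease_genes")
  pathways <- if (!is.null(pathways_path)) read_gmt(pathways_path, "pathway")
  complexes <- if (!is.null(complexes_path)) read_gmt(complexes_path, "complex")
  do_terms <- if (!is.null(do_terms_path)) {
    read_membership_tsv(do_terms_path, kind = "disease_ontology")
  }
  ev <- evidence_table(ranking, disease_of_interest, disease_genes,
    pathways = pathways, complexes = complexes, do_terms = do_terms,
    top_n = top_n
  )
  utils::write.table(ev, file.path(out_dir, "disease_evidence.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (file.exists(gene_ranking_path) && !is.null(pathways)) {
    gr <- read_ranking_file(gene_ranking_path)
    top_genes <- gr |>
      dplyr::filter(.data$rank >= 1) |>
      dplyr::arrange(.data$rank) |>
      utils::head(top_n)
    utils::write.table(
      annotate_genes(top_genes$id, pathways),
      file.path(out_dir, "gene_annotations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(ev)
}

#' Generate a synthetic data set on disk
#'
#' @param out_dir Output directory.
#' @param spec A [synthetic_spec()].
#' @return The `synthetic_hetnet`, invisibly.
#' @export
run_simulate <- function(out_dir, spec = synthetic_spec()) {
  syn <- generate_hetnet(spec)
  write_synthetic(syn, out_dir)
  invisible(syn)
}

# ---- file helpers -----------------------------------------------------------

# rank<TAB>id<TAB>type<TAB>score<TAB>is_seed; candidates first by rank, then
# seed nodes with rank 0. Scores carry 10 significant digits.
write_ranking_file <- function(fit, type, path) {
  cand <- fit$ranking |> dplyr::filter(.data$type == !!type)
  seeds <- if (type == "gene") fit$seed_genes else fit$seed_diseases
  rows <- dplyr::bind_rows(
    cand |> dplyr::mutate(is_seed = 0L),
    tibble(
      id = seeds, type = type, score = unname(fit$p_inf[seeds]),
      rank = 0L, is_seed = 1L
    )
  )
  lines <- sprintf(
    "%d\t%s\t%s\t%s\t%d",
    rows$rank, rows$id, rows$type,
    formatC(rows$score, digits = 10, format = "g"), rows$is_seed
  )
  writeLines(c("# rank\tid\ttype\tscore\tis_seed", lines), path)
  invisible(path)
}

read_ranking_file <- function(path) {
  rows <- read_clean_lines(path)
  fields <- split_fields(rows$text)
  purrr::map(fields, function(f) {
    list(
      rank = as.integer(f[[1]]), id = f[[2]], type = f[[3]],
      score = as.numeric(f[[4]]), is_seed = as.integer(f[[5]])
    )
  }) |> dplyr::bind_rows()
}

write_manifest <- function(path, inputs, values) {
  sums <- tools::md5sum(inputs)
  lines <- c(
    sprintf("input_md5\t%s\t%s", basename(inputs), unname(sums)),
    sprintf("param\t%s\t%s", names(values), unname(values))
  )
  writeLines(lines, path)
  invisible(path)
}
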