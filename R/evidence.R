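#' Read a GMT gene-set file
#'
#' GMT lines are `term<TAB>description<TAB>member1<TAB>member2...`. Lines
#' with fewer than three fields (i.e. an empty member list) are a parse
#' error; duplicate terms are merged by union.
#'
#' @param path Path to the GMT file.
#' @param kind Label for the map (`"pathway"`, `"complex"`, ...).
#' @return An `annotation_map`: a named list of member-id character
#'   vectors.
#' @export
read_gmt <- function(path, kind = "pathway") {
  rows <- read_clean_lines(path)
  fields <- strsplit(rows$text, "\t", fixed = TRUE)
  out <- list()
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      parse_error(path, rows$line[i], "GMT line needs term, description and >= 1 member")
    }
    term <- f[[1]]
    members <- unique(f[-(1:2)])
    out[[term]] <- sort(unique(c(out[[term]], members)))
  }
  annotation_map(out, kind = kind)
}

#' Read a two-column membership TSV as an annotation map
#'
#' Used for disease-to-ontology-term files (`disease<TAB>term`, kind
#' `"disease_ontology"`) and disease-to-gene files (`disease<TAB>gene`,
#' kind `"disease_genes"`). The first column becomes the map key.
#'
#' @param path Path to the TSV file.
#' @param kind Label for the map.
#' @return An `annotation_map` keyed by the first column.
#' @export
read_membership_tsv <- function(path, kind = "disease_genes") {
  rows <- read_clean_lines(path)
  fields <- split_fields(rows$text)
  out <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 2L) {
      parse_error(path, rows$line[i], sprintf("expected 2 fields, got %d", length(f)))
    }
    out[[f[[1]]]] <- sort(unique(c(out[[f[[1]]]], f[[2]])))
  }
  annotation_map(out, kind = kind)
}

#' Construct an annotation map from a named list
#'
#' @param x Named list mapping a term or disease id to a character vector
#'   of member ids; empty member sets are dropped.
#' @param kind One of `"pathway"`, `"complex"`, `"disease_ontology"`,
#'   `"disease_genes"`.
#' @return An `annotation_map`.
#' @export
annotation_map <- function(x, kind = c("pathway", "complex",
                                       "disease_ontology", "disease_genes")) {
  kind <- match.arg(kind)
  x <- x[lengths(x) > 0]
  if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x))))) {
    param_error("annotation map entries must be named")
  }
  structure(lapply(x, function(v) sort(unique(as.character(v)))),
            class = "annotation_map", kind = kind)
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf(
    "<annotation_map kind=%s> %d terms, %d member ids\n",
    attr(x, "kind"), length(x), length(unique(unlist(x)))
  ))
  invisible(x)
}

map_members <- function(map, key) {
  if (is.null(map) || is.null(map[[key]])) character() else map[[key]]
}

#' Shared-annotation evidence for a disease-disease association
#'
#' Counts annotation overlap between two diseases: shared known genes
#' (intersection of their gene sets), shared pathways and protein
#' complexes (terms containing at least one gene of each disease), and
#' shared disease ontology terms (intersection of their term sets). These
#' are the local evidence columns used to support promising associations
#' between a highly ranked candidate disease and the disease of interest.
#'
#' @param disease_a,disease_b Disease ids.
#' @param disease_genes `annotation_map` of kind `"disease_genes"`.
#' @param pathways,complexes `annotation_map`s of gene sets; `NULL` is
#'   treated as empty with a warning.
#' @param do_terms `annotation_map` of kind `"disease_ontology"`; `NULL`
#'   treated as empty with a warning.
#' @return A one-row tibble: `disease_a`, `disease_b`, `shared_genes`,
#'   `shared_complexes`, `shared_pathways`, `shared_do_terms`.
#' @export
shared_annotation_counts <- function(disease_a, disease_b, disease_genes,
                                     pathways = NULL, complexes = NULL,
                                     do_terms = NULL) {
  missing_maps <- c(
    if (is.null(pathways)) "pathways",
    if (is.null(complexes)) "complexes",
    if (is.null(do_terms)) "do_terms"
  )
  if (length(missing_maps) > 0) {
    warn(paste0(
      "treating missing annotation map(s) as empty: ",
      paste(missing_maps, collapse = ", ")
    ))
  }
  ga <- map_members(disease_genes, disease_a)
  gb <- map_members(disease_genes, disease_b)
  dual_hits <- function(map) {
    if (is.null(map) || length(ga) == 0 || length(gb) == 0) return(0L)
    sum(purrr::map_lgl(map, function(members) {
      any(ga %in% members) && any(gb %in% members)
    }))
  }
  tibble(
    disease_a = disease_a, disease_b = disease_b,
    shared_genes = length(intersect(ga, gb)),
    shared_complexes = dual_hits(complexes),
    shared_pathways = dual_hits(pathways),
    shared_do_terms = length(intersect(
      map_members(do_terms, disease_a), map_members(do_terms, disease_b)
    ))
  )
}

#' Shared-annotation evidence table for top-ranked candidate diseases
#'
#' For each of the `top_n` highest-ranked candidate diseases, counts the
#' annotations shared with the disease of interest.
#'
#' @param ranking Ranking tibble (`id`, `type`, `score`, `rank`) as
#'   produced by [rwrh_rank()]/[rank_candidates()].
#' @param disease_of_interest Disease id the candidates are compared with.
#' @param top_n Number of top-ranked candidate diseases to report.
#' @inheritParams shared_annotation_counts
#' @return A tibble with one row per reported disease: rank, id, score and
#'   the four shared-annotation counts.
#' @export
evidence_table <- function(ranking, disease_of_interest, disease_genes,
                           pathways = NULL, complexes = NULL, do_terms = NULL,
                           top_n = 20) {
  top <- ranking |>
    dplyr::filter(.data$type == "disease") |>
    dplyr::arrange(.data$rank) |>
    utils::head(top_n)
  counts <- purrr::map(top$id, function(d) {
    suppressWarnings(shared_annotation_counts(
      disease_of_interest, d, disease_genes,
      pathways = pathways, complexes = complexes, do_terms = do_terms
    ))
  })
  if (length(counts) == 0) {
    return(tibble(
      rank = integer(), disease = character(), score = numeric(),
      shared_genes = integer(), shared_complexes = integer(),
      shared_pathways = integer(), shared_do_terms = integer()
    ))
  }
  dplyr::bind_cols(
    top |> dplyr::select(rank = "rank", disease = "id", score = "score"),
    dplyr::bind_rows(counts) |>
      dplyr::select("shared_genes", "shared_complexes",
                    "shared_pathways", "shared_do_terms")
  )
}

#' Annotate genes with the terms that contain them
#'
#' @param genes Character vector of gene ids.
#' @param map An `annotation_map` of gene sets (pathways or complexes).
#' @return A tibble with `gene`, `n_terms` and a `;`-separated `terms`
#'   column.
#' @export
annotate_genes <- function(genes, map) {
  purrr::map(genes, function(g) {
    hit <- names(map)[purrr::map_lgl(map, function(members) g %in% members)]
    list(gene = g, n_terms = length(hit), terms = paste(hit, collapse = ";"))
  }) |>
    dplyr::bind_rows()
}
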