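#' Read gene chromosome/band annotations
#'
#' Lines are `gene_id<TAB>chromosome<TAB>band`. One record per gene; later
#' duplicates are ignored with a warning. Unannotated genes are simply
#' absent and are excluded from chromosome-based candidate strategies.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `gene_id`, `chromosome`, `band`.
#' @export
read_gene_annotations <- function(path) {
  rows <- read_clean_lines(path)
  fields <- split_fields(rows$text)
  recs <- purrr::map2(fields, rows$line, function(f, ln) {
    if (length(f) != 3L) {
      parse_error(path, ln, sprintf("expected 3 fields, got %d", length(f)))
    }
    list(gene_id = f[[1]], chromosome = f[[2]], band = f[[3]])
  })
  ann <- dplyr::bind_rows(recs)
  if (anyDuplicated(ann$gene_id)) {
    warn("duplicate gene annotation records; keeping the first of each")
    ann <- ann |> dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  }
  ann
}

#' Construct a candidate gene set
#'
#' Builds the set of genes eligible for ranking, by one of the strategies
#' used for disease-gene prioritization: all non-training genes, direct
#' network neighbours of the training genes, neighbours restricted to
#' chromosomes carrying a training gene, all genes on a given chromosome
#' band, or a free user list. Every strategy excludes the seed genes.
#'
#' @param net A `hetnet`.
#' @param seed_genes Training gene ids.
#' @param strategy One of `"all_non_training"`, `"neighbors"`,
#'   `"neighbors_same_chromosome"`, `"chromosome_band"`, `"user_list"`.
#' @param annotations Gene annotation tibble from
#'   [read_gene_annotations()]; required by the chromosome strategies.
#' @param band_spec Band of interest as `"chromosome:band"` (e.g.
#'   `"17:q21"`); required by `"chromosome_band"`.
#' @param user_list Character vector of gene ids; required by
#'   `"user_list"`.
#' @return Sorted character vector of candidate gene ids.
#' @export
candidate_genes <- function(net, seed_genes,
                            strategy = c("all_non_training", "neighbors",
                                         "neighbors_same_chromosome",
                                         "chromosome_band", "user_list"),
                            annotations = NULL, band_spec = NULL,
                            user_list = NULL) {
  stopifnot(inherits(net, "hetnet"))
  strategy <- match.arg(strategy)
  seed_genes <- unique(as.character(seed_genes))
  need <- function(what, arg) {
    if (is.null(what)) {
      param_error(sprintf("strategy '%s' requires `%s`", strategy, arg))
    }
  }
  cand <- switch(strategy,
    all_non_training = setdiff(net$genes, seed_genes),
    neighbors = seed_neighbors(net, seed_genes),
    neighbors_same_chromosome = {
      need(annotations, "annotations")
      nb <- seed_neighbors(net, seed_genes)
      seed_chr <- annotations$chromosome[annotations$gene_id %in% seed_genes]
      same_chr <- annotations$gene_id[annotations$chromosome %in% seed_chr]
      intersect(nb, same_chr)
    },
    chromosome_band = {
      need(annotations, "annotations")
      need(band_spec, "band_spec")
      parts <- strsplit(band_spec, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        param_error("`band_spec` must be 'chromosome:band', e.g. '17:q21'")
      }
      hit <- annotations$gene_id[
        annotations$chromosome == parts[[1]] & annotations$band == parts[[2]]
      ]
      setdiff(intersect(hit, net$genes), seed_genes)
    },
    user_list = {
      need(user_list, "user_list")
      setdiff(intersect(unique(as.character(user_list)), net$genes), seed_genes)
    }
  )
  sort(cand)
}

seed_neighbors <- function(net, seed_genes) {
  present <- intersect(seed_genes, net$genes)
  if (length(present) == 0) return(character())
  sub <- net$W_G[present, , drop = FALSE]
  setdiff(net$genes[Matrix::colSums(sub) > 0], seed_genes)
}

#' Construct the candidate disease set
#'
#' All diseases in the similarity network except the training diseases.
#'
#' @param net A `hetnet`.
#' @param seed_diseases Training disease ids.
#' @return Sorted character vector of candidate disease ids.
#' @export
candidate_diseases <- function(net, seed_diseases) {
  stopifnot(inherits(net, "hetnet"))
  bad <- setdiff(seed_diseases, net$diseases)
  if (length(bad) > 0) {
    validate_error(paste0("unknown disease id(s): ", paste(bad, collapse = ", ")))
  }
  sort(setdiff(net$diseases, seed_diseases))
}
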