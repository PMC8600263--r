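## Crosstalk decomposition.
##
## Two pathways P_i, P_j that share genes are factored into three candidate
## features: the shared set P_i ∩ P_j and the two pathway-specific
## remainders P_i − (P_i ∩ P_j) and P_j − (P_i ∩ P_j). A pair is retained
## only when the intersection holds at least `min_overlap` genes (default
## 3); empty set differences are omitted. Scoring these sub-pathways as
## features of their own removes the double counting that shared genes
## would otherwise inject into pathway activity scores.

#' Decompose one pathway pair into crosstalk sub-pathways
#'
#' @param genes_i,genes_j gene sets of the two pathways (non-empty).
#' @param id_i,id_j their pathway ids (distinct).
#' @param min_overlap minimum intersection size to retain the pair.
#' @return list of sub-pathway records (`feature_id`, `kind` one of
#'   "intersection"/"i_specific"/"j_specific", `parents`, `genes`);
#'   empty list when the overlap is below `min_overlap`.
#' @export
decompose_pair <- function(genes_i, genes_j, id_i = "Pi", id_j = "Pj",
                           min_overlap = 3) {
  stopifnot(length(genes_i) > 0, length(genes_j) > 0, id_i != id_j)
  inter <- intersect(genes_i, genes_j)
  if (length(inter) < min_overlap) return(list())
  # deterministic ids: pair sorted lexicographically
  ord <- order(c(id_i, id_j))
  a <- c(id_i, id_j)[ord[1]]
  b <- c(id_i, id_j)[ord[2]]
  base <- paste0(a, "|", b)
  out <- list(list(feature_id = paste0(base, "|inter"), kind = "intersection",
                   parents = c(id_i, id_j), genes = sort(inter)))
  only_i <- setdiff(genes_i, inter)
  if (length(only_i) > 0) {
    out <- c(out, list(list(feature_id = paste0(base, "|", id_i, ".spec"),
                            kind = "i_specific", parents = c(id_i, id_j),
                            genes = sort(only_i))))
  }
  only_j <- setdiff(genes_j, inter)
  if (length(only_j) > 0) {
    out <- c(out, list(list(feature_id = paste0(base, "|", id_j, ".spec"),
                            kind = "j_specific", parents = c(id_i, id_j),
                            genes = sort(only_j))))
  }
  out
}

#' Extend a screened pathway collection with crosstalk sub-pathways
#'
#' Returns every original pathway (kind "original") plus the crosstalk
#' decomposition of every unordered pathway pair whose intersection meets
#' `min_overlap`. Sub-pathways with identical gene sets (arising from
#' different pairs, or coinciding with an original pathway) are collapsed
#' to a single feature with merged provenance, so the downstream feature
#' matrix carries no perfectly collinear duplicate rows.
#'
#' @param collection named list of gene id vectors (the post-screening
#'   pathway list).
#' @param min_overlap minimum intersection size to retain a pair.
#' @return list of sub-pathway records; the `merged` attribute maps each
#'   kept feature id to any ids collapsed into it.
#' @export
build_crosstalk_features <- function(collection, min_overlap = 3) {
  stopifnot(!is.null(names(collection)))
  ids <- names(collection)
  feats <- lapply(ids, function(id) {
    list(feature_id = id, kind = "original", parents = id,
         genes = sort(unique(collection[[id]])))
  })
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        feats <- c(feats, decompose_pair(collection[[i]], collection[[j]],
                                         ids[i], ids[j], min_overlap))
      }
    }
  }
  # collapse identical gene sets: originals take precedence, then first id
  keys <- vapply(feats, function(f) paste(f$genes, collapse = "\r"), character(1))
  merged <- list()
  keep <- !duplicated(keys)  # originals listed first, so they win
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    merged[[feats[[idx[1]]]$feature_id]] <-
      vapply(feats[idx[-1]], `[[`, character(1), "feature_id")
    feats[[idx[1]]]$parents <-
      unique(unlist(lapply(feats[idx], `[[`, "parents")))
  }
  out <- feats[keep]
  attr(out, "merged") <- merged
  out
}

#' Convert sub-pathway records to a scorable gene-set collection
#'
#' Provenance (kind and parent pathways) is carried in the description
#' attribute, so the collection serializes to GMT via [write_gmt()] and is
#' consumed unchanged by [compute_pas_matrix()].
#'
#' @param subpathways list from [build_crosstalk_features()] or
#'   [decompose_pair()].
#' @return named list of gene vectors with a `description` attribute.
#' @export
subpathways_to_collection <- function(subpathways) {
  sets <- lapply(subpathways, `[[`, "genes")
  names(sets) <- vapply(subpathways, `[[`, character(1), "feature_id")
  attr(sets, "description") <- setNames(
    vapply(subpathways, function(f) {
      paste0(f$kind, ":", paste(f$parents, collapse = ","))
    }, character(1)), names(sets))
  sets
}
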