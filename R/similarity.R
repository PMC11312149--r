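#' Spearman similarity of samples to reference clusters over marker panels
#'
#' For each (sample, cluster) pair, computes the Spearman correlation
#' between the reference cluster's expression (e.g. CPM) and the query
#' sample's expression (e.g. TPM) over the cluster's marker panel,
#' after mapping reference gene ids to query ids through the ortholog
#' map and log10(x + 1)-transforming both profiles (the pseudo-count
#' admits zeros and, being monotone, leaves the rank correlation
#' unchanged). Ties get average ranks. Clusters with fewer than
#' `min_markers` mapped markers present in both matrices yield `NA`.
#'
#' @param ref_profile numeric matrix, clusters x reference genes.
#' @param query_profile numeric matrix, samples x query genes.
#' @param panel named list: cluster -> character vector of reference
#'   marker gene ids (e.g. the top TF markers).
#' @param ortholog_map data.frame with columns `ref_id`, `query_id`;
#'   unmapped markers are dropped and counted.
#' @param min_markers minimum usable markers per cluster (default 3).
#' @return numeric matrix, samples x clusters, of Spearman rho; the
#'   number of dropped (unmapped or absent) markers per cluster is
#'   attached as attribute `"dropped"`.
#' @export
cluster_correlation <- function(ref_profile, query_profile, panel,
                                ortholog_map, min_markers = 3L) {
  if (!length(panel)) stop("empty marker panel")
  clusters <- names(panel)
  miss <- setdiff(clusters, rownames(ref_profile))
  if (length(miss)) stop("cluster(s) missing from ref_profile: ",
                         paste(miss, collapse = ", "))
  samples <- rownames(query_profile)
  out <- matrix(NA_real_, length(samples), length(clusters),
                dimnames = list(samples, clusters))
  dropped <- integer(length(clusters)); names(dropped) <- clusters
  for (cl in clusters) {
    mk <- unique(panel[[cl]])
    q_id <- ortholog_map$query_id[match(mk, ortholog_map$ref_id)]
    ok <- !is.na(q_id) & mk %in% colnames(ref_profile) &
      q_id %in% colnames(query_profile)
    dropped[cl] <- sum(!ok)
    if (sum(ok) < min_markers) next
    rv <- log10(ref_profile[cl, mk[ok]] + 1)
    qm <- log10(query_profile[, q_id[ok], drop = FALSE] + 1)
    out[, cl] <- apply(qm, 1L, function(qv)
      stats::cor(rv, qv, method = "spearman"))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Marker concordance counts
#'
#' Per-cluster count (and fraction) of panel markers whose query
#' expression exceeds a threshold — the fallback similarity measure when
#' reference cluster profiles are unavailable.
#'
#' @param panel named list: cluster -> reference marker ids.
#' @param query_tpm named numeric vector of query expression.
#' @param ortholog_map data.frame with columns `ref_id`, `query_id`.
#' @param threshold expression cutoff (default 5, strict `>`).
#' @return data.frame with columns `cluster`, `n_markers` (mapped),
#'   `n_expressed`, `fraction`.
#' @export
marker_concordance <- function(panel, query_tpm, ortholog_map,
                               threshold = 5) {
  if (!length(panel)) stop("empty marker panel")
  rows <- lapply(names(panel), function(cl) {
    mk <- unique(panel[[cl]])
    q_id <- ortholog_map$query_id[match(mk, ortholog_map$ref_id)]
    q_id <- q_id[!is.na(q_id) & q_id %in% names(query_tpm)]
    n_exp <- sum(query_tpm[q_id] > threshold)
    data.frame(cluster = cl, n_markers = length(q_id),
               n_expressed = n_exp,
               fraction = if (length(q_id)) n_exp / length(q_id)
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
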