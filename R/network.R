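#' Classify TF ChIP-Seq peaks by binding change
#'
#' Computes the log2 fold change of the condition-B normalized counts
#' over the condition-A normalized counts for each peak and classifies
#' it as Enriched (`log2FC >= 1`), Depleted (`log2FC <= -1`) or Equal
#' (`|log2FC| < 1`); both outer bounds are inclusive, as printed.
#' Input-subtracted counts may dip below zero; they are floored at 0 and
#' a pseudocount is added before the log ratio.
#'
#' @param count_a,count_b numeric vectors of input-subtracted,
#'   library-normalized counts in conditions A and B (e.g. AFE and PE).
#' @param pseudocount added to both counts after flooring (default 1).
#' @return data.frame with columns `log2fc` and `category` (factor
#'   Enriched/Equal/Depleted).
#' @export
classify_rara_peaks <- function(count_a, count_b, pseudocount = 1) {
  stopifnot(length(count_a) == length(count_b))
  a <- pmax(count_a, 0) + pseudocount
  b <- pmax(count_b, 0) + pseudocount
  lfc <- log2(b / a)
  cat_ <- ifelse(lfc >= 1, "Enriched",
                 ifelse(lfc <= -1, "Depleted", "Equal"))
  data.frame(log2fc = lfc,
             category = factor(cat_, levels = c("Enriched", "Equal",
                                                "Depleted")))
}

#' TFs directly targeted by a ChIP-Seq-profiled factor
#'
#' A TF qualifies as a direct target when it is the nearest
#' protein-coding gene (no distance cap, ties by smallest `gene_id`) of
#' at least one binding peak called in the target condition and its gene
#' is upregulated in the given contrast.
#'
#' @param peaks data.frame of peaks called in the target condition, with
#'   `chrom`, `start`, `end`.
#' @param genes gene table with `gene_id`, `chrom`, `tss`, `is_tf` and a
#'   `de_<contrast>` column.
#' @param contrast contrast whose `up` status qualifies a target.
#' @return character vector of TF gene ids.
#' @export
identify_direct_targets <- function(peaks, genes, contrast) {
  de_col <- paste0("de_", contrast)
  if (!de_col %in% names(genes))
    stop("gene table has no column ", de_col)
  no_genes <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(no_genes)) {
    warning("no genes on chromosome(s) ",
            paste(no_genes, collapse = ", "), "; peak(s) skipped")
    peaks <- peaks[!peaks$chrom %in% no_genes, , drop = FALSE]
  }
  nn <- nearest_tss(peaks[, c("chrom", "start", "end")], genes,
                    max_dist = Inf)
  hit <- unique(nn$gene_id[!is.na(nn$gene_id)])
  g <- genes[match(hit, genes$gene_id), ]
  sort(g$gene_id[g$is_tf & g[[de_col]] == "up"])
}

#' Distances of footprint-bearing Gain peaks to TF gene TSSs
#'
#' For each (source TF, target TF) pair, finds the minimum gap between a
#' Gain peak containing a footprint of the source TF's motif and the TSS
#' of the target TF gene (0 when the TSS lies inside the peak). Pairs
#' with no footprint-bearing peak on the target's chromosome are absent
#' from the result.
#'
#' @param footprints data.frame with `chrom`, `start`, `end`, `tf`.
#' @param gain_peaks data.frame with `chrom`, `start`, `end`.
#' @param tf_genes data.frame with `gene_id`, `chrom`, `tss` for the TF
#'   genes acting as targets.
#' @return data.frame with columns `source`, `target`, `distance`.
#' @export
mediating_peak_distances <- function(footprints, gain_peaks, tf_genes) {
  # footprint fully inside a Gain peak
  fp_peak <- integer(0); fp_row <- integer(0)
  for (i in seq_len(nrow(footprints))) {
    hit <- which(gain_peaks$chrom == footprints$chrom[i] &
                   gain_peaks$start <= footprints$start[i] &
                   gain_peaks$end >= footprints$end[i])
    if (length(hit)) {
      fp_peak <- c(fp_peak, hit)
      fp_row <- c(fp_row, rep(i, length(hit)))
    }
  }
  if (!length(fp_peak))
    return(data.frame(source = character(0), target = character(0),
                      distance = numeric(0)))
  src <- footprints$tf[fp_row]
  res <- list(); k <- 0L
  for (s in unique(src)) {
    pk <- unique(fp_peak[src == s])
    ps <- gain_peaks$start[pk]; pe <- gain_peaks$end[pk]
    pc <- gain_peaks$chrom[pk]
    for (j in seq_len(nrow(tf_genes))) {
      same <- pc == tf_genes$chrom[j]
      if (!any(same)) next
      tss <- tf_genes$tss[j]
      d <- ifelse(tss >= ps[same] & tss < pe[same], 0,
                  ifelse(tss < ps[same], ps[same] - tss,
                         tss - pe[same] + 1))
      k <- k + 1L
      res[[k]] <- data.frame(source = s, target = tf_genes$gene_id[j],
                             distance = min(d),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Assemble the condition-specific TF-TF activation network
#'
#' Filters a differential regulatory-network edge table down to the
#' edges supported by the full chain: differential score > `score_min`;
#' both TFs expressed in the target condition (TPM > `tpm_min`); both
#' TFs satisfying at least one of three activity criteria (integrated
#' activity call, footprint enrichment in a Gain-peak class, or top-k
#' influence rank); and at least one mediating Gain peak carrying a
#' source-TF footprint within `dist_network` of the target TSS
#' (strict `<`). Edges whose minimum mediating distance is below
#' `dist_display` are additionally flagged for display, so the displayed
#' edges are a subset of the network.
#'
#' @param edges data.frame with columns `source`, `target`, `score`.
#' @param tpm named numeric: TF -> mean TPM in the target condition.
#' @param criteria data.frame with columns `tf`, `active_integrated`,
#'   `fp_gain_enriched`, `top_influence` (logical); every TF on an edge
#'   must appear.
#' @param med_dist data.frame from [mediating_peak_distances()].
#' @param score_min,tpm_min,dist_network,dist_display thresholds
#'   (0.7, 5, 50000, 25000).
#' @return object of class `tf_network`: list with `edges` (kept edges
#'   with `distance` and `display` columns) and `nodes` (TFs incident to
#'   a kept edge).
#' @export
build_network <- function(edges, tpm, criteria, med_dist,
                          score_min = 0.7, tpm_min = 5,
                          dist_network = 50000, dist_display = 25000) {
  tfs <- unique(c(edges$source, edges$target))
  miss <- setdiff(tfs, names(tpm))
  if (length(miss)) stop("TF(s) without TPM annotation: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(tfs, criteria$tf)
  if (length(miss)) stop("TF(s) without activity-criteria annotation: ",
                         paste(miss, collapse = ", "))
  crit_any <- criteria$active_integrated | criteria$fp_gain_enriched |
    criteria$top_influence
  names(crit_any) <- criteria$tf
  key <- paste(edges$source, edges$target, sep = "\r")
  mkey <- paste(med_dist$source, med_dist$target, sep = "\r")
  dist <- med_dist$distance[match(key, mkey)]
  keep <- edges$score > score_min &
    tpm[edges$source] > tpm_min & tpm[edges$target] > tpm_min &
    crit_any[edges$source] & crit_any[edges$target] &
    !is.na(dist) & dist < dist_network
  kept <- edges[keep, , drop = FALSE]
  kept$distance <- dist[keep]
  kept$display <- kept$distance < dist_display
  rownames(kept) <- NULL
  structure(list(edges = kept,
                 nodes = sort(unique(c(kept$source, kept$target)))),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat("tf_network:", length(x$nodes), "TFs,", nrow(x$edges),
      "edges (", sum(x$edges$display), "display )\n")
  invisible(x)
}

#' Categorize network TFs by responsiveness to the inducing signal
#'
#' Partitions TFs into direct targets of the profiled receptor
#' (`RARA_direct_target`: in `direct_targets` and upregulated in the
#' expanded contrast), signal-responsive TFs (`RA_responsive`:
#' upregulated but not direct targets) and non-responsive TFs
#' (`RA_non_responsive`). `forced` adds or overrides nodes with a fixed
#' category (configuration entries, e.g. a target known from external
#' evidence).
#'
#' @param tfs character vector of network TF ids.
#' @param direct_targets TFs from [identify_direct_targets()].
#' @param up_expanded TFs upregulated in the expanded contrast.
#' @param forced optional named character vector: TF -> category.
#' @return named factor of categories over `union(tfs, names(forced))`.
#' @export
categorize_ra_response <- function(tfs, direct_targets, up_expanded,
                                   forced = NULL) {
  all_tfs <- union(tfs, names(forced))
  up <- all_tfs %in% up_expanded
  cat_ <- ifelse(all_tfs %in% direct_targets & up, "RARA_direct_target",
                 ifelse(up, "RA_responsive", "RA_non_responsive"))
  names(cat_) <- all_tfs
  if (!is.null(forced)) cat_[names(forced)] <- forced
  factor(cat_, levels = c("RARA_direct_target", "RA_responsive",
                          "RA_non_responsive"))
}

#' Export a TF network to GraphML
#'
#' Writes the network as GraphML with edge attributes (score, mediating
#' distance, display flag) and optional node attributes (log2FC and
#' signal-response category).
#'
#' @param net a [build_network()] result.
#' @param path output file path.
#' @param node_attrs optional data.frame with column `tf` plus attribute
#'   columns.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, node_attrs = NULL) {
  g <- as_tf_igraph(net, node_attrs)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
as_tf_igraph <- function(net, node_attrs = NULL) {
  stopifnot(inherits(net, "tf_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  if (!is.null(node_attrs)) {
    m <- match(net$nodes, node_attrs$tf)
    for (cc in setdiff(names(node_attrs), "tf")) {
      val <- node_attrs[[cc]][m]
      if (is.factor(val)) val <- as.character(val)
      g <- igraph::set_vertex_attr(g, cc, value = val)
    }
  }
  g
}
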