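#' Read a gene table
#'
#' Reads a tab-separated gene table with header columns `gene_id`,
#' `chrom`, `tss`, `strand`, one `tpm_<condition>` column per condition,
#' one `de_<contrast>` column per contrast (values `up`, `down`, `no`)
#' and a logical `is_tf` column.
#'
#' @param path path to the file (plain or gzip).
#' @return data.frame of gene records.
#' @export
read_genes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  tpm_cols <- grep("^tpm_", names(x), value = TRUE)
  if (any(unlist(x[tpm_cols]) < 0)) stop("negative TPM value")
  de_cols <- grep("^de_", names(x), value = TRUE)
  for (dc in de_cols) {
    bad <- setdiff(unique(x[[dc]]), c("up", "down", "no"))
    if (length(bad)) stop("invalid DE status in ", dc, ": ",
                          paste(bad, collapse = ", "))
  }
  if ("is_tf" %in% names(x)) x$is_tf <- as.logical(x$is_tf)
  x
}

#' Nearest expressed gene TSS for query intervals
#'
#' For each query interval, finds the nearest gene among those expressed
#' (`TPM > min_tpm`) in at least one of the two conditions, measuring the
#' distance from the interval to the TSS point: 0 when the TSS lies inside
#' `[start, end)`, otherwise the gap to the nearest covered base. Genes
#' farther than `max_dist` (inclusive cutoff) yield no assignment. Ties
#' are broken by the lexicographically smallest `gene_id`, making the
#' assignment deterministic. Strand is ignored: the TSS is a point.
#'
#' @param query data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes gene table with `gene_id`, `chrom`, `tss` and
#'   `tpm_<condition>` columns.
#' @param conditions character vector of the two condition labels whose
#'   `tpm_` columns define expression.
#' @param max_dist maximum TSS distance in bp (default 50000, inclusive).
#' @param min_tpm expression threshold (default 1, strict `>`).
#' @return data.frame with columns `gene_id` (NA when no gene qualifies)
#'   and `distance`.
#' @export
nearest_expressed_tss <- function(query, genes, conditions,
                                  max_dist = 50000, min_tpm = 1) {
  tpm_cols <- paste0("tpm_", conditions)
  miss <- setdiff(tpm_cols, names(genes))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  expressed <- Reduce(`|`, lapply(tpm_cols, function(cc) genes[[cc]] > min_tpm))
  cand <- genes[expressed, c("gene_id", "chrom", "tss")]
  nearest_tss(query, cand, max_dist = max_dist)
}

#' Nearest TSS for query intervals (no expression filter)
#'
#' Workhorse behind [nearest_expressed_tss()]: nearest gene TSS per query
#' interval with interval-to-point gap distance, inclusive `max_dist`
#' cutoff and lexicographic tie-break on `gene_id`.
#'
#' @param query data.frame with `chrom`, `start`, `end`.
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param max_dist maximum distance (default `Inf`).
#' @return data.frame with columns `gene_id` and `distance`.
#' @export
nearest_tss <- function(query, genes, max_dist = Inf) {
  n <- nrow(query)
  out_id <- rep(NA_character_, n)
  out_d <- rep(NA_real_, n)
  if (nrow(genes) == 0L)
    return(data.frame(gene_id = out_id, distance = out_d))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    # one representative (smallest id) per distinct TSS position
    rep1 <- !duplicated(g$tss)
    pos <- g$tss[rep1]
    id <- g$gene_id[rep1]
    qs <- query$start[qi]; qe <- query$end[qi]
    hi <- findInterval(qe - 1, pos)        # last TSS <= end-1
    lo <- findInterval(qs - 1, pos) + 1L   # first TSS >= start
    iL <- lo - 1L                          # last TSS < start
    inside <- hi >= lo
    dL <- ifelse(iL >= 1L, qs - pos[pmax(iL, 1L)], Inf)
    iR <- hi + 1L
    dR <- ifelse(iR <= length(pos), pos[pmin(iR, length(pos))] - qe + 1, Inf)
    idL <- ifelse(iL >= 1L, id[pmax(iL, 1L)], NA_character_)
    idR <- ifelse(iR <= length(pos), id[pmin(iR, length(pos))],
                  NA_character_)
    d <- pmin(ifelse(inside, 0, Inf), dL, dR)
    pick <- ifelse(inside, id[pmax(lo, 1L)],
                   ifelse(dL < dR, idL,
                          ifelse(dR < dL, idR, pmin(idL, idR))))
    # several distinct TSS positions inside one query: min id among them
    multi <- which(inside & hi > lo)
    for (j in multi) pick[j] <- min(id[lo[j]:hi[j]])
    ok <- is.finite(d) & d <= max_dist
    out_id[qi[ok]] <- pick[ok]
    out_d[qi[ok]] <- d[ok]
  }
  data.frame(gene_id = out_id, distance = out_d,
             stringsAsFactors = FALSE)
}
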