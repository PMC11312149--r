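#' Center log2 mean accessibility across conditions
#'
#' Prepares the region x condition matrix of mean normalized
#' accessibility for differential motif enrichment: each value is
#' log2-transformed and the per-region mean of the log2 values across
#' conditions is subtracted, so every row of the result sums to zero.
#'
#' @param mean_counts numeric matrix, regions x conditions, of
#'   library-normalized mean counts (must be > 0).
#' @return centered log2 matrix of the same shape.
#' @examples
#' prepare_scaled_accessibility(matrix(c(4, 8, 16), 1))
#' @export
prepare_scaled_accessibility <- function(mean_counts) {
  m <- as.matrix(mean_counts)
  if (any(m <= 0)) stop("mean counts must be positive")
  l <- log2(m)
  l - rowMeans(l)
}

#' Footprint enrichment scores per condition
#'
#' Converts footprint-enrichment adjusted p-values to
#' `-log10(adjusted p)` after flooring zeros at `floor` to avoid
#' infinities, then averages the transformed values over the DAR sets
#' assigned to each condition, yielding one footprint (FP) enrichment
#' score per motif and condition. A motif absent from (untested in) a
#' DAR set contributes p = 1, i.e. a score of 0, to that set's average.
#'
#' @param fp_padj numeric matrix, motifs x DAR sets, of adjusted
#'   p-values; `NA` marks a motif untested in a set.
#' @param condition_map named character vector mapping each DAR-set
#'   column to a condition.
#' @param floor replacement for zero p-values (default 1e-16).
#' @return numeric matrix, motifs x conditions.
#' @export
fp_enrichment_scores <- function(fp_padj, condition_map, floor = 1e-16) {
  m <- as.matrix(fp_padj)
  unmapped <- setdiff(colnames(m), names(condition_map))
  if (length(unmapped))
    stop("DAR set(s) not mapped to a condition: ",
         paste(unmapped, collapse = ", "))
  p <- m
  p[is.na(p)] <- 1
  if (any(p < 0 | p > 1)) stop("adjusted p-values must lie in [0, 1]")
  s <- -log10(pmax(p, floor))
  conds <- unique(unname(condition_map[colnames(m)]))
  out <- sapply(conds, function(cc) {
    cols <- colnames(m)[condition_map[colnames(m)] == cc]
    rowMeans(s[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), conds))
  out
}

#' Expression Z-scores along conditions
#'
#' Standardizes log2-transformed mean TPM values across conditions for
#' each TF: `z = (log2(tpm) - mean) / sd`, with the population standard
#' deviation (the conditions are the whole population). A constant row
#' yields a row of zeros. No pseudocount is used by default because
#' rows are expected to have passed an expression filter; zero TPMs are
#' rejected unless `pseudocount > 0`.
#'
#' @param tpm numeric matrix, TFs x conditions, of mean TPM (>= 2
#'   columns).
#' @param pseudocount added before log2 (default 0).
#' @return matrix of Z-scores, same shape; every row mean is 0.
#' @export
expression_zscores <- function(tpm, pseudocount = 0) {
  m <- as.matrix(tpm)
  if (ncol(m) < 2L) stop("need >= 2 conditions")
  if (any(m < 0)) stop("negative TPM")
  if (any(m + pseudocount <= 0))
    stop("zero TPM with no pseudocount; filter rows or set pseudocount")
  l <- log2(m + pseudocount)
  mu <- rowMeans(l)
  sdp <- sqrt(rowMeans((l - mu)^2)) # population sd (ddof 0)
  z <- (l - mu) / ifelse(sdp == 0, Inf, sdp)
  z
}

#' Integrated selection of cell-type-specific active TF motifs
#'
#' Joins motif enrichment Z-scores, footprint enrichment and TF
#' expression into per-(motif, TF) activity calls. A row is selected iff
#' all of: (1) absolute motif Z-score >= `z_abs` in at least one
#' condition; (2) footprint-enrichment adjusted p < `fp_alpha` in at
#' least one DAR set; (3) TF mean TPM > `tpm_min` in at least one
#' condition; (4) the TF gene is differentially expressed in at least
#' one contrast; (5) the motif Z-score profile correlates positively
#' (Pearson r > `r_min`) with both the FP enrichment scores and the
#' expression Z-scores across conditions. An undefined correlation
#' (zero-variance profile) fails the filter.
#'
#' @param input list with elements `motif_z` (matrix motif x condition),
#'   `fp_padj` (matrix motif x DAR set, `NA` = untested),
#'   `condition_map` (DAR set -> condition), `tpm` (matrix TF x
#'   condition), `motif_tf` (data.frame with columns `motif`, `tf`),
#'   `de_any` (named logical per TF).
#' @param z_abs,fp_alpha,tpm_min,r_min thresholds (2, 0.001, 5, 0.5).
#' @param fp_floor zero-p floor for [fp_enrichment_scores()].
#' @return data.frame, one row per (motif, TF) pair: per-condition
#'   columns `z_*`, `fp_*`, `ez_*`, the two correlations, the individual
#'   filter flags and `selected`. Motifs with no TF mapping are skipped
#'   with a warning.
#' @export
select_active_motifs <- function(input, z_abs = 2, fp_alpha = 0.001,
                                 tpm_min = 5, r_min = 0.5,
                                 fp_floor = 1e-16) {
  mz <- as.matrix(input$motif_z)
  conds <- colnames(mz)
  if (is.null(conds)) stop("motif_z needs condition column names")
  fp <- fp_enrichment_scores(input$fp_padj, input$condition_map,
                             floor = fp_floor)
  if (!all(conds %in% colnames(fp)))
    stop("FP scores missing condition(s): ",
         paste(setdiff(conds, colnames(fp)), collapse = ", "))
  fp <- fp[, conds, drop = FALSE]
  map <- input$motif_tf
  motifs <- rownames(mz)
  no_tf <- setdiff(motifs, map$motif)
  if (length(no_tf)) {
    warning("motif(s) without TF mapping skipped: ",
            paste(no_tf, collapse = ", "))
  }
  map <- map[map$motif %in% motifs, , drop = FALSE]
  tpm <- as.matrix(input$tpm)[, conds, drop = FALSE]
  miss_tf <- setdiff(map$tf, rownames(tpm))
  if (length(miss_tf))
    stop("TF(s) without TPM values: ", paste(miss_tf, collapse = ", "))
  ez <- expression_zscores(tpm)
  de <- input$de_any

  n <- nrow(map)
  r_fp <- r_ez <- numeric(n)
  pass_z <- pass_fp <- pass_tpm <- pass_de <- logical(n)
  padj <- as.matrix(input$fp_padj)
  for (i in seq_len(n)) {
    mo <- map$motif[i]; tf <- map$tf[i]
    zv <- mz[mo, ]
    pass_z[i] <- max(abs(zv)) >= z_abs
    pv <- padj[mo, ]
    pass_fp[i] <- any(!is.na(pv) & pv < fp_alpha)
    pass_tpm[i] <- max(tpm[tf, ]) > tpm_min
    pass_de[i] <- isTRUE(de[[tf]])
    r_fp[i] <- safe_cor(zv, fp[mo, ])
    r_ez[i] <- safe_cor(zv, ez[tf, ])
  }
  selected <- pass_z & pass_fp & pass_tpm & pass_de &
    !is.na(r_fp) & r_fp > r_min & !is.na(r_ez) & r_ez > r_min
  out <- data.frame(motif = map$motif, tf = map$tf,
                    stringsAsFactors = FALSE)
  for (cc in conds) out[[paste0("z_", cc)]] <- mz[map$motif, cc]
  for (cc in conds) out[[paste0("fp_", cc)]] <- fp[map$motif, cc]
  for (cc in conds) out[[paste0("ez_", cc)]] <- ez[map$tf, cc]
  out$pearson_z_fp <- r_fp
  out$pearson_z_expr <- r_ez
  out$pass_z <- pass_z; out$pass_fp <- pass_fp
  out$pass_tpm <- pass_tpm; out$pass_de <- pass_de
  out$selected <- selected
  out
}

# Pearson correlation that returns NA (not an error/warning) on
# zero-variance input.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Default mapping of DAR sets to conditions
#'
#' For the three-stage design (DE, AFE, PE) with contrasts DE vs AFE,
#' DE vs PE and AFE vs PE, each condition's specific DAR sets are the
#' ones whose accessibility is highest in that condition: the Lose sets
#' of its contrasts as stage A, the Gain sets as stage B.
#'
#' @return named character vector DAR set -> condition.
#' @export
default_condition_map <- function() {
  c("Lose_DEvsAFE" = "DE", "Lose_DEvsPE" = "DE",
    "Gain_DEvsAFE" = "AFE", "Lose_AFEvsPE" = "AFE",
    "Gain_DEvsPE" = "PE", "Gain_AFEvsPE" = "PE")
}
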