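#' Tally annotated neighbors per state transition
#'
#' For each observed transition (including identical-state pairs), counts
#' the up, down and unchanged annotations among the bins undergoing that
#' transition (`UP_T`, `DOWN_T`, `NO_T`) and among all other bins
#' (`UP_O`, `DOWN_O`, `NO_O`), the latter serving as controls. Bins with
#' `NA` annotation (no qualifying neighbor) are excluded from both
#' groups. When `id` is supplied (gene mode), counts are over unique ids
#' within each group, so a gene that is the nearest neighbor of many bins
#' counts once per group; without `id` (peak mode) counts are over bins.
#'
#' @param s_from,s_to character vectors: per-bin state in condition A and
#'   B.
#' @param label per-bin annotation in `up`/`down`/`no`, or `NA` to
#'   exclude the bin.
#' @param id optional per-bin id (e.g. nearest gene id) switching to
#'   unique-id counting.
#' @return data.frame with columns `s_from`, `s_to`, `UP_T`, `DOWN_T`,
#'   `NO_T`, `UP_O`, `DOWN_O`, `NO_O`, one row per observed transition.
#' @export
tally_neighbors <- function(s_from, s_to, label, id = NULL) {
  stopifnot(length(s_from) == length(s_to),
            length(label) == length(s_from))
  bad <- setdiff(unique(label[!is.na(label)]), c("up", "down", "no"))
  if (length(bad))
    stop("annotation label(s) outside {up, down, no}: ",
         paste(bad, collapse = ", "))
  trans <- paste(s_from, s_to, sep = "\r")
  lv <- sort(unique(trans))
  tf <- factor(trans, levels = lv)
  lab <- factor(label, levels = c("up", "down", "no"))
  keep <- !is.na(lab)
  if (is.null(id)) {
    tab_t <- table(tf[keep], lab[keep])
    tot <- colSums(tab_t)
    tab_o <- matrix(rep(tot, each = length(lv)), ncol = 3L) - unclass(tab_t)
  } else {
    stopifnot(length(id) == length(s_from))
    ti <- tf[keep]; ii <- id[keep]; li <- lab[keep]
    dup <- duplicated(paste(as.integer(ti), ii, sep = "\r"))
    ti <- ti[!dup]; ii <- ii[!dup]; li <- li[!dup]
    tab_t <- table(ti, li)
    # totals over unique ids (an id carries a single label)
    first <- !duplicated(ii)
    tot <- table(li[first])
    # an id contributes to the O group of transition t iff it occurs in
    # some transition other than t, i.e. unless t is its only transition
    n_trans <- table(ii)
    only <- ii %in% names(n_trans)[n_trans == 1L]
    tab_only <- table(ti[only], li[only])
    tab_o <- matrix(rep(as.vector(tot), each = length(lv)), ncol = 3L) -
      unclass(tab_only)
  }
  parts <- strsplit(lv, "\r", fixed = TRUE)
  data.frame(
    s_from = vapply(parts, `[`, "", 1L),
    s_to = vapply(parts, `[`, "", 2L),
    UP_T = as.vector(tab_t[, "up"]), DOWN_T = as.vector(tab_t[, "down"]),
    NO_T = as.vector(tab_t[, "no"]),
    UP_O = as.vector(tab_o[, 1L]), DOWN_O = as.vector(tab_o[, 2L]),
    NO_O = as.vector(tab_o[, 3L]),
    stringsAsFactors = FALSE)
}

#' Fisher exact test triplet for transition association
#'
#' Three two-sided Fisher exact tests per transition, each row of the
#' 2x2 table being one of the two groups:
#' `P_UPDOWN`: `[UP_T, DOWN_T]` vs `[UP_O, DOWN_O]`;
#' `P_UP`: `[UP_T, DOWN_T + NO_T]` vs `[UP_O, DOWN_O + NO_O]`;
#' `P_DOWN`: `[DOWN_T, UP_T + NO_T]` vs `[DOWN_O, UP_O + NO_O]`.
#' A table with an all-zero margin yields p = 1 by convention.
#'
#' @param counts data.frame from [tally_neighbors()].
#' @return data.frame with columns `p_updown`, `p_up`, `p_down`.
#' @export
fisher_triplet <- function(counts) {
  f2 <- function(a, b, c, d) {
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
      return(1)
    # fisher.test can exceed 1 by rounding on large tables
    min(1, stats::fisher.test(matrix(c(a, c, b, d), 2L))$p.value)
  }
  n <- nrow(counts)
  p_ud <- p_u <- p_d <- numeric(n)
  for (i in seq_len(n)) {
    ut <- counts$UP_T[i]; dt <- counts$DOWN_T[i]; nt <- counts$NO_T[i]
    uo <- counts$UP_O[i]; do_ <- counts$DOWN_O[i]; no <- counts$NO_O[i]
    p_ud[i] <- f2(ut, dt, uo, do_)
    p_u[i] <- f2(ut, dt + nt, uo, do_ + no)
    p_d[i] <- f2(dt, ut + nt, do_, uo + no)
  }
  data.frame(p_updown = p_ud, p_up = p_u, p_down = p_d)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector, clipped at 1. Thin,
#' validated wrapper over `stats::p.adjust(method = "BH")`; each test
#' family (updown, up, down) is adjusted separately across all
#' transitions of a run.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted values.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Ratio statistics for transition association
#'
#' For each transition, with `T`-group total `nT = UP_T + DOWN_T + NO_T`
#' and control total `nO = UP_O + DOWN_O + NO_O`:
#' `RATIO_UPDOWN = ((UP_T - DOWN_T)/nT) / ((UP_O - DOWN_O)/nO)`,
#' `RATIO_UP = (UP_T/nT) / (UP_O/nO)`,
#' `RATIO_DOWN = (DOWN_T/nT) / (DOWN_O/nO)`.
#' A ratio is undefined (`NA`) when either group total is 0 or when its
#' control numerator is 0 (`UP_O = DOWN_O` for RATIO_UPDOWN).
#'
#' @param counts data.frame from [tally_neighbors()].
#' @return data.frame with columns `ratio_updown`, `ratio_up`,
#'   `ratio_down`.
#' @export
compute_ratios <- function(counts) {
  nT <- counts$UP_T + counts$DOWN_T + counts$NO_T
  nO <- counts$UP_O + counts$DOWN_O + counts$NO_O
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  fT_ud <- safe_div(counts$UP_T - counts$DOWN_T, nT)
  fO_ud <- safe_div(counts$UP_O - counts$DOWN_O, nO)
  fT_u <- safe_div(counts$UP_T, nT); fO_u <- safe_div(counts$UP_O, nO)
  fT_d <- safe_div(counts$DOWN_T, nT); fO_d <- safe_div(counts$DOWN_O, nO)
  data.frame(
    ratio_updown = ifelse(is.na(fT_ud) | is.na(fO_ud) | fO_ud == 0,
                          NA_real_, fT_ud / fO_ud),
    ratio_up = ifelse(is.na(fT_u) | is.na(fO_u) | fO_u == 0,
                      NA_real_, fT_u / fO_u),
    ratio_down = ifelse(is.na(fT_d) | is.na(fO_d) | fO_d == 0,
                        NA_real_, fT_d / fO_d))
}

#' Classify transitions by neighbor enrichment
#'
#' A transition is enriched in nearby upregulated neighbors
#' (`up_enriched`) when `RATIO_UPDOWN > 1`, `RATIO_UP > ratio_min`,
#' `P_UPDOWN < alpha` and `P_UP < alpha`; enriched in downregulated
#' neighbors (`down_enriched`) when `RATIO_UPDOWN < 1`, `RATIO_DOWN >
#' ratio_min`, `P_UPDOWN < alpha` and `P_DOWN < alpha`; `none`
#' otherwise. All inequalities are strict, as printed. When
#' `RATIO_UPDOWN` is undefined, or the direction-determining ratio is
#' undefined, the label is `undefined`.
#'
#' @param ratios data.frame from [compute_ratios()].
#' @param p data.frame with columns `p_updown`, `p_up`, `p_down`
#'   (normally the BH-adjusted values).
#' @param ratio_min directional ratio threshold (default 1.2).
#' @param alpha significance threshold (default 0.05).
#' @return factor with levels up_enriched, down_enriched, none,
#'   undefined.
#' @export
classify_association <- function(ratios, p, ratio_min = 1.2,
                                 alpha = 0.05) {
  n <- nrow(ratios)
  lab <- rep("none", n)
  r_ud <- ratios$ratio_updown
  undef <- is.na(r_ud) |
    (!is.na(r_ud) & r_ud > 1 & is.na(ratios$ratio_up)) |
    (!is.na(r_ud) & r_ud < 1 & is.na(ratios$ratio_down))
  up <- !undef & !is.na(r_ud) & r_ud > 1 &
    ratios$ratio_up > ratio_min & p$p_updown < alpha & p$p_up < alpha
  down <- !undef & !is.na(r_ud) & r_ud < 1 &
    ratios$ratio_down > ratio_min & p$p_updown < alpha & p$p_down < alpha
  lab[up] <- "up_enriched"
  lab[down] <- "down_enriched"
  lab[undef] <- "undefined"
  factor(lab, levels = c("up_enriched", "down_enriched", "none",
                         "undefined"))
}

# shared tail of the two association pipelines
finish_association <- function(counts, use_adjusted = TRUE,
                               ratio_min = 1.2, alpha = 0.05) {
  p <- fisher_triplet(counts)
  q <- data.frame(q_updown = adjust_bh(p$p_updown),
                  q_up = adjust_bh(p$p_up),
                  q_down = adjust_bh(p$p_down))
  r <- compute_ratios(counts)
  used <- if (use_adjusted)
    data.frame(p_updown = q$q_updown, p_up = q$q_up, p_down = q$q_down)
  else p
  lab <- classify_association(r, used, ratio_min = ratio_min,
                              alpha = alpha)
  cbind(counts, p, q, r, data.frame(label = lab))
}

#' Transition association with nearby differential gene expression
#'
#' For every bin of the grid, assigns the nearest expressed gene (TPM >
#' `min_tpm` in either condition, TSS within `max_dist`); bins with no
#' qualifying gene are excluded. Each transition's neighborhood is then
#' tested for enrichment of up/downregulated genes via the Fisher
#' triplet, BH adjustment per test family, the three ratio statistics
#' and the threshold classification.
#'
#' @param track_a,track_b [state_track()]s for conditions A and B.
#' @param genes gene table (see [read_genes()]).
#' @param contrast contrast name; DE status is read from column
#'   `de_<contrast>`.
#' @param conditions the two condition labels whose `tpm_` columns define
#'   expression (defaults to the track condition labels).
#' @param max_dist,min_tpm nearest-gene parameters (50 kb, TPM > 1).
#' @param unique_genes count unique genes per group (default TRUE) or
#'   per-bin multiplicity.
#' @param use_adjusted classify on BH-adjusted p-values (default TRUE).
#' @param ratio_min,alpha classification thresholds (1.2, 0.05).
#' @return data.frame, one row per observed transition, with counts, raw
#'   and adjusted p-values, ratios and the class label.
#' @export
associate_genes <- function(track_a, track_b, genes, contrast,
                            conditions = c(track_a$condition,
                                           track_b$condition),
                            max_dist = 50000, min_tpm = 1,
                            unique_genes = TRUE, use_adjusted = TRUE,
                            ratio_min = 1.2, alpha = 0.05) {
  de_col <- paste0("de_", contrast)
  if (!de_col %in% names(genes))
    stop("gene table has no column ", de_col)
  grid <- track_a$grid
  bins <- bin_coords(grid)
  nn <- nearest_expressed_tss(bins, genes, conditions,
                              max_dist = max_dist, min_tpm = min_tpm)
  lab <- genes[[de_col]][match(nn$gene_id, genes$gene_id)]
  counts <- tally_neighbors(as.character(track_a$states),
                            as.character(track_b$states),
                            lab,
                            id = if (unique_genes) nn$gene_id else NULL)
  finish_association(counts, use_adjusted = use_adjusted,
                     ratio_min = ratio_min, alpha = alpha)
}

#' Annotate grid bins by the classified peaks they contain
#'
#' A bin is `up` when a Gain-peak summit falls in it, `down` when a
#' Lose-peak summit does, `no` otherwise. A bin containing both takes
#' `up` (Gain precedence) and is flagged.
#'
#' @param peaks data.frame with `klass` and `bin` columns.
#' @param grid a [genome_grid()].
#' @return list with `label` (per-bin up/down/no) and `conflicted`
#'   (indices of bins holding both Gain and Lose summits).
#' @export
annotate_bins_by_peaks <- function(peaks, grid) {
  lab <- rep("no", grid$total_bins)
  gain_bins <- unique(peaks$bin[peaks$klass == "Gain"])
  lose_bins <- unique(peaks$bin[peaks$klass == "Lose"])
  lab[lose_bins] <- "down"
  lab[gain_bins] <- "up"
  list(label = lab, conflicted = intersect(gain_bins, lose_bins))
}

#' Transition association with differential chromatin accessibility
#'
#' Peak-mode analogue of [associate_genes()]: upregulated genes are
#' replaced by bins holding Gain-peak summits, downregulated genes by
#' bins holding Lose-peak summits, and unchanged genes by bins with
#' neither. All bins are annotated, so none are excluded.
#'
#' @param track_a,track_b [state_track()]s for conditions A and B.
#' @param peaks classified peak table with `klass` and `bin` columns.
#' @param use_adjusted,ratio_min,alpha as in [associate_genes()].
#' @return data.frame as in [associate_genes()]; the indices of bins
#'   holding both Gain and Lose summits are attached as attribute
#'   `"conflicted_bins"`.
#' @export
associate_peaks <- function(track_a, track_b, peaks,
                            use_adjusted = TRUE, ratio_min = 1.2,
                            alpha = 0.05) {
  ann <- annotate_bins_by_peaks(peaks, track_a$grid)
  counts <- tally_neighbors(as.character(track_a$states),
                            as.character(track_b$states),
                            ann$label)
  out <- finish_association(counts, use_adjusted = use_adjusted,
                            ratio_min = ratio_min, alpha = alpha)
  attr(out, "conflicted_bins") <- ann$conflicted
  out
}
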