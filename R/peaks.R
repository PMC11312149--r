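#' Read a peak table
#'
#' Reads a BED6+-style tab-separated peak file with per-peak differential
#' statistics. Expected columns: chrom, start, end, summit_offset (bp from
#' `start`), log2fc, fdr, and four 0/1 call flags (replicates 1 and 2 of
#' conditions A and B). A header line is accepted and detected by a
#' non-numeric second field.
#'
#' @param path path to the file (plain or gzip).
#' @return data.frame with columns `chrom`, `start`, `end`, `summit`,
#'   `log2fc`, `fdr`, `called_A1`, `called_A2`, `called_B1`, `called_B2`.
#' @export
read_peaks <- function(path) {
  first <- utils::read.table(path, sep = "\t", header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  has_header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  x <- utils::read.table(path, sep = "\t", header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 10L) stop("peak file needs >= 10 columns")
  out <- data.frame(chrom = as.character(x[[1]]),
                    start = as.numeric(x[[2]]), end = as.numeric(x[[3]]),
                    summit = as.numeric(x[[2]]) + as.numeric(x[[4]]),
                    log2fc = as.numeric(x[[5]]), fdr = as.numeric(x[[6]]),
                    called_A1 = as.logical(as.integer(x[[7]])),
                    called_A2 = as.logical(as.integer(x[[8]])),
                    called_B1 = as.logical(as.integer(x[[9]])),
                    called_B2 = as.logical(as.integer(x[[10]])),
                    stringsAsFactors = FALSE)
  validate_peaks(out)
  out
}

validate_peaks <- function(peaks) {
  need <- c("chrom", "start", "end", "summit")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peak table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(peaks$start >= peaks$end)) stop("peak with start >= end")
  if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end))
    stop("peak summit outside [start, end)")
  invisible(peaks)
}

#' Classify peaks as Gain, Lose, Common or Unclassified
#'
#' Applies the differential-accessibility classification for a contrast
#' A vs B: Gain peaks are called in both replicates of B with
#' `fdr < fdr_max` and `log2fc > lfc_min`; Lose peaks are called in both
#' replicates of A with `fdr < fdr_max` and `log2fc < -lfc_min`; Common
#' peaks are called in both replicates of A and/or B and have
#' `fdr > fdr_max` and/or `|log2fc| < lfc_min`; everything else is
#' Unclassified. All inequalities are strict, as printed; peaks exactly
#' at a threshold therefore fall through to Unclassified.
#'
#' @param peaks data.frame with columns `log2fc`, `fdr`, `called_A1`,
#'   `called_A2`, `called_B1`, `called_B2` (log2fc oriented B over A).
#' @param fdr_max FDR threshold (default 0.01).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @return factor with levels Gain, Lose, Common, Unclassified.
#' @examples
#' classify_dars(data.frame(log2fc = 1.5, fdr = 0.005,
#'   called_A1 = FALSE, called_A2 = FALSE,
#'   called_B1 = TRUE, called_B2 = TRUE))
#' @export
classify_dars <- function(peaks, fdr_max = 0.01, lfc_min = 1) {
  need <- c("log2fc", "fdr", "called_A1", "called_A2",
            "called_B1", "called_B2")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(peaks$log2fc) || anyNA(peaks$fdr))
    stop("missing log2fc/fdr statistic for peak(s) ",
         paste(which(is.na(peaks$log2fc) | is.na(peaks$fdr)),
               collapse = ", "))
  in_A <- peaks$called_A1 & peaks$called_A2
  in_B <- peaks$called_B1 & peaks$called_B2
  gain <- in_B & peaks$fdr < fdr_max & peaks$log2fc > lfc_min
  lose <- in_A & peaks$fdr < fdr_max & peaks$log2fc < -lfc_min
  common <- (in_A | in_B) &
    (peaks$fdr > fdr_max | abs(peaks$log2fc) < lfc_min)
  klass <- rep("Unclassified", nrow(peaks))
  klass[common] <- "Common"
  klass[lose] <- "Lose"
  klass[gain] <- "Gain"
  factor(klass, levels = c("Gain", "Lose", "Common", "Unclassified"))
}

#' Assign peaks to grid bins by summit position
#'
#' Each peak is assigned to the bin containing its summit.
#'
#' @param peaks data.frame with `chrom` and `summit` columns.
#' @param grid a [genome_grid()].
#' @return integer vector of global bin indices, one per peak.
#' @export
assign_peak_bins <- function(peaks, grid) {
  bin_index(grid, peaks$chrom, peaks$summit)
}

#' Stratify classified peaks by chromatin state
#'
#' Groups Lose peaks by the chromatin state of their summit bin in
#' condition A and Gain peaks by the state of their bin in condition B.
#' For each state `s` the background set comprises the Common peaks whose
#' bin has state `s` in A and/or in B.
#'
#' @param peaks data.frame with a `klass` column (from [classify_dars()])
#'   and a `bin` column (from [assign_peak_bins()]).
#' @param track_a,track_b [state_track()]s for the two conditions, on the
#'   same grid.
#' @return list with `groups` (data.frame: `peak` row index, `klass`,
#'   `state`) and `background` (data.frame: `peak` row index, `state`;
#'   a Common peak appears once per state it backs).
#' @export
stratify_peaks_by_state <- function(peaks, track_a, track_b) {
  stopifnot(inherits(track_a, "state_track"), inherits(track_b, "state_track"))
  if (!identical(track_a$grid, track_b$grid)) stop("tracks on different grids")
  if (is.null(peaks$bin) || is.null(peaks$klass))
    stop("peaks need 'bin' and 'klass' columns")
  if (any(peaks$bin < 1L | peaks$bin > track_a$grid$total_bins))
    stop("peak bin outside track")
  sa <- as.character(track_a$states[peaks$bin])
  sb <- as.character(track_b$states[peaks$bin])
  kl <- as.character(peaks$klass)
  gi <- which(kl == "Gain")
  li <- which(kl == "Lose")
  groups <- data.frame(
    peak = c(gi, li),
    klass = c(rep("Gain", length(gi)), rep("Lose", length(li))),
    state = c(sb[gi], sa[li]),
    stringsAsFactors = FALSE)
  ci <- which(kl == "Common")
  bg <- rbind(data.frame(peak = ci, state = sa[ci]),
              data.frame(peak = ci, state = sb[ci]))
  bg <- bg[!duplicated(bg), , drop = FALSE]
  bg <- bg[order(bg$state, bg$peak), , drop = FALSE]
  rownames(bg) <- NULL
  list(groups = groups, background = bg)
}
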