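#' Fixed-width genomic bin grid
#'
#' Defines the genome-wide grid of fixed-width bins on which chromatin-state
#' calls, peak summits and TSSs are placed. Coordinates are 0-based
#' half-open (BED convention); bin `b` of a chromosome covers
#' `[b * bin_size, (b + 1) * bin_size)`. Bins are indexed globally,
#' 1-based, chromosome blocks in the order of `chrom_sizes`.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 200, the resolution at which
#'   histone-mark segmentations are typically called).
#' @return an object of class `genome_grid` with elements `chrom_sizes`,
#'   `bin_size`, `n_bins` (bins per chromosome), `offset` (global index of
#'   the bin before each chromosome block) and `total_bins`.
#' @examples
#' grid <- genome_grid(c(chr1 = 1e6, chr2 = 5e5))
#' grid$total_bins
#' @export
genome_grid <- function(chrom_sizes, bin_size = 200L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicated chromosome names")
  bin_size <- as.integer(bin_size)
  if (length(bin_size) != 1L || is.na(bin_size) || bin_size <= 0L)
    stop("bin_size must be a single positive integer")
  if (any(chrom_sizes <= 0)) stop("every chromosome length must be > 0")
  n_bins <- as.integer(ceiling(chrom_sizes / bin_size))
  names(n_bins) <- names(chrom_sizes)
  offset <- c(0L, cumsum(n_bins))[seq_along(n_bins)]
  names(offset) <- names(chrom_sizes)
  structure(
    list(chrom_sizes = chrom_sizes, bin_size = bin_size,
         n_bins = n_bins, offset = offset,
         total_bins = sum(n_bins)),
    class = "genome_grid")
}

#' @export
print.genome_grid <- function(x, ...) {
  cat("genome_grid:", length(x$chrom_sizes), "chromosome(s),",
      x$bin_size, "bp bins,", x$total_bins, "bins total\n")
  invisible(x)
}

#' Global bin index of genomic positions
#'
#' Maps 0-based positions to 1-based global bin indices on the grid.
#'
#' @param grid a [genome_grid()].
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 0-based positions.
#' @return integer vector of global bin indices.
#' @export
bin_index <- function(grid, chrom, pos) {
  stopifnot(inherits(grid, "genome_grid"))
  m <- match(chrom, names(grid$chrom_sizes))
  if (anyNA(m)) {
    bad <- unique(chrom[is.na(m)])
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  if (any(pos < 0) || any(pos >= grid$chrom_sizes[m]))
    stop("position outside chromosome bounds")
  unname(grid$offset[m] + as.integer(pos %/% grid$bin_size) + 1L)
}

#' Coordinates of grid bins
#'
#' Inverse of [bin_index()]: chromosome, start and end (0-based half-open)
#' of each global bin index. Ends are clipped to the chromosome length.
#'
#' @param grid a [genome_grid()].
#' @param bins integer vector of global bin indices (default: all bins).
#' @return data.frame with columns `bin`, `chrom`, `start`, `end`.
#' @export
bin_coords <- function(grid, bins = seq_len(grid$total_bins)) {
  stopifnot(inherits(grid, "genome_grid"))
  if (any(bins < 1L) || any(bins > grid$total_bins))
    stop("bin index out of range")
  breaks <- c(0L, cumsum(grid$n_bins))
  ci <- findInterval(bins - 1L, breaks, rightmost.closed = FALSE) # block id
  local <- bins - 1L - grid$offset[ci]
  start <- local * grid$bin_size
  end <- pmin(start + grid$bin_size, grid$chrom_sizes[ci])
  data.frame(bin = bins, chrom = names(grid$chrom_sizes)[ci],
             start = start, end = end, row.names = NULL)
}

#' Default chromatin-state alphabet
#'
#' The ten-state histone-mark model renamed to functional labels, with the
#' two no-mark states fused into a single quiescent state, leaving nine
#' labels: active/acetylated promoter (TssA), promoter (Tss), promoter
#' flank (TssFlnk), bivalent promoter (TssBiv), Polycomb-repressed
#' (ReprPC), active enhancer (EnhA), primed enhancer (EnhPr), bivalent
#' enhancer (EnhBiv) and quiescent (Quies).
#'
#' @return character vector of state labels.
#' @export
default_states <- function() {
  c("TssA", "Tss", "TssFlnk", "TssBiv", "ReprPC",
    "EnhA", "EnhPr", "EnhBiv", "Quies")
}

#' Per-bin chromatin-state track
#'
#' One chromatin-state label per grid bin for one condition.
#'
#' @param grid a [genome_grid()].
#' @param states character or factor vector, one label per bin.
#' @param condition condition label (e.g. "DE", "PE").
#' @param alphabet state alphabet; labels outside it are an error.
#' @return object of class `state_track` with elements `grid`, `condition`
#'   and `states` (factor of length `grid$total_bins`).
#' @export
state_track <- function(grid, states, condition = "cond",
                        alphabet = default_states()) {
  stopifnot(inherits(grid, "genome_grid"))
  if (length(states) != grid$total_bins)
    stop("states must have one label per bin (", grid$total_bins, ")")
  s <- as.character(states)
  bad <- setdiff(unique(s), alphabet)
  if (length(bad))
    stop("state label(s) outside alphabet: ", paste(bad, collapse = ", "))
  structure(
    list(grid = grid, condition = condition,
         states = factor(s, levels = alphabet)),
    class = "state_track")
}

#' @export
print.state_track <- function(x, ...) {
  cat("state_track [", x$condition, "]: ", length(x$states), " bins, ",
      nlevels(x$states), " states\n", sep = "")
  invisible(x)
}
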