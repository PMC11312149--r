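#' Read a dense chromatin-state segmentation onto a grid
#'
#' Reads a BED4-like dense segmentation file (chrom, start, end, state)
#' and rasterizes it onto the bin grid. Segments that tile the grid
#' exactly map directly; a bin partially covered by several segments
#' takes the state with the largest overlap, ties going to the segment
#' that appears earlier in the file. Bins not covered by any segment
#' default to the quiescent state. State labels listed in `collapse`
#' are renamed before any other processing (by default the two no-mark
#' states are fused into `Quies`).
#'
#' @param path path to a BED4+ file (plain or gzip); `track`/`browser`/`#`
#'   header lines are skipped.
#' @param grid a [genome_grid()].
#' @param condition condition label for the resulting track.
#' @param alphabet state alphabet after collapsing.
#' @param fill_state state assigned to uncovered bins (default `"Quies"`).
#' @param collapse named character vector mapping raw labels to analysis
#'   labels.
#' @return a [state_track()].
#' @export
read_segmentation <- function(path, grid, condition = "cond",
                              alphabet = default_states(),
                              fill_state = "Quies",
                              collapse = c(Quies1 = "Quies",
                                           Quies2 = "Quies")) {
  seg <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  # drop UCSC-style header lines that survive comment filtering
  drop <- grepl("^(track|browser)", seg[[1]])
  seg <- seg[!drop, , drop = FALSE]
  if (ncol(seg) < 4L) stop("segmentation file needs >= 4 columns")
  seg <- data.frame(chrom = as.character(seg[[1]]),
                    start = as.numeric(seg[[2]]),
                    end = as.numeric(seg[[3]]),
                    state = as.character(seg[[4]]),
                    stringsAsFactors = FALSE)
  hit <- match(seg$state, names(collapse))
  seg$state[!is.na(hit)] <- unname(collapse[hit[!is.na(hit)]])
  rasterize_segments(seg, grid, condition = condition,
                     alphabet = alphabet, fill_state = fill_state)
}

# Majority-overlap rasterization of (chrom,start,end,state) segments.
rasterize_segments <- function(seg, grid, condition = "cond",
                               alphabet = default_states(),
                               fill_state = "Quies") {
  m <- match(seg$chrom, names(grid$chrom_sizes))
  if (anyNA(m))
    stop("unknown chromosome(s) in segmentation: ",
         paste(unique(seg$chrom[is.na(m)]), collapse = ", "))
  if (any(seg$start < 0) || any(seg$end > grid$chrom_sizes[m]))
    stop("segment outside chromosome bounds")
  if (any(seg$start >= seg$end)) stop("segment with start >= end")
  bad <- setdiff(unique(seg$state), alphabet)
  if (length(bad))
    stop("state label(s) outside alphabet: ", paste(bad, collapse = ", "))

  # conflicting-overlap check: within a chromosome, a segment starting
  # before the furthest end seen so far overlaps; differing states -> error
  ord <- order(m, seg$start, seg$end)
  os <- seg[ord, , drop = FALSE]; om <- m[ord]
  if (nrow(os) > 1L) {
    max_end <- os$end[1L]; max_state <- os$state[1L]
    for (i in 2:nrow(os)) {
      if (om[i] != om[i - 1L]) {
        max_end <- os$end[i]; max_state <- os$state[i]
        next
      }
      if (os$start[i] < max_end && os$state[i] != max_state)
        stop("overlapping segments with conflicting states near ",
             os$chrom[i], ":", os$start[i])
      if (os$end[i] >= max_end) {
        max_end <- os$end[i]; max_state <- os$state[i]
      }
    }
  }

  bs <- grid$bin_size
  fb <- as.integer(seg$start %/% bs)
  lb <- as.integer((seg$end - 1) %/% bs)
  nb <- lb - fb + 1L
  seg_i <- rep.int(seq_len(nrow(seg)), nb)
  local_bin <- fb[seg_i] + sequence(nb) - 1L
  gbin <- grid$offset[m[seg_i]] + local_bin + 1L
  b0 <- as.numeric(local_bin) * bs
  overlap <- pmin(seg$end[seg_i], b0 + bs) - pmax(seg$start[seg_i], b0)
  # per bin keep largest overlap; ties -> earliest segment in file order
  pick <- order(gbin, -overlap, seg_i)
  keep <- pick[!duplicated(gbin[pick])]

  states <- rep.int(fill_state, grid$total_bins)
  states[gbin[keep]] <- seg$state[seg_i[keep]]
  state_track(grid, states, condition = condition, alphabet = alphabet)
}

#' Write a state track as a dense segmentation BED file
#'
#' Run-length encodes the per-bin labels back into (chrom, start, end,
#' state) rows. Inverse of [read_segmentation()] for exactly tiled input.
#'
#' @param track a [state_track()].
#' @param path output path (".gz" suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(track, path) {
  stopifnot(inherits(track, "state_track"))
  grid <- track$grid
  rows <- vector("list", length(grid$n_bins))
  for (i in seq_along(grid$n_bins)) {
    idx <- grid$offset[i] + seq_len(grid$n_bins[i])
    r <- rle(as.character(track$states[idx]))
    endbin <- cumsum(r$lengths)
    startbin <- endbin - r$lengths
    rows[[i]] <- data.frame(
      chrom = names(grid$chrom_sizes)[i],
      start = startbin * grid$bin_size,
      end = pmin(endbin * grid$bin_size, grid$chrom_sizes[i]),
      state = r$values, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
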