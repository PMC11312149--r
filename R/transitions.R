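#' Count chromatin-state transitions between two conditions
#'
#' Tabulates, over all grid bins, the ordered pairs (state in A, state in
#' B), including identical-state pairs on the diagonal.
#'
#' @param track_a,track_b [state_track()]s on the same grid with the same
#'   state alphabet.
#' @return object of class `transition_counts`: list with `states`
#'   (alphabet), `O` (observed count matrix, rows = state in A, cols =
#'   state in B) and `N` (total bins).
#' @export
count_transitions <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "state_track"), inherits(track_b, "state_track"))
  if (!identical(track_a$grid, track_b$grid))
    stop("tracks are on different grids")
  if (!identical(levels(track_a$states), levels(track_b$states)))
    stop("tracks use different state alphabets")
  states <- levels(track_a$states)
  S <- length(states)
  O <- matrix(tabulate(as.integer(track_a$states) +
                         S * (as.integer(track_b$states) - 1L),
                       nbins = S * S),
              nrow = S, dimnames = list(from = states, to = states))
  structure(list(states = states, O = O, N = length(track_a$states)),
            class = "transition_counts")
}

#' Expected transition counts under state-call shuffling
#'
#' The null model holds the condition-A state calls fixed and uniformly
#' permutes the condition-B calls across all bins. `method = "permutation"`
#' averages the observed transition counts over `n_perm` shuffles;
#' `method = "analytic"` returns the closed-form expectation of that
#' procedure, `E[s1, s2] = n_A(s1) * n_B(s2) / N`. Both preserve the
#' per-condition state marginals, so the expected matrix sums to `N`.
#'
#' @param track_a,track_b [state_track()]s on the same grid.
#' @param method `"permutation"` or `"analytic"`.
#' @param n_perm number of shuffles (default 1000).
#' @param seed RNG seed for permutation mode (default 1).
#' @return numeric matrix of expected counts (rows = state in A).
#' @export
expected_counts <- function(track_a, track_b,
                            method = c("permutation", "analytic"),
                            n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(track_a, "state_track"), inherits(track_b, "state_track"))
  if (!identical(track_a$grid, track_b$grid))
    stop("tracks are on different grids")
  N <- length(track_a$states)
  if (N == 0L) stop("empty tracks")
  states <- levels(track_a$states)
  S <- length(states)
  ai <- as.integer(track_a$states)
  bi <- as.integer(track_b$states)
  if (method == "analytic") {
    nA <- tabulate(ai, nbins = S)
    nB <- tabulate(bi, nbins = S)
    E <- outer(nA, nB) / N
    dimnames(E) <- list(from = states, to = states)
    return(E)
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  acc <- numeric(S * S)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  for (p in seq_len(n_perm)) {
    bp <- bi[sample.int(N)]
    acc <- acc + tabulate(ai + S * (bp - 1L), nbins = S * S)
  }
  E <- matrix(acc / n_perm, nrow = S,
              dimnames = list(from = states, to = states))
  E
}

#' Transition enrichment and directional fold enrichment
#'
#' The enrichment score of a transition is the observed count divided by
#' its shuffled expectation, `ES = O / E`, controlling for state
#' coverage. The fold enrichment divides each transition's score by the
#' score of the opposite direction, `FE(s1 -> s2) = ES(s1 -> s2) /
#' ES(s2 -> s1)`, controlling for the overall similarity of the two
#' states; the diagonal is therefore 1 and `FE(s1 -> s2) * FE(s2 -> s1)
#' = 1` wherever both are defined. When the reverse score is 0 the fold
#' enrichment is undefined and reported as `NA`.
#'
#' @param counts a [count_transitions()] result.
#' @param E expected-count matrix from [expected_counts()].
#' @param pseudocount optional pseudocount added to `O` before scoring
#'   (default 0; exploratory use only).
#' @return object of class `transition_enrichment`: list with `states`,
#'   `O`, `E`, `ES`, `FE`, `N`.
#' @export
fold_enrichment <- function(counts, E, pseudocount = 0) {
  stopifnot(inherits(counts, "transition_counts"))
  if (!identical(dim(E), dim(counts$O)))
    stop("E and O dimensions differ")
  O <- counts$O + pseudocount
  if (any(E == 0 & O > 0))
    stop("E = 0 where O > 0: impossible marginal")
  ES <- ifelse(E > 0, O / E, NA_real_)
  rev_ES <- t(ES)
  FE <- ifelse(is.na(ES) | is.na(rev_ES) | rev_ES == 0,
               NA_real_, ES / rev_ES)
  diag(FE) <- ifelse(is.finite(diag(ES)) & diag(ES) > 0, 1, NA_real_)
  dimnames(ES) <- dimnames(FE) <- dimnames(counts$O)
  structure(list(states = counts$states, O = counts$O, E = E,
                 ES = ES, FE = FE, N = counts$N),
            class = "transition_enrichment")
}

#' Display mask for a transition-enrichment heatmap
#'
#' A cell is `"colored"` when its fold enrichment exceeds `min_fe` and it
#' is supported by at least `min_bins` observed bins; poorly represented
#' transitions (fewer than `min_bins` bins) are `"grey"`; everything else
#' is `"uncolored"`.
#'
#' @param enr a [fold_enrichment()] result.
#' @param min_fe fold-enrichment threshold (default 1.5, strict `>`).
#' @param min_bins minimum observed bins (default 200, `>=`).
#' @return character matrix with values colored/uncolored/grey.
#' @export
mask_for_display <- function(enr, min_fe = 1.5, min_bins = 200) {
  stopifnot(inherits(enr, "transition_enrichment"))
  m <- matrix("uncolored", nrow(enr$O), ncol(enr$O),
              dimnames = dimnames(enr$O))
  m[!is.na(enr$FE) & enr$FE > min_fe & enr$O >= min_bins] <- "colored"
  m[enr$O < min_bins] <- "grey"
  m
}

#' Tidy table of a transition-enrichment result
#'
#' @param enr a [fold_enrichment()] result.
#' @param min_fe,min_bins passed to [mask_for_display()].
#' @return data.frame with columns `s_from`, `s_to`, `O`, `E`, `ES`,
#'   `FE`, `masked`.
#' @export
transition_table <- function(enr, min_fe = 1.5, min_bins = 200) {
  stopifnot(inherits(enr, "transition_enrichment"))
  mask <- mask_for_display(enr, min_fe = min_fe, min_bins = min_bins)
  st <- enr$states
  data.frame(
    s_from = rep(st, times = length(st)),
    s_to = rep(st, each = length(st)),
    O = as.vector(enr$O), E = as.vector(enr$E),
    ES = as.vector(enr$ES), FE = as.vector(enr$FE),
    masked = as.vector(mask),
    stringsAsFactors = FALSE)
}

# Seed handling: run a block under a local RNG state without disturbing
# the caller's stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
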