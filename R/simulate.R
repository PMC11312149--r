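#' Build a joint transition-weight matrix
#'
#' Constructs the joint distribution of per-bin (state in A, state in B)
#' pairs used by [simulate_state_tracks()]. The base law mixes state
#' persistence (a `diag_weight` share of mass on the diagonal) with
#' independent draws from `marginal`, which keeps both condition
#' marginals equal to `marginal` and all off-diagonal fold enrichments
#' at 1. Planted entries multiply chosen ordered cells by a
#' fold factor, then the matrix is renormalized; because the touched
#' cells are small, the realized directional fold enrichment stays close
#' to the planted factor.
#'
#' @param states state alphabet.
#' @param marginal named state probabilities (default: a genome dominated
#'   by the quiescent state with a few percent in each marked state).
#' @param diag_weight share of bins that keep their state (default 0.5).
#' @param planted optional data.frame with columns `from`, `to`, `fe`.
#' @return matrix over ordered state pairs, nonnegative, summing to 1.
#' @export
transition_weights <- function(states = default_states(),
                               marginal = NULL, diag_weight = 0.5,
                               planted = NULL) {
  if (is.null(marginal)) {
    marginal <- c(TssA = 0.02, Tss = 0.02, TssFlnk = 0.02,
                  TssBiv = 0.01, ReprPC = 0.05, EnhA = 0.04,
                  EnhPr = 0.04, EnhBiv = 0.02, Quies = 0.78)
    marginal <- marginal[states]
    if (anyNA(marginal)) {
      marginal <- stats::setNames(rep(1 / length(states),
                                      length(states)), states)
    }
  }
  marginal <- marginal / sum(marginal)
  J <- diag_weight * diag(marginal) +
    (1 - diag_weight) * outer(marginal, marginal)
  dimnames(J) <- list(from = states, to = states)
  if (!is.null(planted)) {
    # solve for the cell multipliers so the *realized* directional fold
    # enrichment (which involves the perturbed marginals) equals the
    # requested factor exactly
    fe_of <- function(J, a, b) {
      rA <- rowSums(J); cB <- colSums(J)
      (J[a, b] / (rA[a] * cB[b])) / (J[b, a] / (rA[b] * cB[a]))
    }
    delta <- Inf
    for (iter in 1:200) {
      delta <- 0
      for (i in seq_len(nrow(planted))) {
        a <- planted$from[i]; b <- planted$to[i]
        cur <- fe_of(J, a, b)
        if (!is.finite(cur) || cur <= 0)
          stop("requested fold enrichment not attainable: the ",
               "planted cell is too large relative to its state ",
               "marginals")
        # damped multiplicative update: planting inflates the pair's
        # marginals, so the bare fixed point can overshoot
        J[a, b] <- J[a, b] * (planted$fe[i] / cur)^0.5
        delta <- max(delta, abs(cur - planted$fe[i]) / planted$fe[i])
      }
      J <- J / sum(J)
      if (delta < 1e-12) break
    }
    if (delta > 1e-6)
      stop("requested fold enrichment not attainable: the planted ",
           "cell is too large relative to its state marginals")
  }
  J
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults
#' describe the study conditions used throughout: a toy genome of two
#' 10-Mb chromosomes binned at 200 bp (100,000 bins), the nine-state
#' alphabet, i.i.d. per-bin transitions from [transition_weights()],
#' 2000 protein-coding genes, null differential-expression and peak
#' association laws, and the three-condition TF-activity design.
#'
#' @param chrom_sizes,bin_size,states genome layout and state alphabet.
#' @param joint_weights joint transition law (default
#'   [transition_weights()] over `states`).
#' @param conditions the two compared conditions (A, B order).
#' @param contrast contrast label; genes carry a `de_<contrast>` column.
#' @param gene_count number of protein-coding genes.
#' @param tss_law list `(transition, frac)`: fraction of TSSs placed
#'   inside bins of the named transition (`"From->To"`); `frac = 0`
#'   places all TSSs uniformly.
#' @param expressed_frac fraction of genes drawn from the expressed TPM
#'   law.
#' @param tpm_meanlog,tpm_sdlog log-normal TPM law of expressed genes
#'   (median 10 TPM).
#' @param noexpr_meanlog,noexpr_sdlog TPM law of non-expressed genes
#'   (median 0.2 TPM).
#' @param de_association named list of `c(up =, down =)` probabilities
#'   per transition (`"From->To"`), with a `default` entry.
#' @param peak_association named list of `c(gain =, lose =)`
#'   probabilities per transition, with a `default` entry.
#' @param common_peak_rate probability that a bin with neither a Gain
#'   nor a Lose summit holds a Common peak.
#' @param tf_config list: `conditions`, `n_coherent`, `n_decoy`.
#' @param network_config list: `n_tfs`, `n_true`, `n_false`.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(chrom_sizes = c(chr1 = 1e7, chr2 = 1e7),
                              bin_size = 200L,
                              states = default_states(),
                              joint_weights = NULL,
                              conditions = c("DE", "PE"),
                              contrast = "DEvsPE",
                              gene_count = 2000L,
                              tss_law = list(transition = NULL, frac = 0),
                              expressed_frac = 0.7,
                              tpm_meanlog = log(10), tpm_sdlog = 1,
                              noexpr_meanlog = log(0.2),
                              noexpr_sdlog = 0.75,
                              de_association =
                                list(default = c(up = 0.1, down = 0.1)),
                              peak_association =
                                list(default = c(gain = 0.02,
                                                 lose = 0.015)),
                              common_peak_rate = 0.05,
                              tf_config = list(
                                conditions = c("DE", "AFE", "PE"),
                                n_coherent = 6L, n_decoy = 6L),
                              network_config = list(
                                n_tfs = 12L, n_true = 5L,
                                n_false = 5L)) {
  if (length(states) < 2L) stop("degenerate state alphabet")
  if (is.null(joint_weights))
    joint_weights <- transition_weights(states)
  if (any(joint_weights < 0) ||
      abs(sum(joint_weights) - 1) > 1e-8)
    stop("joint_weights must be nonnegative and sum to 1")
  probs <- unlist(de_association)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  structure(
    list(chrom_sizes = chrom_sizes, bin_size = bin_size,
         states = states, joint_weights = joint_weights,
         conditions = conditions, contrast = contrast,
         gene_count = gene_count, tss_law = tss_law,
         expressed_frac = expressed_frac,
         tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog,
         noexpr_meanlog = noexpr_meanlog, noexpr_sdlog = noexpr_sdlog,
         de_association = de_association,
         peak_association = peak_association,
         common_peak_rate = common_peak_rate,
         tf_config = tf_config, network_config = network_config),
    class = "sim_config")
}

#' Simulate paired chromatin-state tracks
#'
#' Draws one (state in A, state in B) pair per grid bin, i.i.d. from the
#' configured joint transition law. The exact sampling distribution is
#' returned as the ground truth.
#'
#' @param cfg a [simulation_config()].
#' @param seed RNG seed.
#' @return list with `track_a`, `track_b` ([state_track()]s) and `truth`
#'   (the joint weight matrix).
#' @export
simulate_state_tracks <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- genome_grid(cfg$chrom_sizes, cfg$bin_size)
  S <- length(cfg$states)
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  idx <- sample.int(S * S, grid$total_bins, replace = TRUE,
                    prob = as.vector(cfg$joint_weights))
  ai <- (idx - 1L) %% S + 1L
  bi <- (idx - 1L) %/% S + 1L
  list(track_a = state_track(grid, cfg$states[ai],
                             condition = cfg$conditions[1],
                             alphabet = cfg$states),
       track_b = state_track(grid, cfg$states[bi],
                             condition = cfg$conditions[2],
                             alphabet = cfg$states),
       truth = cfg$joint_weights)
}

# law lookup helper: named list with "default" entry
law_for <- function(law, key) {
  if (!is.null(law[[key]])) law[[key]] else law[["default"]]
}

#' Simulate a gene table over simulated tracks
#'
#' TSSs are placed uniformly over the genome except for a configurable
#' fraction placed inside bins of a designated transition (the spatial
#' association between transitions and genes). Each gene's differential
#' expression status is drawn from the association law of the
#' transition of the bin containing its TSS; TPMs are drawn from the
#' expressed or non-expressed log-normal law per condition.
#'
#' @param cfg a [simulation_config()].
#' @param tracks result of [simulate_state_tracks()].
#' @param seed RNG seed.
#' @return gene table data.frame (see [read_genes()] for columns).
#' @export
simulate_genes <- function(cfg, tracks, seed) {
  n <- cfg$gene_count
  if (n == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      tss = numeric(0), strand = character(0)))
  }
  grid <- tracks$track_a$grid
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  trans <- paste(tracks$track_a$states, tracks$track_b$states,
                 sep = "->")
  # placement: a planted share of genes is put into *distinct* bins of
  # the designated transition (one gene per bin, sampled without
  # replacement, capped at the number of such bins); a gene inside a bin
  # is that bin's nearest gene at distance 0, so the planted bins carry
  # the planted expression law while the remaining genes keep the
  # control group at background composition
  planted <- rep(FALSE, n)
  if (!is.null(cfg$tss_law$transition) && cfg$tss_law$frac > 0) {
    tbins <- which(trans == cfg$tss_law$transition)
    k <- min(round(cfg$tss_law$frac * n), length(tbins))
    if (k > 0) planted[seq_len(k)] <- TRUE
  }
  tss <- numeric(n); chrom <- character(n)
  k <- sum(planted)
  if (k > 0) {
    bsel <- tbins[sample.int(length(tbins), k, replace = FALSE)]
    bc <- bin_coords(grid, bsel)
    chrom[planted] <- bc$chrom
    tss[planted] <- bc$start +
      floor(stats::runif(k) * (bc$end - bc$start))
  }
  m <- n - k
  if (m > 0) {
    ci <- sample.int(length(cfg$chrom_sizes), m, replace = TRUE,
                     prob = cfg$chrom_sizes)
    chrom[!planted] <- names(cfg$chrom_sizes)[ci]
    tss[!planted] <- floor(stats::runif(m) * cfg$chrom_sizes[ci])
  }
  gbin <- bin_index(grid, chrom, tss)
  # DE label from the law of the gene's own transition
  de <- character(n)
  u <- stats::runif(n)
  gene_trans <- trans[gbin]
  for (tkey in unique(gene_trans)) {
    law <- law_for(cfg$de_association, tkey)
    sel <- gene_trans == tkey
    de[sel] <- ifelse(u[sel] < law["up"], "up",
                      ifelse(u[sel] < law["up"] + law["down"], "down",
                             "no"))
  }
  expressed <- stats::runif(n) < cfg$expressed_frac
  draw_tpm <- function() {
    ifelse(expressed,
           stats::rlnorm(n, cfg$tpm_meanlog, cfg$tpm_sdlog),
           stats::rlnorm(n, cfg$noexpr_meanlog, cfg$noexpr_sdlog))
  }
  out <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    chrom = chrom, tss = tss,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (cc in cfg$conditions) out[[paste0("tpm_", cc)]] <- draw_tpm()
  out[[paste0("de_", cfg$contrast)]] <- de
  out$is_tf <- FALSE
  out
}

#' Simulate a classified peak set over simulated tracks
#'
#' Per bin, draws at most one summit: a Gain summit with the
#' transition's `gain` probability, a Lose summit with its `lose`
#' probability, otherwise a Common summit at the background rate. Peaks
#' are 201 bp windows centered on their summit (clipped at chromosome
#' edges); one peak per bin, so summits never collide. In
#' `mode = "labels"` the class is assigned directly; in
#' `mode = "statistics"` per-peak (log2fc, fdr, replicate call flags)
#' are drawn so that [classify_dars()] reproduces the intended class.
#'
#' @param cfg a [simulation_config()].
#' @param tracks result of [simulate_state_tracks()].
#' @param seed RNG seed.
#' @param mode `"labels"` or `"statistics"`.
#' @return peak data.frame with `chrom`, `start`, `end`, `summit`,
#'   `bin`, `klass` and, in statistics mode, `log2fc`, `fdr` and the
#'   four call flags.
#' @export
simulate_peaks <- function(cfg, tracks, seed,
                           mode = c("labels", "statistics")) {
  mode <- match.arg(mode)
  grid <- tracks$track_a$grid
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  trans <- paste(tracks$track_a$states, tracks$track_b$states,
                 sep = "->")
  nb <- grid$total_bins
  pg <- pl <- numeric(nb)
  for (tkey in unique(trans)) {
    law <- law_for(cfg$peak_association, tkey)
    sel <- trans == tkey
    pg[sel] <- law["gain"]; pl[sel] <- law["lose"]
  }
  u <- stats::runif(nb)
  klass <- rep(NA_character_, nb)
  klass[u < pg] <- "Gain"
  klass[u >= pg & u < pg + pl] <- "Lose"
  rest <- is.na(klass)
  klass[rest][stats::runif(sum(rest)) < cfg$common_peak_rate] <- "Common"
  bins <- which(!is.na(klass))
  bc <- bin_coords(grid, bins)
  summit <- bc$start + floor(stats::runif(length(bins)) *
                               (bc$end - bc$start))
  csize <- cfg$chrom_sizes[bc$chrom]
  start <- pmax(summit - 100, 0)
  end <- pmin(summit + 101, csize)
  out <- data.frame(chrom = bc$chrom, start = start, end = end,
                    summit = summit, bin = bins,
                    klass = factor(klass[bins],
                                   levels = c("Gain", "Lose", "Common",
                                              "Unclassified")),
                    stringsAsFactors = FALSE)
  if (mode == "statistics") {
    np <- nrow(out)
    kl <- as.character(out$klass)
    lfc <- numeric(np); fdr <- numeric(np)
    a1 <- a2 <- b1 <- b2 <- logical(np)
    g <- kl == "Gain"; l <- kl == "Lose"; cm <- kl == "Common"
    lfc[g] <- stats::runif(sum(g), 1.2, 3)
    fdr[g] <- stats::runif(sum(g), 0, 0.009)
    b1[g] <- b2[g] <- TRUE
    a1[g] <- stats::runif(sum(g)) < 0.3
    lfc[l] <- -stats::runif(sum(l), 1.2, 3)
    fdr[l] <- stats::runif(sum(l), 0, 0.009)
    a1[l] <- a2[l] <- TRUE
    b1[l] <- stats::runif(sum(l)) < 0.3
    lfc[cm] <- stats::runif(sum(cm), -0.8, 0.8)
    fdr[cm] <- stats::runif(sum(cm), 0.02, 1)
    a1[cm] <- a2[cm] <- TRUE
    b1[cm] <- b2[cm] <- stats::runif(sum(cm)) < 0.8
    out$log2fc <- lfc; out$fdr <- fdr
    out$called_A1 <- a1; out$called_A2 <- a2
    out$called_B1 <- b1; out$called_B2 <- b2
  }
  rownames(out) <- NULL
  out
}

#' Simulate TF-activity inputs with planted active TFs
#'
#' Coherent TFs receive condition-aligned motif Z-scores, footprint
#' enrichment p-values and expression profiles that pass every selection
#' filter; decoys each violate exactly one filter (low Z, footprint p
#' above threshold, low TPM, no differential expression, anti-correlated
#' expression, anti-correlated footprint profile — cycling), providing a
#' per-filter negative control.
#'
#' @param cfg a [simulation_config()].
#' @param seed RNG seed.
#' @return list with `input` (see [select_active_motifs()]) and `truth`
#'   (data.frame of the planted active (motif, tf) pairs).
#' @export
simulate_tf_inputs <- function(cfg, seed) {
  tfc <- cfg$tf_config
  conds <- tfc$conditions
  nc <- length(conds)
  cmap <- default_condition_map()
  sets <- names(cmap)
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  n_coh <- tfc$n_coherent; n_dec <- tfc$n_decoy
  n <- n_coh + n_dec
  motifs <- sprintf("M%03d", seq_len(n))
  tfs <- sprintf("TF%03d", seq_len(n))
  decoy_class <- rep(1:6, length.out = n_dec)
  home <- conds[rep(seq_len(nc), length.out = n)]

  z <- matrix(0, n, nc, dimnames = list(motifs, conds))
  padj <- matrix(NA_real_, n, length(sets),
                 dimnames = list(motifs, sets))
  tpm <- matrix(0, n, nc, dimnames = list(tfs, conds))
  de <- rep(TRUE, n); names(de) <- tfs

  z_profile <- function(h, peak = 2.6, low = -1.3) {
    ifelse(conds == h, peak, low) + stats::rnorm(nc, 0, 0.1)
  }
  p_profile <- function(h, strong = TRUE) {
    home_sets <- cmap[sets] == h
    p <- stats::runif(length(sets), 0.3, 0.9)
    p[home_sets] <- if (strong) 10^-stats::runif(sum(home_sets), 4, 8)
                    else stats::runif(sum(home_sets), 0.002, 0.009)
    p
  }
  tpm_profile <- function(h, hi = c(20, 60), lo = c(0.5, 2)) {
    ifelse(conds == h, stats::runif(nc, hi[1], hi[2]),
           stats::runif(nc, lo[1], lo[2]))
  }
  for (i in seq_len(n)) {
    h <- home[i]
    cls <- if (i <= n_coh) 0L else decoy_class[i - n_coh]
    z[i, ] <- if (cls == 1L) z_profile(h, 1.5, -0.75) else z_profile(h)
    padj[i, ] <- if (cls == 2L) p_profile(h, strong = FALSE)
                 else if (cls == 6L) {
                   # footprint evidence peaking away from home
                   away <- conds[conds != h][1]
                   p_profile(away)
                 } else p_profile(h)
    tpm[i, ] <- if (cls == 3L) tpm_profile(h, hi = c(2, 4.5))
                else if (cls == 5L) {
                  away <- conds[conds != h][1]
                  tpm_profile(away)
                } else tpm_profile(h)
    if (cls == 4L) de[i] <- FALSE
  }
  list(input = list(motif_z = z, fp_padj = padj, condition_map = cmap,
                    tpm = tpm,
                    motif_tf = data.frame(motif = motifs, tf = tfs,
                                          stringsAsFactors = FALSE),
                    de_any = de),
       truth = data.frame(motif = motifs[seq_len(n_coh)],
                          tf = tfs[seq_len(n_coh)],
                          stringsAsFactors = FALSE))
}

#' Simulate TF-network inputs with a planted true network
#'
#' Lays out TF genes on the configured genome, then builds a candidate
#' edge table in which the planted true edges pass the whole filter
#' chain (score > 0.7, both TPM > 5, activity criteria, mediating Gain
#' peak with a source footprint within 50 kb of the target TSS; half of
#' the mediating peaks within 25 kb) and each false edge violates
#' exactly one predicate. Binding (RARA-style) peaks are placed so that
#' designated TFs are the nearest genes of a peak called in the target
#' condition.
#'
#' @param cfg a [simulation_config()].
#' @param seed RNG seed.
#' @return list with `tf_genes`, `edges`, `footprints`, `gain_peaks`,
#'   `tpm` (named, target condition), `criteria`, `rara_peaks` and
#'   `truth` (list `edges`, `direct_targets`).
#' @export
simulate_network_inputs <- function(cfg, seed) {
  nwc <- cfg$network_config
  n_tfs <- nwc$n_tfs
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  # deterministic layout: TF genes 150 kb apart with 100 kb of headroom
  # at chromosome ends, so mediating peaks (< 80 kb from their target)
  # and binding peaks never come within 50 kb of a neighboring TF
  spacing <- 1.5e5; margin <- 1e5
  ci <- integer(n_tfs); within <- numeric(n_tfs)
  chrom_i <- 1L; cur <- margin
  for (i in seq_len(n_tfs)) {
    while (chrom_i <= length(cfg$chrom_sizes) &&
           cur > cfg$chrom_sizes[chrom_i] - margin) {
      chrom_i <- chrom_i + 1L; cur <- margin
    }
    if (chrom_i > length(cfg$chrom_sizes))
      stop("genome too small to place ", n_tfs, " TF genes")
    ci[i] <- chrom_i; within[i] <- cur
    cur <- cur + spacing
  }
  tf_ids <- sprintf("TFN%02d", seq_len(n_tfs))
  tf_genes <- data.frame(
    gene_id = tf_ids, chrom = names(cfg$chrom_sizes)[ci],
    tss = within, strand = "+", is_tf = TRUE,
    stringsAsFactors = FALSE)

  # roles: last two TFs are dedicated violators (low TPM; no criteria)
  tpm <- stats::runif(n_tfs, 10, 80); names(tpm) <- tf_ids
  low_tpm_tf <- tf_ids[n_tfs]
  tpm[low_tpm_tf] <- 2
  no_crit_tf <- tf_ids[n_tfs - 1L]
  criteria <- data.frame(
    tf = tf_ids,
    active_integrated = rep(c(TRUE, FALSE), length.out = n_tfs),
    fp_gain_enriched = rep(c(FALSE, TRUE), length.out = n_tfs),
    top_influence = TRUE, stringsAsFactors = FALSE)
  criteria[criteria$tf == no_crit_tf,
           c("active_integrated", "fp_gain_enriched",
             "top_influence")] <- FALSE

  good <- setdiff(tf_ids, c(low_tpm_tf, no_crit_tf))
  n_true <- nwc$n_true
  # true edges form a ring over the first n_true qualifying TFs; false
  # edges draw on the remaining ones so no pair collides with a true edge
  if (n_true + 2L > length(good))
    stop("too many true edges requested for the TF count")
  src <- good[seq_len(n_true)]
  tgt <- good[c(seq_len(n_true)[-1L], 1L)]
  true_edges <- data.frame(source = src, target = tgt,
                           score = stats::runif(n_true, 0.75, 0.95),
                           stringsAsFactors = FALSE)

  gain_peaks <- list(); footprints <- list()
  add_mediating <- function(source, target, dist) {
    gi <- match(target, tf_genes$gene_id)
    ps <- tf_genes$tss[gi] + dist
    pk <- data.frame(chrom = tf_genes$chrom[gi], start = ps,
                     end = ps + 400, stringsAsFactors = FALSE)
    fp <- data.frame(chrom = tf_genes$chrom[gi], start = ps + 50,
                     end = ps + 70, tf = source,
                     stringsAsFactors = FALSE)
    gain_peaks[[length(gain_peaks) + 1L]] <<- pk
    footprints[[length(footprints) + 1L]] <<- fp
  }
  near <- rep(c(TRUE, FALSE), length.out = n_true) # half < 25 kb
  for (i in seq_len(n_true)) {
    d <- if (near[i]) floor(stats::runif(1, 1000, 24000))
         else floor(stats::runif(1, 26000, 49000))
    add_mediating(true_edges$source[i], true_edges$target[i], d)
  }

  # false edges, one violated predicate each, cycling
  n_false <- nwc$n_false
  pool <- good[(n_true + 1L):length(good)]
  fsrc <- character(n_false); ftgt <- character(n_false)
  fscore <- numeric(n_false)
  for (i in seq_len(n_false)) {
    viol <- (i - 1L) %% 5L + 1L
    s <- pool[(i - 1L) %% length(pool) + 1L]
    t <- pool[i %% length(pool) + 1L]
    sc <- stats::runif(1, 0.75, 0.95)
    if (viol == 1L) sc <- stats::runif(1, 0.4, 0.69)
    if (viol == 2L) t <- low_tpm_tf
    if (viol == 3L) s <- no_crit_tf
    if (viol %in% c(1L, 2L, 3L))
      add_mediating(s, t, floor(stats::runif(1, 1000, 40000)))
    if (viol == 4L)
      add_mediating(s, t, floor(stats::runif(1, 55000, 80000)))
    # viol 5: no mediating footprint at all
    fsrc[i] <- s; ftgt[i] <- t; fscore[i] <- sc
  }
  false_edges <- data.frame(source = fsrc, target = ftgt,
                            score = fscore, stringsAsFactors = FALSE)
  # drop accidental duplicates of true edges
  dup <- paste(false_edges$source, false_edges$target) %in%
    paste(true_edges$source, true_edges$target)
  false_edges <- false_edges[!dup, , drop = FALSE]
  edges <- rbind(true_edges, false_edges)
  rownames(edges) <- NULL

  # binding peaks: two designated direct targets among the true-edge TFs
  direct <- sort(unique(c(true_edges$source[1], true_edges$target[1])))
  rara <- do.call(rbind, lapply(direct, function(tf) {
    gi <- match(tf, tf_genes$gene_id)
    ps <- tf_genes$tss[gi] - 2000
    data.frame(chrom = tf_genes$chrom[gi], start = ps, end = ps + 401,
               summit = ps + 200, stringsAsFactors = FALSE)
  }))
  de_col <- paste0("de_", cfg$contrast)
  tf_genes[[de_col]] <- ifelse(tf_ids %in% direct, "up",
                               sample(c("up", "no"), n_tfs, TRUE))
  for (cc in cfg$conditions)
    tf_genes[[paste0("tpm_", cc)]] <- unname(tpm)

  list(tf_genes = tf_genes, edges = edges,
       footprints = do.call(rbind, footprints),
       gain_peaks = do.call(rbind, gain_peaks),
       tpm = tpm, criteria = criteria, rara_peaks = rara,
       truth = list(edges = true_edges, direct_targets = direct))
}
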