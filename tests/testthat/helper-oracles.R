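# Independent oracles and small fixtures shared across the suite.

# Two-sided Fisher exact p by exhaustive enumeration over all tables
# with the same margins (hypergeometric mass <= observed mass, with the
# same relative-error guard R's implementation documents).
fisher_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - m2):min(k, m1)
  pr <- stats::dhyper(xs, m1, m2, k)
  p0 <- stats::dhyper(a, m1, m2, k)
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up closed form: sorted q_(i) = min_{j >= i}
# p_(j) * m / j, clipped at 1, mapped back to input order.
bh_closed_form <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force nearest expressed TSS: linear scan over all genes.
brute_nearest <- function(query, genes, conditions, max_dist = 50000,
                          min_tpm = 1) {
  tpm_cols <- paste0("tpm_", conditions)
  expr <- Reduce(`|`, lapply(tpm_cols, function(cc) genes[[cc]] > min_tpm))
  g <- genes[expr, , drop = FALSE]
  out_id <- rep(NA_character_, nrow(query))
  out_d <- rep(NA_real_, nrow(query))
  for (i in seq_len(nrow(query))) {
    gi <- g[g$chrom == query$chrom[i], , drop = FALSE]
    if (!nrow(gi)) next
    d <- ifelse(gi$tss >= query$start[i] & gi$tss < query$end[i], 0,
                ifelse(gi$tss < query$start[i],
                       query$start[i] - gi$tss,
                       gi$tss - query$end[i] + 1))
    dmin <- min(d)
    if (dmin > max_dist) next
    out_id[i] <- min(gi$gene_id[d == dmin])
    out_d[i] <- dmin
  }
  data.frame(gene_id = out_id, distance = out_d,
             stringsAsFactors = FALSE)
}

# Tiny two-chromosome grid used by the unit tests.
toy_grid <- function() genome_grid(c(chrA = 2000, chrB = 1000),
                                   bin_size = 200L)

# Tracks built from explicit state vectors on a single-chromosome grid.
toy_tracks <- function(a, b, alphabet = sort(unique(c(a, b)))) {
  grid <- genome_grid(c(chr1 = length(a) * 200), bin_size = 200L)
  list(track_a = state_track(grid, a, "A", alphabet),
       track_b = state_track(grid, b, "B", alphabet))
}

# Study conditions with a planted transition-expression association:
# ~250 expected T-bins on the 100k-bin genome, planted genes one per
# bin at the planted up/down law, background at the null law.
planted_assoc_config <- function() {
  jw <- transition_weights(
    planted = data.frame(from = "ReprPC", to = "EnhA", fe = 3.125))
  simulation_config(
    joint_weights = jw,
    tss_law = list(transition = "ReprPC->EnhA", frac = 0.15),
    de_association = list(default = c(up = 0.1, down = 0.1),
                          "ReprPC->EnhA" = c(up = 0.6, down = 0.05)))
}

# Hand-built 12-edge network fixture; the hand-enumerated kept set is
# edges 1-5 (see test-network.R for the per-edge reasoning).
hand_network_fixture <- function() {
  tfs <- paste0("T", 1:8)
  tpm <- stats::setNames(rep(10, 8), tfs)
  tpm["T7"] <- 3 # fails TPM > 5
  criteria <- data.frame(tf = tfs, active_integrated = TRUE,
                         fp_gain_enriched = FALSE,
                         top_influence = FALSE,
                         stringsAsFactors = FALSE)
  criteria[criteria$tf == "T6",
           c("active_integrated", "fp_gain_enriched",
             "top_influence")] <- FALSE # fails all three criteria
  edges <- data.frame(
    source = c("T1", "T2", "T3", "T1", "T4", "T1", "T2", "T1", "T7",
               "T6", "T2", "T8"),
    target = c("T2", "T3", "T1", "T3", "T5", "T4", "T4", "T7", "T2",
               "T2", "T8", "T2"),
    score = c(0.9, 0.8, 0.75, 0.71, 0.95, 0.7, 0.65, 0.9, 0.9, 0.9,
              0.9, 0.9),
    stringsAsFactors = FALSE)
  med <- data.frame(
    source = c("T1", "T2", "T3", "T1", "T4", "T1", "T2", "T1", "T7",
               "T6", "T2"),
    target = c("T2", "T3", "T1", "T3", "T5", "T4", "T4", "T7", "T2",
               "T2", "T8"),
    distance = c(10000, 30000, 24999, 49999, 1000, 5000, 5000, 5000,
                 5000, 5000, 50000),
    stringsAsFactors = FALSE)
  list(edges = edges, tpm = tpm, criteria = criteria, med = med)
}
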