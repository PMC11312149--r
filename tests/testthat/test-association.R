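test_that("neighbor tallies count unique genes per group and bins in peak mode", {
  # 10 bins; 3 undergo t = a->b; nearest genes g1 (up), g2 (up, twice)
  s_from <- c(rep("a", 3), rep("c", 7))
  s_to <- c(rep("b", 3), rep("c", 7))
  label <- c("up", "up", "up", "down", "no", "no", "up", NA, "no", "no")
  id <- c("g1", "g2", "g2", "g3", "g4", "g5", "g6", NA, "g7", "g8")
  tal <- tally_neighbors(s_from, s_to, label, id)
  t_row <- tal[tal$s_from == "a" & tal$s_to == "b", ]
  expect_equal(t_row$UP_T, 2) # g2 deduplicated
  expect_equal(t_row$DOWN_T, 0)
  expect_equal(t_row$NO_T, 0)
  expect_equal(t_row$UP_O, 1)  # g6
  expect_equal(t_row$DOWN_O, 1)
  expect_equal(t_row$NO_O, 4)
  # a gene nearest to bins of two transitions counts once in each group
  tal2 <- tally_neighbors(c("a", "c"), c("b", "c"), c("up", "up"),
                          c("g1", "g1"))
  expect_equal(tal2$UP_T[tal2$s_from == "a"], 1)
  expect_equal(tal2$UP_O[tal2$s_from == "a"], 1)
  # peaks mode: per-bin counts
  tal3 <- tally_neighbors(c(rep("a", 4), rep("c", 6)),
                          c(rep("b", 4), rep("c", 6)),
                          c("up", "no", "no", "no",
                            rep("no", 5), "down"))
  t3 <- tal3[tal3$s_from == "a", ]
  expect_equal(c(t3$UP_T, t3$DOWN_T, t3$NO_T), c(1, 0, 3))
  expect_error(tally_neighbors("a", "b", "sideways"), "sideways")
})

test_that("Fisher triplet matches exhaustive same-margin enumeration", {
  # perfectly balanced table
  tal <- data.frame(UP_T = 1, DOWN_T = 1, NO_T = 0, UP_O = 10,
                    DOWN_O = 10, NO_O = 0)
  expect_equal(fisher_triplet(tal)$p_updown, 1)
  # closed case [[5,0],[0,5]]: 2 / C(10,5)
  tal <- data.frame(UP_T = 5, DOWN_T = 0, NO_T = 0, UP_O = 0,
                    DOWN_O = 5, NO_O = 0)
  expect_equal(fisher_triplet(tal)$p_updown, 2 / 252,
               tolerance = 1e-12)
  # all-zero margin -> 1 by convention
  tal <- data.frame(UP_T = 0, DOWN_T = 0, NO_T = 3, UP_O = 0,
                    DOWN_O = 0, NO_O = 5)
  expect_equal(unlist(fisher_triplet(tal)[c("p_updown")]), c(p_updown = 1))
  # random tables with N <= 50 against the enumeration oracle
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]
    c_ <- cuts[3] - cuts[2]; d <- n - cuts[3]
    tal <- data.frame(UP_T = a, DOWN_T = b, NO_T = 0, UP_O = c_,
                      DOWN_O = d, NO_O = 0)
    expect_equal(fisher_triplet(tal)$p_updown,
                 fisher_enum(a, b, c_, d), tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the step-up closed form and preserves order", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(23)
  for (i in 1:20) {
    p <- stats::runif(sample(1:50, 1))
    q <- adjust_bh(p)
    expect_equal(q, bh_closed_form(p), tolerance = 1e-14)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ratio statistics follow the displayed formulas with NA on zero denominators", {
  tal <- data.frame(UP_T = 6, DOWN_T = 2, NO_T = 12, UP_O = 15,
                    DOWN_O = 5, NO_O = 80)
  r <- compute_ratios(tal)
  expect_equal(r$ratio_updown, (4 / 20) / (10 / 100)) # 2.0
  expect_equal(r$ratio_up, (6 / 20) / (15 / 100))     # 2.0
  expect_equal(r$ratio_down, (2 / 20) / (5 / 100))    # 2.0
  # control numerator 0 (UP_O = DOWN_O) -> RATIO_UPDOWN undefined
  tal$UP_O <- tal$DOWN_O <- 5
  expect_true(is.na(compute_ratios(tal)$ratio_updown))
  # empty transition group -> everything undefined
  tal0 <- data.frame(UP_T = 0, DOWN_T = 0, NO_T = 0, UP_O = 3,
                     DOWN_O = 3, NO_O = 4)
  expect_true(is.na(compute_ratios(tal0)$ratio_updown))
  # proportional groups -> all defined ratios are 1
  tal1 <- data.frame(UP_T = 3, DOWN_T = 1, NO_T = 6, UP_O = 9,
                     DOWN_O = 3, NO_O = 18)
  r1 <- compute_ratios(tal1)
  expect_equal(unlist(r1), c(ratio_updown = 1, ratio_up = 1,
                             ratio_down = 1))
})

test_that("classification applies the printed threshold rule", {
  lab <- function(r_ud, r_u, r_d, q_ud, q_u, q_d)
    as.character(classify_association(
      data.frame(ratio_updown = r_ud, ratio_up = r_u, ratio_down = r_d),
      data.frame(p_updown = q_ud, p_up = q_u, p_down = q_d)))
  expect_equal(lab(2.0, 2.0, 2.0, 0.01, 0.02, 0.9), "up_enriched")
  expect_equal(lab(0.5, 0.9, 1.5, 0.01, 0.9, 0.03), "down_enriched")
  expect_equal(lab(2.0, 1.1, NA, 0.01, 0.01, NA), "none") # RATIO_UP <= 1.2
  expect_equal(lab(2.0, 1.2, NA, 0.01, 0.01, NA), "none") # strict >
  expect_equal(lab(NA, 2.0, 2.0, 0.01, 0.01, 0.01), "undefined")
  expect_equal(lab(2.0, NA, 1.5, 0.01, 0.01, 0.01), "undefined")
  expect_equal(lab(1.0, 2.0, 2.0, 0.01, 0.01, 0.01), "none") # exactly 1
  expect_equal(lab(2.0, 2.0, 2.0, 0.06, 0.01, 0.01), "none") # p fails
})

test_that("up/down symmetry: swapping labels mirrors the classification", {
  set.seed(31)
  s_from <- sample(c("a", "b"), 4000, TRUE)
  s_to <- sample(c("a", "b"), 4000, TRUE)
  lab <- sample(c("up", "down", "no"), 4000, TRUE,
                prob = c(0.3, 0.1, 0.6))
  tal <- tally_neighbors(s_from, s_to, lab)
  swapped <- c(up = "down", down = "up", no = "no")[lab]
  tal_s <- tally_neighbors(s_from, s_to, unname(swapped))
  expect_equal(tal_s$UP_T, tal$DOWN_T)
  expect_equal(tal_s$DOWN_O, tal$UP_O)
  p <- fisher_triplet(tal); p_s <- fisher_triplet(tal_s)
  expect_equal(p_s$p_updown, p$p_updown, tolerance = 1e-12)
  expect_equal(p_s$p_up, p$p_down, tolerance = 1e-12)
  r <- compute_ratios(tal); r_s <- compute_ratios(tal_s)
  l1 <- classify_association(r, setNames(p, c("p_updown", "p_up", "p_down")))
  l2 <- classify_association(r_s, setNames(p_s, c("p_updown", "p_up", "p_down")))
  map <- c(up_enriched = "down_enriched", down_enriched = "up_enriched",
           none = "none", undefined = "undefined")
  expect_equal(unname(map[as.character(l1)]), as.character(l2))
})

test_that("planted transition-expression signal is recovered and the null stays quiet", {
  cfg <- planted_assoc_config()
  hits <- 0L
  for (s in 1:3) {
    tr <- simulate_state_tracks(cfg, s)
    g <- simulate_genes(cfg, tr, s + 1000L)
    ag <- associate_genes(tr$track_a, tr$track_b, g,
                          contrast = "DEvsPE")
    row <- ag[ag$s_from == "ReprPC" & ag$s_to == "EnhA", ]
    if (as.character(row$label) == "up_enriched") hits <- hits + 1L
    expect_gt(row$ratio_up, 1.2)
  }
  expect_equal(hits, 3L)
  # null law: no transition called enriched
  cfg0 <- simulation_config()
  tr <- simulate_state_tracks(cfg0, 99)
  g <- simulate_genes(cfg0, tr, 1099)
  ag0 <- associate_genes(tr$track_a, tr$track_b, g,
                         contrast = "DEvsPE")
  expect_equal(sum(ag0$label %in% c("up_enriched", "down_enriched")), 0)
})

test_that("peak-mode association recovers a planted Gain enrichment", {
  jw <- transition_weights(
    planted = data.frame(from = "ReprPC", to = "EnhA", fe = 3.125))
  cfg <- simulation_config(
    joint_weights = jw,
    peak_association = list(default = c(gain = 0.02, lose = 0.015),
                            "ReprPC->EnhA" = c(gain = 0.5,
                                               lose = 0.02)))
  tr <- simulate_state_tracks(cfg, 4)
  pk <- simulate_peaks(cfg, tr, 1004)
  ap <- associate_peaks(tr$track_a, tr$track_b, pk)
  row <- ap[ap$s_from == "ReprPC" & ap$s_to == "EnhA", ]
  expect_equal(as.character(row$label), "up_enriched")
})

test_that("bins holding both Gain and Lose summits take Gain and are flagged", {
  grid <- genome_grid(c(chr1 = 2000), bin_size = 200L)
  peaks <- data.frame(bin = c(3L, 3L, 5L),
                      klass = c("Gain", "Lose", "Lose"))
  ann <- annotate_bins_by_peaks(peaks, grid)
  expect_equal(ann$label[3], "up")
  expect_equal(ann$label[5], "down")
  expect_equal(ann$conflicted, 3L)
})
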