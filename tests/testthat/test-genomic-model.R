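test_that("grid bins are half-open, counted by ceiling, and invert cleanly", {
  grid <- genome_grid(c(chr1 = 1000, chr2 = 450), bin_size = 200L)
  expect_equal(unname(grid$n_bins), c(5L, 3L)) # ceil(450/200) = 3
  expect_equal(grid$total_bins, 8L)
  expect_equal(bin_index(grid, "chr1", 0), 1L)
  expect_equal(bin_index(grid, "chr1", 199), 1L)
  expect_equal(bin_index(grid, "chr1", 200), 2L)
  expect_equal(bin_index(grid, "chr2", 0), 6L)
  bc <- bin_coords(grid)
  expect_equal(bc$end[8], 450) # last bin clipped to chromosome length
  expect_equal(bin_index(grid, bc$chrom, bc$start), bc$bin)
  expect_error(bin_index(grid, "chrX", 10), "chrX")
  expect_error(bin_index(grid, "chr1", 1000), "bounds")
})

test_that("segmentation rasterization tiles, fills, and breaks ties by file order", {
  grid <- genome_grid(c(chr1 = 1000), bin_size = 200L)
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t600\tTssA", f)
  tr <- read_segmentation(f, grid)
  expect_equal(as.character(tr$states), c("TssA", "TssA", "TssA",
                                          "Quies", "Quies"))
  # partial coverage: uncovered bins fall back to the quiescent state
  writeLines(c("chr1\t0\t400\tEnhA"), f)
  tr <- read_segmentation(f, grid)
  expect_equal(as.character(tr$states[3:5]), rep("Quies", 3))
  # equal-overlap tie inside bin 2 ([200, 400)): earlier segment wins
  writeLines(c("chr1\t0\t300\tEnhA", "chr1\t300\t600\tTss"), f)
  tr <- read_segmentation(f, grid)
  expect_equal(as.character(tr$states[1:3]), c("EnhA", "EnhA", "Tss"))
  # majority overlap beats file order
  writeLines(c("chr1\t0\t250\tEnhA", "chr1\t250\t600\tTss"), f)
  tr <- read_segmentation(f, grid)
  expect_equal(as.character(tr$states[2]), "Tss")
})

test_that("segmentation reader validates chromosomes, overlaps, and collapses Quies1/2", {
  grid <- genome_grid(c(chr1 = 1000), bin_size = 200L)
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrZ\t0\t200\tTssA", f)
  expect_error(read_segmentation(f, grid), "chrZ")
  writeLines(c("chr1\t0\t400\tTssA", "chr1\t200\t600\tEnhA"), f)
  expect_error(read_segmentation(f, grid), "conflicting")
  # same-state overlap is tolerated
  writeLines(c("chr1\t0\t400\tTssA", "chr1\t200\t600\tTssA"), f)
  expect_silent(read_segmentation(f, grid))
  writeLines(c("chr1\t0\t400\tQuies1", "chr1\t400\t1000\tQuies2"), f)
  tr <- read_segmentation(f, grid)
  expect_equal(unique(as.character(tr$states)), "Quies")
})

test_that("segmentation writer round-trips through the reader, gzip included", {
  grid <- genome_grid(c(chrA = 2000, chrB = 900), bin_size = 200L)
  set.seed(42)
  tr <- state_track(grid, sample(default_states(), grid$total_bins,
                                 replace = TRUE), "A")
  f <- withr::local_tempfile(fileext = ".bed.gz")
  write_segmentation(tr, f)
  tr2 <- read_segmentation(f, grid, condition = "A")
  expect_identical(tr2$states, tr$states)
})

test_that("rasterization is total: state counts sum to the bin total", {
  grid <- genome_grid(c(chr1 = 10000), bin_size = 200L)
  set.seed(7)
  f <- withr::local_tempfile(fileext = ".bed")
  # ragged, non-aligned segments
  cuts <- sort(sample(1:9999, 30))
  seg <- data.frame(chrom = "chr1", start = c(0, cuts),
                    end = c(cuts, 10000),
                    state = sample(default_states(), 31, replace = TRUE))
  utils::write.table(seg, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tr <- read_segmentation(f, grid)
  expect_equal(sum(table(tr$states)), grid$total_bins)
})

test_that("DAR classification applies the Gain/Lose/Common rule with strict bounds", {
  mk <- function(log2fc, fdr, inA, inB)
    data.frame(log2fc = log2fc, fdr = fdr, called_A1 = inA,
               called_A2 = inA, called_B1 = inB, called_B2 = inB)
  expect_equal(as.character(classify_dars(mk(1.5, 0.005, FALSE, TRUE))),
               "Gain")
  expect_equal(as.character(classify_dars(mk(-1.5, 1e-4, TRUE, FALSE))),
               "Lose")
  expect_equal(as.character(classify_dars(mk(2.0, 0.2, TRUE, FALSE))),
               "Common")
  # exactly at the thresholds: neither rule fires
  expect_equal(as.character(classify_dars(mk(1.0, 0.005, FALSE, TRUE))),
               "Unclassified")
  expect_equal(as.character(classify_dars(mk(2.0, 0.01, FALSE, TRUE))),
               "Unclassified")
  # called in one replicate only: never Gain/Lose/Common
  p <- data.frame(log2fc = 1.5, fdr = 0.005, called_A1 = FALSE,
                  called_A2 = FALSE, called_B1 = TRUE,
                  called_B2 = FALSE)
  expect_equal(as.character(classify_dars(p)), "Unclassified")
  expect_error(classify_dars(mk(NA, 0.5, TRUE, TRUE)), "missing")
})

test_that("DAR classes partition: no peak is both Gain and Lose", {
  set.seed(11)
  n <- 500
  p <- data.frame(log2fc = stats::rnorm(n, 0, 2),
                  fdr = stats::runif(n),
                  called_A1 = sample(c(TRUE, FALSE), n, TRUE),
                  called_A2 = sample(c(TRUE, FALSE), n, TRUE),
                  called_B1 = sample(c(TRUE, FALSE), n, TRUE),
                  called_B2 = sample(c(TRUE, FALSE), n, TRUE))
  kl <- classify_dars(p)
  expect_equal(length(kl), n)
  gain <- p$called_B1 & p$called_B2 & p$fdr < 0.01 & p$log2fc > 1
  lose <- p$called_A1 & p$called_A2 & p$fdr < 0.01 & p$log2fc < -1
  expect_false(any(gain & lose))
  expect_true(all(kl[gain] == "Gain"))
  expect_true(all(kl[lose] == "Lose"))
})

test_that("summit-bin assignment follows half-open bin boundaries", {
  grid <- genome_grid(c(chr1 = 10000), bin_size = 200L)
  pk <- data.frame(chrom = "chr1", start = c(1100, 0, 0),
                   end = c(1400, 300, 300),
                   summit = c(1234, 0, 199))
  bins <- assign_peak_bins(pk, grid)
  expect_equal(bins, c(7L, 1L, 1L)) # summit 1234 -> bin [1200, 1400)
  expect_equal(bin_coords(grid, bins[1])$start, 1200)
  expect_identical(assign_peak_bins(pk, grid), bins) # idempotent
  expect_error(assign_peak_bins(
    data.frame(chrom = "chr1", summit = 10001), grid), "bounds")
})

test_that("nearest expressed TSS honours distance, expression and tie rules", {
  genes <- data.frame(
    gene_id = c("GA", "GB", "GC"), chrom = "chr1",
    tss = c(41199, 1100, 52000),
    tpm_DE = c(2, 5, 9), tpm_PE = c(0, 0, 9),
    stringsAsFactors = FALSE)
  q <- data.frame(chrom = "chr1", start = 1000, end = 1200)
  # containment -> distance 0
  nn <- nearest_expressed_tss(q, genes, c("DE", "PE"))
  expect_equal(nn$gene_id, "GB")
  expect_equal(nn$distance, 0)
  # gap arithmetic: TSS 41199 vs bin [1000, 1200) -> 40000
  nn <- nearest_expressed_tss(q, genes[1, ], c("DE", "PE"))
  expect_equal(nn$distance, 40000)
  # beyond the 50-kb cutoff -> no assignment
  nn <- nearest_expressed_tss(q, genes[3, ], c("DE", "PE"))
  expect_true(is.na(nn$gene_id))
  # cutoff is inclusive
  g50 <- data.frame(gene_id = "GX", chrom = "chr1", tss = 51199,
                    tpm_DE = 2, tpm_PE = 0)
  expect_equal(nearest_expressed_tss(q, g50, c("DE", "PE"))$distance,
               50000)
  # expression filter: TPM must exceed 1 in at least one condition
  g_low <- transform(genes[2, ], tpm_DE = 1, tpm_PE = 0.5)
  expect_true(is.na(nearest_expressed_tss(q, g_low,
                                          c("DE", "PE"))$gene_id))
  # equidistant left/right TSS -> lexicographically smaller id
  g_tie <- data.frame(gene_id = c("GZ", "GA"), chrom = "chr1",
                      tss = c(900, 1299), tpm_DE = 5, tpm_PE = 5)
  nn <- nearest_expressed_tss(q, g_tie, c("DE", "PE"))
  expect_equal(nn$gene_id, "GA")
  expect_equal(nn$distance, 100)
})

test_that("nearest TSS agrees with a brute-force scan on random instances", {
  set.seed(3)
  for (rep in 1:5) {
    ng <- sample(50:400, 1)
    genes <- data.frame(
      gene_id = sprintf("G%04d", sample.int(5000, ng)),
      chrom = sample(c("c1", "c2"), ng, TRUE),
      tss = sample.int(2e5, ng, replace = TRUE) - 1,
      tpm_DE = stats::rlnorm(ng, 0, 2),
      tpm_PE = stats::rlnorm(ng, 0, 2),
      stringsAsFactors = FALSE)
    nq <- 300
    qs <- sample.int(2e5 - 300, nq)
    q <- data.frame(chrom = sample(c("c1", "c2"), nq, TRUE),
                    start = qs, end = qs + 200)
    got <- nearest_expressed_tss(q, genes, c("DE", "PE"))
    want <- brute_nearest(q, genes, c("DE", "PE"))
    expect_identical(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
  }
})

test_that("state stratification keys Lose by A-state, Gain by B-state, background by either", {
  tt <- toy_tracks(c("ReprPC", "EnhA", "EnhA", "Quies"),
                   c("EnhA", "Quies", "EnhA", "Tss"),
                   alphabet = default_states())
  peaks <- data.frame(
    bin = c(1L, 2L, 3L, 4L),
    klass = c("Gain", "Lose", "Common", "Common"))
  st <- stratify_peaks_by_state(peaks, tt$track_a, tt$track_b)
  expect_equal(st$groups$state[st$groups$klass == "Gain"], "EnhA")
  expect_equal(st$groups$state[st$groups$klass == "Lose"], "EnhA")
  # Common peak with EnhA in A and/or B backs the EnhA groups
  expect_true(all(c(3L) %in% st$background$peak[st$background$state ==
                                                  "EnhA"]))
  # peak 4 (Quies in A, Tss in B) backs both states
  expect_setequal(st$background$state[st$background$peak == 4L],
                  c("Quies", "Tss"))
  expect_error(stratify_peaks_by_state(
    data.frame(bin = 99L, klass = "Gain"), tt$track_a, tt$track_b),
    "outside")
})
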