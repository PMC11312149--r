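test_that("binding-change classification uses inclusive outer bounds", {
  # pseudocount 1: counts (a, b) -> log2((b+1)/(a+1))
  r <- classify_rara_peaks(c(0, 1, 0, 3, 7), c(1, 0, 0, 8.2, 1))
  expect_equal(as.character(r$category[1]), "Enriched")  # log2 2 = 1
  expect_equal(as.character(r$category[2]), "Depleted")  # log2 1/2 = -1
  expect_equal(as.character(r$category[3]), "Equal")
  expect_equal(as.character(r$category[4]), "Enriched")  # 1.2
  expect_equal(as.character(r$category[5]), "Depleted")  # -2
  expect_equal(r$log2fc[1], 1)
  # |log2FC| just under 1 stays Equal
  r2 <- classify_rara_peaks(0, 0.98)
  expect_equal(as.character(r2$category), "Equal")
  # negative input-subtracted counts are floored at 0
  r3 <- classify_rara_peaks(-5, 1)
  expect_equal(r3$log2fc, 1)
})

test_that("direct targets must be nearest gene of a peak and upregulated", {
  genes <- data.frame(
    gene_id = c("TFA", "PCG", "TFB", "TFC"),
    chrom = "chr1", tss = c(1000, 52000, 60000, 500000),
    is_tf = c(TRUE, FALSE, TRUE, TRUE),
    de_DEvsPE = c("up", "up", "up", "up"),
    stringsAsFactors = FALSE)
  # peak near TFA
  pk <- data.frame(chrom = "chr1", start = 2000, end = 2401)
  expect_equal(identify_direct_targets(pk, genes, "DEvsPE"), "TFA")
  # nearest gene is protein-coding non-TF: contributes nothing even
  # though a TF is second nearest
  pk2 <- data.frame(chrom = "chr1", start = 50000, end = 50401)
  expect_equal(length(identify_direct_targets(pk2, genes, "DEvsPE")), 0)
  # TF not upregulated -> excluded
  genes2 <- transform(genes, de_DEvsPE = c("no", "up", "up", "up"))
  expect_equal(length(identify_direct_targets(pk, genes2, "DEvsPE")), 0)
  # peak on a chromosome without genes -> skipped with warning
  pk3 <- rbind(pk, data.frame(chrom = "chrZ", start = 10, end = 400))
  expect_warning(res <- identify_direct_targets(pk3, genes, "DEvsPE"),
                 "chrZ")
  expect_equal(res, "TFA")
})

test_that("mediating distances take the minimum gap from footprint-bearing Gain peaks", {
  gp <- data.frame(chrom = "chr1", start = c(10000, 40000),
                   end = c(10400, 40400))
  fp <- data.frame(chrom = "chr1", start = c(10050, 40050),
                   end = c(10070, 40070), tf = c("S1", "S1"))
  tg <- data.frame(gene_id = c("TG1", "TG2"), chrom = "chr1",
                   tss = c(5000, 10200))
  md <- mediating_peak_distances(fp, gp, tg)
  expect_equal(md$distance[md$target == "TG1"], 5000)  # 10000 - 5000
  expect_equal(md$distance[md$target == "TG2"], 0)     # TSS inside peak
  # footprint outside any Gain peak contributes nothing
  fp2 <- data.frame(chrom = "chr1", start = 90000, end = 90020,
                    tf = "S2")
  expect_equal(nrow(mediating_peak_distances(fp2, gp, tg)), 0)
})

test_that("the 12-edge hand fixture reduces to its hand-enumerated 5-edge answer", {
  # Edge-by-edge: (1) T1->T2 0.9/10k keep+display; (2) T2->T3 0.8/30k
  # keep; (3) T3->T1 0.75/24999 keep+display (< 25 kb boundary);
  # (4) T1->T3 0.71/49999 keep (< 50 kb boundary); (5) T4->T5 0.95/1k
  # keep+display; (6) T1->T4 score 0.70 not > 0.7; (7) T2->T4 score
  # 0.65; (8) T1->T7 target TPM 3; (9) T7->T2 source TPM 3; (10)
  # T6->T2 source meets no activity criterion; (11) T2->T8 distance
  # 50000 not < 50 kb; (12) T8->T2 no mediating footprint.
  fx <- hand_network_fixture()
  net <- build_network(fx$edges, fx$tpm, fx$criteria, fx$med)
  kept <- paste(net$edges$source, net$edges$target)
  expect_setequal(kept, c("T1 T2", "T2 T3", "T3 T1", "T1 T3", "T4 T5"))
  expect_equal(nrow(net$edges), 5)
  disp <- paste(net$edges$source, net$edges$target)[net$edges$display]
  expect_setequal(disp, c("T1 T2", "T3 T1", "T4 T5"))
  # displayed edges are a subset of network edges by construction
  expect_true(all(net$edges$display %in% c(TRUE, FALSE)))
  expect_setequal(net$nodes, c("T1", "T2", "T3", "T4", "T5"))
  # missing annotation is an error
  expect_error(build_network(fx$edges, fx$tpm[-1], fx$criteria,
                             fx$med), "TPM")
})

test_that("planted network and direct targets are recovered exactly", {
  for (s in 1:3) {
    nw <- simulate_network_inputs(simulation_config(), seed = s)
    med <- mediating_peak_distances(nw$footprints, nw$gain_peaks,
                                    nw$tf_genes)
    net <- build_network(nw$edges, nw$tpm, nw$criteria, med)
    expect_setequal(paste(net$edges$source, net$edges$target),
                    paste(nw$truth$edges$source,
                          nw$truth$edges$target))
    expect_setequal(
      identify_direct_targets(nw$rara_peaks, nw$tf_genes, "DEvsPE"),
      nw$truth$direct_targets)
  }
})

test_that("RA-response categories partition TFs and honour forced entries", {
  cats <- categorize_ra_response(
    tfs = c("A", "B", "C"),
    direct_targets = c("A", "C"),
    up_expanded = c("A", "B"))
  expect_equal(as.character(cats[["A"]]), "RARA_direct_target")
  expect_equal(as.character(cats[["B"]]), "RA_responsive")
  # direct target not upregulated in the expanded contrast is demoted
  expect_equal(as.character(cats[["C"]]), "RA_non_responsive")
  expect_false(any(is.na(cats)))
  # forced addition of an external node with a fixed category
  cats2 <- categorize_ra_response(
    c("A"), c("A"), c("A"),
    forced = c(GBX2 = "RARA_direct_target"))
  expect_equal(as.character(cats2[["GBX2"]]), "RARA_direct_target")
  expect_setequal(names(cats2), c("A", "GBX2"))
})

test_that("GraphML export preserves edges and node attributes", {
  fx <- hand_network_fixture()
  net <- build_network(fx$edges, fx$tpm, fx$criteria, fx$med)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, f, node_attrs = data.frame(
    tf = net$nodes, ra_category = "RA_responsive"))
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), 5)
  expect_true("ra_category" %in% igraph::vertex_attr_names(g))
})
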