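test_that("simulation is fully reproducible from (config, seed)", {
  cfg <- small_config(seed = 99)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$genes, e2$genes)
  expect_identical(as.character(e1$seqs), as.character(e2$seqs))
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$chip$tracks[["chip_d2"]]$depth,
                   e2$chip$tracks[["chip_d2"]]$depth)
  expect_identical(e1$rna$counts, e2$rna$counts)
})

test_that("generated UTRs carry AREs exactly where ground truth says", {
  exp <- small_experiment()
  utr_ids <- names(exp$seqs)[endsWith(names(exp$seqs), "_utr3")]
  hits <- scan_ares(exp$seqs[utr_ids], "clustered")
  scanned <- sub("_utr3$", "", unique(hits$sequence_id))
  truth_pos <- names(exp$truth$are_status)[which(exp$truth$are_status)]
  expect_setequal(scanned, truth_pos)

  # are_fraction = 0 leaves no ATTTA pentamer anywhere
  cfg0 <- small_config(seed = 7, are_fraction = 0)
  ann <- simulate_annotation(cfg0)
  utrs <- ann$seqs[endsWith(names(ann$seqs), "_utr3")]
  expect_false(any(grepl("ATTTA", as.character(utrs))))
})

test_that("embedded smORFs are recovered exactly by the ORF finder", {
  exp <- small_experiment()
  lnc <- exp$seqs[endsWith(names(exp$seqs), "_lnc")]
  found <- find_smorfs(lnc, 10, 100)
  truth <- exp$truth$smorfs
  expect_equal(nrow(found), nrow(truth))
  found <- found[match(truth$transcript_id, found$transcript_id), ]
  expect_equal(found$start, truth$start)
  expect_equal(found$end, truth$end)
  expect_equal(found$n_codons, truth$n_codons)
})

test_that("zero-dispersion coverage equals the constructed means", {
  cfg <- sim_config(n_genes = 12, gene_length_range = c(900, 1200),
                    noise_dispersion = 0, n_chroms = 1, n_lncrna = 0,
                    archetype_fractions = c(initiation_only = 0,
                                            elongation_up = 0,
                                            elongation_down = 0,
                                            unresponsive = 1),
                    seed = 5)
  ann <- simulate_annotation(cfg)
  chip <- simulate_polii_coverage(ann$genes, ann$truth, cfg)
  # unresponsive world: every dDAVP track equals its vehicle partner
  expect_equal(chip$tracks$chip_d1$depth, chip$tracks$chip_v1$depth)
  # PPR : body depth ratio equals the configured pause peak height
  g <- ann$genes[1, ]
  occ <- region_occupancy(chip$tracks$chip_v1, g, ppr_len = 400)
  ppr_mean <- occ[["ppr"]] / 400
  body_mean <- occ[["beyond"]] / (gene_length(g) - 400)
  expect_equal(ppr_mean / body_mean, cfg$pause_peak_height, tolerance = 1e-9)
})

test_that("elongation effects scale beyond-PPR depth as constructed", {
  # zero-noise: exact; default noise: within sampling error over seeds
  for (disp in c(0, 0.05)) {
    ratios <- vapply(1:3, function(sd_) {
      cfg <- sim_config(n_genes = 30, gene_length_range = c(1200, 2000),
                        noise_dispersion = disp, n_chroms = 1,
                        n_lncrna = 0,
                        archetype_fractions = c(initiation_only = 0.4,
                                                elongation_up = 0.2,
                                                elongation_down = 0,
                                                unresponsive = 0.4),
                        elongation_effect_range = c(2, 2),
                        aqp2_effect_log2 = 2, seed = sd_)
      ann <- simulate_annotation(cfg)
      chip <- simulate_polii_coverage(ann$genes, ann$truth, cfg)
      gid <- names(ann$truth$archetype)[ann$truth$archetype ==
                                          "elongation_up"][1]
      g <- ann$genes[ann$genes$gene_id == gid, ]
      d <- region_occupancy(chip$tracks$chip_d1, g)[["beyond"]]
      v <- region_occupancy(chip$tracks$chip_v1, g)[["beyond"]]
      d / v
    }, numeric(1))
    tol <- if (disp == 0) 1e-9 else 0.15
    expect_equal(mean(ratios), 4, tolerance = tol)
  }
})

test_that("RNA counts respond only through elongation archetypes", {
  cfg <- small_config(seed = 21, noise_dispersion = 0)
  ann <- simulate_annotation(cfg)
  rna <- simulate_rna_counts(ann$genes, ann$truth, cfg)
  unresp <- names(ann$truth$archetype)[ann$truth$archetype ==
                                         "unresponsive"]
  ratio <- rna$counts[unresp, "rna_d1"] / rna$counts[unresp, "rna_v1"]
  expect_equal(unname(ratio), rep(1, length(unresp)))

  # aqp2-like gene recovers its +4.5 log2 effect at default noise
  cfg2 <- small_config(seed = 22)
  ann2 <- simulate_annotation(cfg2)
  rna2 <- simulate_rna_counts(ann2$genes, ann2$truth, cfg2)
  aqp <- ann2$truth$aqp2_like
  d <- rna2$counts[aqp, grepl("_d", colnames(rna2$counts))]
  v <- rna2$counts[aqp, grepl("_v", colnames(rna2$counts))]
  expect_lt(abs(mean(log2(d + 0.5)) - mean(log2(v + 0.5)) - 4.5), 0.5)
})

test_that("column sums follow configured library-size factors", {
  sf <- c(rep(1, 9), rep(2, 9))
  cfg <- small_config(seed = 31, rna_lib_factors = sf,
                      archetype_fractions = c(initiation_only = 0,
                                              elongation_up = 0,
                                              elongation_down = 0,
                                              unresponsive = 1))
  ann <- simulate_annotation(cfg)
  rna <- simulate_rna_counts(ann$genes, ann$truth, cfg)
  cs <- colSums(rna$counts)
  expect_equal(mean(cs[10:18]) / mean(cs[1:9]), 2, tolerance = 0.1)
})

test_that("a fixed chromosome length too small to fit the genes errors", {
  cfg <- small_config(seed = 1, chrom_length = 5000)
  expect_error(simulate_annotation(cfg), "genome too small")
})

test_that("config validation catches inconsistent worlds", {
  expect_error(sim_config(archetype_fractions = c(initiation_only = 0.5,
                                                  elongation_up = 0.2,
                                                  elongation_down = 0.1,
                                                  unresponsive = 0.1)),
               "sum to 1")
  expect_error(sim_config(ppr_effect = -1), "positive")
  expect_error(sim_config(noise_dispersion = -0.1), ">= 0")
})
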