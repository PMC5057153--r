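test_that("TPM follows the rate normalization and conserves column sums", {
  m <- matrix(c(100, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(m, c(1000, 4000))$tpm
  expect_equal(unname(tpm[, 1]), c(800000, 200000))

  one <- matrix(7, 1, 1, dimnames = list("g", "s"))
  expect_equal(unname(compute_tpm(one, 500)$tpm[1, 1]), 1e6)

  set.seed(2)
  counts <- matrix(rpois(60, 50), 20, 3,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  lens <- sample(200:5000, 20)
  tpm <- compute_tpm(counts, lens)$tpm
  expect_equal(unname(colSums(tpm)), rep(1e6, 3), tolerance = 1e-9)

  # scale invariance: doubling every count leaves the TPM column unchanged
  tpm2 <- compute_tpm(counts * 2, lens)$tpm
  expect_equal(tpm2, tpm)

  zero <- counts; zero[, 2] <- 0
  expect_error(compute_tpm(zero, lens), "all-zero")
})

test_that("region occupancy splits the gene body at the PPR", {
  v <- rep(1, 2000)
  g <- gene_models("g", "chr1", "+", 100, 1100)
  tr <- coverage_track(list(chr1 = v))
  expect_equal(region_occupancy(tr, g),
               c(full = 1000, ppr = 400, beyond = 600))

  # minus strand: PPR is the rightmost 400 bp; depth only on leftmost 100
  v2 <- numeric(2000); v2[101:200] <- 2
  gm <- gene_models("g", "chr1", "-", 100, 1100)
  tr2 <- coverage_track(list(chr1 = v2))
  occ <- region_occupancy(tr2, gm)
  expect_equal(occ, c(full = 200, ppr = 0, beyond = 200))

  # genes no longer than the PPR count wholly as PPR
  gs <- gene_models("g", "chr1", "+", 100, 400)
  occ3 <- region_occupancy(tr, gs)
  expect_equal(occ3[["ppr"]], occ3[["full"]])
  expect_equal(occ3[["beyond"]], 0)

  out <- gene_models("g", "chr1", "+", 1900, 2100)
  expect_error(region_occupancy(tr, out), "outside")
})

test_that("occupancy additivity and agreement with per-base oracle", {
  set.seed(11)
  tr <- random_track(chrom_len = 8000, n_runs = 120)
  n <- 60
  genes <- gene_models(
    sprintf("g%02d", 1:n), "chr1", sample(c("+", "-"), n, TRUE),
    start = s <- sample.int(6000, n), end = s + sample(100:1500, n)
  )
  occ <- occupancy_table(list(s1 = tr), genes)
  expect_equal(occ$full, occ$ppr + occ$beyond, tolerance = 1e-9)
  for (i in sample.int(n, 10)) {
    o <- oracle_region_sums(tr$depth$chr1, genes$start[i], genes$end[i],
                            genes$strand[i], 400)
    expect_equal(occ$full[i], o[["full"]])
    expect_equal(occ$ppr[i], o[["ppr"]])
  }
})

test_that("mirroring the genome and flipping strands changes nothing", {
  set.seed(13)
  L <- 5000
  tr <- random_track(chrom_len = L, n_runs = 60)
  n <- 25
  genes <- gene_models(
    sprintf("g%02d", 1:n), "chr1", sample(c("+", "-"), n, TRUE),
    start = s <- sample.int(3500, n), end = s + sample(150:1200, n)
  )
  mirror_genes <- gene_models(
    genes$gene_id, "chr1",
    ifelse(genes$strand == "+", "-", "+"),
    start = L - genes$end, end = L - genes$start
  )
  mirror_tr <- coverage_track(list(chr1 = rev(tr$depth$chr1)))
  occ <- occupancy_table(list(s = tr), genes)
  mocc <- occupancy_table(list(s = mirror_tr), mirror_genes)
  expect_equal(mocc$full, occ$full, tolerance = 1e-9)
  expect_equal(mocc$ppr, occ$ppr, tolerance = 1e-9)
  expect_equal(mocc$beyond, occ$beyond, tolerance = 1e-9)
})

test_that("metagene profile rescales bodies and orients by strand", {
  # constant depth stays flat at that constant (no normalization)
  v <- rep(3, 6000)
  tr <- coverage_track(list(chr1 = v))
  g <- gene_models("g", "chr1", "+", 2000, 4000)
  prof <- metagene_profile(list(s = tr), g, c(s = "vehicle"),
                           body_bins = 50, flank = 1000, normalize = FALSE)
  expect_equal(unique(prof$depth), 3)
  expect_equal(nrow(prof), 1000 + 50 + 1000)

  # signal confined to the first 400 bp of a 4000 bp gene lands in the
  # first 10% of body bins, whichever the strand
  for (strand in c("+", "-")) {
    v2 <- numeric(8000)
    g2 <- gene_models("g", "chr1", strand, 2000, 6000)
    if (strand == "+") v2[2001:2400] <- 5 else v2[5601:6000] <- 5
    tr2 <- coverage_track(list(chr1 = v2))
    p <- metagene_profile(list(s = tr2), g2, c(s = "x"), body_bins = 100,
                          flank = 1000, normalize = FALSE)
    body <- p$depth[p$zone == "body"]
    expect_true(all(body[1:10] > 0))
    expect_true(all(body[11:100] == 0))
  }
})

test_that("metagene of a single gene equals its own rescaled track", {
  set.seed(17)
  v <- numeric(5000); v[1501:3500] <- round(runif(2000, 0, 10), 1)
  tr <- coverage_track(list(chr1 = v))
  g <- gene_models("g", "chr1", "+", 1500, 3500)
  p <- metagene_profile(list(s = tr), g, c(s = "x"), body_bins = 40,
                        flank = 1000, normalize = FALSE)
  expect_equal(p$depth[p$zone == "body"],
               oracle_bin_body(v[1501:3500], 40))
  expect_equal(p$depth[p$zone == "upstream"], v[501:1500])

  short <- gene_models(c("g", "tiny"), "chr1", "+", c(1500, 100),
                       c(3500, 120))
  expect_warning(metagene_profile(list(s = tr), short, c(s = "x"),
                                  body_bins = 40, normalize = FALSE),
                 "skipped")
})
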