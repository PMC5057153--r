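test_that("empirical threshold is 2 x the median of pair SDs", {
  # build pairs whose log2 ratio SDs are exactly 0.1, 0.2, 0.4
  set.seed(4)
  n <- 200
  base <- rnorm(n)
  mk <- function(s) {
    r <- as.vector(scale(base)) * s     # sd exactly s
    2^r                                  # column a; column b is all ones
  }
  mat <- cbind(a1 = mk(0.1), b1 = 1, a2 = mk(0.2), b2 = 1,
               a3 = mk(0.4), b3 = 1)
  rownames(mat) <- paste0("g", 1:n)
  thr <- empirical_threshold(mat, list(c("a1", "b1"), c("a2", "b2"),
                                       c("a3", "b3")), pseudocount = 0)
  expect_equal(thr$se_cc, 0.2, tolerance = 1e-9)
  expect_equal(thr$ratio_threshold, 0.4, tolerance = 1e-9)

  # a sample compared with itself has SD 0
  thr0 <- empirical_threshold(mat, list(c("a1", "a1"), c("b1", "b1"),
                                        c("a2", "a2")))
  expect_equal(thr0$ratio_threshold, 0)
  expect_error(empirical_threshold(mat, list()), "at least one")
})

test_that("threshold grows with configured simulator noise", {
  thr_at <- function(disp) {
    median(vapply(1:3, function(sd_) {
      cfg <- small_config(seed = 100 + sd_, noise_dispersion = disp)
      ann <- simulate_annotation(cfg)
      rna <- simulate_rna_counts(ann$genes, ann$truth, cfg)
      tpm <- compute_tpm(filter_expressed(rna$counts),
                         setNames(gene_length(ann$genes),
                                  ann$genes$gene_id))$tpm
      empirical_threshold(tpm, make_cc_pairs(rna$design,
                                             "rna"))$ratio_threshold
    }, numeric(1)))
  }
  t_small <- thr_at(0.02); t_mid <- thr_at(0.1); t_big <- thr_at(0.4)
  expect_lt(t_small, t_mid)
  expect_lt(t_mid, t_big)
})

test_that("Welch RNA test agrees with stats::t.test and handles nulls", {
  set.seed(8)
  n <- 40
  mat <- matrix(rlnorm(n * 8, 4, 1), n, 8,
                dimnames = list(paste0("g", 1:n),
                                c(paste0("v", 1:4), paste0("d", 1:4))))
  design <- experiment_design(colnames(mat), "rna",
                              rep(c("vehicle", "ddavp"), each = 4), NA)
  res <- differential_test(mat, design, "rna", pseudocount = 0.5)
  for (i in c(1, 17, 40)) {
    lt <- t.test(log2(mat[i, 5:8] + 0.5), log2(mat[i, 1:4] + 0.5))
    expect_equal(res$p[i], lt$p.value, tolerance = 1e-12)
    expect_equal(res$effect[i], unname(diff(rev(lt$estimate))),
                 tolerance = 1e-12)
  }

  # identical groups: zero effect, t = 0, p = 1
  same <- cbind(mat[, 1:4], mat[, 1:4])
  colnames(same) <- design$sample_id
  res0 <- differential_test(same, design, "rna")
  expect_equal(res0$effect, rep(0, n))
  expect_equal(res0$p, rep(1, n))
})

test_that("paired ChIP test matches a one-sample t on pair ratios", {
  set.seed(9)
  n <- 30
  mat <- matrix(rlnorm(n * 6, 5, 0.7), n, 6,
                dimnames = list(paste0("g", 1:n),
                                c("v1", "d1", "v2", "d2", "v3", "d3")))
  design <- experiment_design(colnames(mat), "chip",
                              rep(c("vehicle", "ddavp"), 3),
                              rep(1:3, each = 2))
  res <- differential_test(mat, design, "chip", pseudocount = 0.5)
  expect_equal(res$n, rep(3, n))
  for (i in c(2, 15, 30)) {
    r <- log2((mat[i, c("d1", "d2", "d3")] + 0.5) /
                (mat[i, c("v1", "v2", "v3")] + 0.5))
    lt <- t.test(r)
    expect_equal(res$p[i], lt$p.value, tolerance = 1e-12)
    expect_equal(res$effect[i], unname(lt$estimate), tolerance = 1e-12)
  }
})

test_that("condition-label swap negates effects and preserves P values", {
  set.seed(10)
  mat <- matrix(rlnorm(50 * 6, 4, 1), 50, 6,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  design <- experiment_design(colnames(mat), "rna",
                              rep(c("vehicle", "ddavp"), each = 3), NA)
  swapped <- design
  swapped$condition <- ifelse(design$condition == "vehicle", "ddavp",
                              "vehicle")
  a <- differential_test(mat, design, "rna")
  b <- differential_test(mat, swapped, "rna")
  expect_equal(b$effect, -a$effect, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("null data give uniform-looking P values", {
  set.seed(12)
  n <- 600
  mat <- matrix(rnbinom(n * 18, size = 20, mu = 200), n, 18,
                dimnames = list(paste0("g", 1:n),
                                c(paste0("v", 1:9), paste0("d", 1:9))))
  design <- experiment_design(colnames(mat), "rna",
                              rep(c("vehicle", "ddavp"), each = 9), NA)
  res <- differential_test(compute_tpm(mat, rep(1000, n))$tpm, design, "rna")
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("volcano calls require both gates, strictly", {
  thr <- list(alpha = 0.05, ratio_threshold = 0.5)
  tbl <- data.frame(
    gene_id = c("aqp2like", "loud_ns", "at_threshold", "down"),
    effect = c(4.52, 3.0, 0.5, -1.2),
    se = 0.3, t = 1,
    p = c(1e-4, 0.2, 1e-4, 1e-3)
  )
  out <- classify_volcano(tbl, thr)
  expect_equal(out$call, c("up", "ns", "ns", "down"))

  # BH adjustment only tightens the significance gate
  out_bh <- classify_volcano(tbl, thr, adjust = "BH")
  expect_true(all(out_bh$call == "ns" | out$call != "ns"))
})

test_that("ratio_median is the exact sample median", {
  expect_equal(ratio_median(c(-1, 0, 1)), 0)
  expect_equal(ratio_median(c(0.2, 0.4, 0.9, 1.1)), 0.65)
  expect_equal(ratio_median(c(0.3, NA, Inf, 0.7)), 0.5)
  expect_error(ratio_median(numeric(0)), "no finite")
})
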