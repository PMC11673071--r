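test_that("QC removes cells outside the expressed-gene and mitochondrial bounds", {
  # 400 genes; cells expressing 150 / 300 / 300 genes
  v <- matrix(0, 400, 3)
  v[1:150, 1] <- 1
  v[1:300, 2] <- 1
  v[1:300, 3] <- 1
  x <- make_gem(v, genes = sprintf("G%03d", 1:400))
  meta <- data.frame(obs_id = obs_ids(x), pct_mito = c(0.01, 0.06, 0.01))
  out <- qc_filter(x, meta)
  expect_identical(obs_ids(out), "c03")  # c01 too few genes, c02 6% mito
  log <- attr(out, "qc_log")
  expect_equal(unname(log[c("below_min_genes", "high_mito", "retained")]),
               c(1, 1, 1))
  # boundary: exactly 5% mito fails ("less than 5%" retained)
  meta$pct_mito <- c(0.01, 0.05, 0.01)
  expect_identical(obs_ids(qc_filter(x, meta)), "c03")
  expect_error(qc_thresholds(300, 200), "min_genes")
})

test_that("mitochondrial fraction is computable from MT- prefixed genes", {
  v <- matrix(c(95, 5, 90, 10), 2)
  x <- make_gem(v, genes = c("G1", "MT-ND1"))
  out <- qc_filter(x, thresholds = qc_thresholds(1, 10, 0.07))
  expect_identical(obs_ids(out), "c01")  # c02 has 10% mito
})

test_that("CPM normalization scales columns to 1e6 and flags zero cells", {
  x <- make_gem(matrix(c(10, 999990, 1, 1, 0, 0), 2))
  cp <- cpm_normalize(x)
  expect_equal(cp$values[1, 1], 10)            # scale factor 1
  expect_equal(as.numeric(cp$values[, 2]), c(5e5, 5e5))
  expect_identical(cp$zero_obs, "c03")
  expect_identical(cp$layer, "cpm")
  validate_gem(cp)

  set.seed(42)
  big <- make_gem(matrix(rpois(100 * 50, 2), 100, 50),
                  genes = sprintf("G%03d", 1:100), obs = sprintf("c%03d", 1:50))
  cb <- cpm_normalize(big)
  cs <- colSums(cb$values)
  live <- !(obs_ids(cb) %in% cb$zero_obs)
  expect_true(all(abs(cs[live] - 1e6) <= 1e-6 * 1e6))
})

test_that("log transform is log2(x+1), invertible, and guards the pseudocount", {
  x <- make_gem(matrix(c(0, 3, 7, 1), 2), layer = "tpm")
  lg <- log_transform(x)
  expect_equal(lg$values[1, 1], 0)   # log2(0 + 1)
  expect_equal(lg$values[2, 1], 2)   # log2(3 + 1)
  expect_identical(lg$layer, "log_tpm")
  expect_equal(as.matrix(2^lg$values - 1), as.matrix(x$values), tolerance = 1e-9)
  expect_error(log_transform(x, pseudocount = 0), "pseudocount")
  expect_error(log_transform(make_gem(matrix(1, 1, 1))), "layer")
})

test_that("NP co-expression counting uses presence/absence and sums the layer", {
  v <- matrix(c(3, 1, 2, 50,
                0, 0, 0, 0), 4)
  x <- make_gem(v, genes = c("VGF", "SST", "TAC1", "GAPDH"))
  expect_warning(prof <- count_np_coexpression(x, c("VGF", "SST", "TAC1", "NPY")),
                 "NPY")
  expect_equal(prof$np_count, c(3L, 0L))
  expect_equal(prof$np_transcript_sum, c(6, 0))
  expect_error(count_np_coexpression(x, c("FOO", "BAR")), "none of the")

  panel10 <- make_gem(matrix(1, 10, 1), genes = sprintf("NPX%02d", 1:10))
  p10 <- count_np_coexpression(panel10, sprintf("NPX%02d", 1:10))
  expect_equal(p10$np_count, 10L)
  expect_equal(p10$np_transcript_sum, 10)
})

test_that("np_count depends only on the zero pattern (scale invariance)", {
  set.seed(5)
  v <- matrix(rpois(30 * 20, 0.5), 30, 20)
  x <- make_gem(v, genes = sprintf("NPY%02d", 1:30), obs = sprintf("c%02d", 1:20))
  panel <- sprintf("NPY%02d", 1:30)
  p1 <- count_np_coexpression(x, panel)
  p2 <- count_np_coexpression(make_gem(v * 7.3, genes = sprintf("NPY%02d", 1:30),
                                       obs = sprintf("c%02d", 1:20)), panel)
  expect_identical(p1$np_count, p2$np_count)
})

test_that("stratification matches the 0-1 / 2-5 / 6+ boundaries and partitions cells", {
  prof <- data.frame(obs_id = paste0("c", 1:7), np_count = c(0, 1, 2, 5, 6, 9, 40))
  s <- stratify(prof)
  expect_equal(as.character(s$stratum),
               c("low", "low", "mid", "mid", "high", "high", "high"))
  # partition property under arbitrary schemes
  set.seed(9)
  for (i in 1:20) {
    cuts <- sort(sample(0:10, 2))
    if (cuts[1] == cuts[2]) next
    sc <- stratum_scheme(cuts[1], cuts[2])
    cnt <- data.frame(obs_id = paste0("x", 1:50),
                      np_count = sample(0:15, 50, replace = TRUE))
    st <- stratify(cnt, sc)
    expect_equal(sum(table(st$stratum)), 50)
    expect_false(anyNA(st$stratum))
  }
})

test_that("Spearman correlation matches hand-derived values and reference code", {
  prof <- function(x, y) data.frame(obs_id = seq_along(x), np_count = x,
                                    np_transcript_sum = y)
  expect_equal(np_count_abundance_correlation(prof(1:3, c(10, 20, 30)))$estimate, 1)
  expect_equal(np_count_abundance_correlation(prof(1:3, c(2, 1, 3)))$estimate, 0.5)
  expect_equal(np_count_abundance_correlation(prof(1:3, c(30, 20, 10)))$estimate, -1)
  expect_error(np_count_abundance_correlation(prof(c(1, 1, 1), c(1, 2, 3))),
               "zero variance")

  # invariance under strictly monotone transform of either variable
  set.seed(21)
  x <- sample(0:8, 40, replace = TRUE)
  y <- x * 2 + rnorm(40)
  r1 <- np_count_abundance_correlation(prof(x, y))
  r2 <- np_count_abundance_correlation(prof(x, exp(y / 3)))
  expect_equal(r1$estimate, r2$estimate)
  expect_equal(r1$p_value, r2$p_value)

  # t-approximation path agrees with cor.test's t approximation
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(r1$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r1$p_value, ref$p.value, tolerance = 1e-10)

  # exact permutation path agrees with cor.test's exact null (no ties, n = 7)
  set.seed(3)
  xs <- rnorm(7); ys <- rnorm(7)
  mine <- npvuln:::spearman_test(xs, ys, "greater", exact_max = 9L)
  ref2 <- cor.test(xs, ys, method = "spearman", alternative = "greater",
                   exact = TRUE)
  expect_equal(mine$p_value, ref2$p.value, tolerance = 1e-12)
})

test_that("stratum proportions divide donor cell counts and sum to one", {
  prof <- stratify(data.frame(obs_id = paste0("c", 1:12),
                              np_count = c(rep(0, 7), 3, 3, 8, 0, 0)))
  meta <- data.frame(obs_id = paste0("c", 1:12),
                     donor_id = c(rep("d1", 10), "d2", "d2"),
                     condition = "CT")
  pr <- stratum_proportions(prof, meta)
  d1 <- pr[pr$donor_id == "d1", ]
  expect_equal(d1$proportion[match(c("low", "mid", "high"), d1$stratum)],
               c(0.7, 0.2, 0.1))
  d2 <- pr[pr$donor_id == "d2", ]
  expect_equal(d2$proportion[match(c("low", "mid", "high"), d2$stratum)],
               c(1, 0, 0))
  expect_equal(as.numeric(tapply(pr$proportion, pr$donor_id, sum)), c(1, 1))
  expect_equal(sum(pr$n_cells), 12L)

  meta2 <- rbind(meta, data.frame(obs_id = "ghost", donor_id = "d3",
                                  condition = "AD"))
  expect_warning(stratum_proportions(prof, meta2), "d3")
})

test_that("stratum-proportion comparison reproduces the exact rank-sum null", {
  rec <- data.frame(donor_id = paste0("d", 1:6),
                    condition = rep(c("CT", "AD"), each = 3),
                    stratum = "high",
                    n_cells = 1L,
                    proportion = c(0.30, 0.40, 0.35, 0.10, 0.05, 0.12))
  res <- compare_stratum_proportions(rec, "CT", "AD", "high", "greater")
  expect_equal(res$p_value, 1 / choose(6, 3))  # = 0.05, full separation

  same <- rec; same$proportion <- rep(c(0.2, 0.3, 0.25), 2)
  expect_equal(compare_stratum_proportions(same, "CT", "AD", "high",
                                           "two_sided")$p_value, 1)

  # label-swap symmetry: greater <-> less give identical p
  p1 <- compare_stratum_proportions(rec, "CT", "AD", "high", "greater")$p_value
  p2 <- compare_stratum_proportions(rec, "AD", "CT", "high", "less")$p_value
  expect_equal(p1, p2)

  expect_error(compare_stratum_proportions(rec, "CT", "MCI", "high"),
               "'MCI' absent")
})

test_that("exact rank-sum path agrees with brute-force enumeration (with ties)", {
  set.seed(33)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    # coarse values force ties
    x <- sample(1:4, nx, replace = TRUE) / 10
    y <- sample(1:4, ny, replace = TRUE) / 10
    for (alt in c("two_sided", "greater", "less")) {
      mine <- rank_sum_test(x, y, alt, exact_max = 0L)  # force enumeration
      expect_equal(mine$p_value, oracle_ranksum_p(x, y, alt), tolerance = 1e-12,
                   info = paste("rep", i, alt))
    }
  }
  # tie-free path additionally agrees with wilcox.test's exact p
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    mine <- rank_sum_test(x, y, "two_sided")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("donor subsampling is seeded, deterministic, and validates availability", {
  meta <- data.frame(donor_id = paste0("d", 1:8),
                     condition = rep(c("CT", "AD"), each = 4))
  expect_identical(subsample_donors(meta, 4, seed = 123),
                   meta$donor_id)  # exactly enough: input order
  big <- data.frame(donor_id = paste0("d", 1:40),
                    condition = rep(c("CT", "AD"), each = 20))
  s1 <- subsample_donors(big, 8, seed = 123)
  s2 <- subsample_donors(big, 8, seed = 123)
  expect_identical(s1, s2)
  expect_error(subsample_donors(meta, 5, seed = 1), "condition 'CT'")

  # different seeds give different selections essentially always
  diffs <- vapply(1:100, function(i) {
    !identical(subsample_donors(big, 8, seed = i),
               subsample_donors(big, 8, seed = i + 1000))
  }, logical(1))
  expect_gte(sum(diffs), 99)

  # caller RNG state is untouched
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(subsample_donors(big, 8, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})
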