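base_meta <- function(...) {
  defaults <- data.frame(sample_id = "s1", region = "Hippocampus",
                         age = 45, sex = "M", hardy = 1, rin = 7.2,
                         stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  defaults
}

test_that("aging exclusion filters match the stated rules, including boundaries", {
  m <- rbind(base_meta(sample_id = "ok"),
             base_meta(sample_id = "h3", hardy = 3),
             base_meta(sample_id = "r55", rin = 5.5),
             base_meta(sample_id = "r6", rin = 6),       # boundary: RIN must exceed 6
             base_meta(sample_id = "a25", age = 25),
             base_meta(sample_id = "abr", age = "20-29"),
             base_meta(sample_id = "nosex", sex = NA),
             base_meta(sample_id = "noage", age = NA))
  kept <- filter_aging_samples(m)
  expect_identical(kept$sample_id, "ok")
  log <- attr(kept, "filter_log")
  expect_equal(unname(log["hardy_3_4"]), 1)
  expect_equal(unname(log["low_rin"]), 2)
  expect_equal(unname(log["age_20_29"]), 2)
  expect_equal(unname(log["incomplete_metadata"]), 2)
  expect_warning(filter_aging_samples(base_meta(hardy = 4)), "no samples")
})

test_that("age brackets map to midpoints and numerics pass through", {
  expect_equal(age_to_numeric(c("60-69", "30-39")), c(64.5, 34.5))
  expect_equal(age_to_numeric(c(41, 59.5)), c(41, 59.5))
  expect_true(is.na(age_to_numeric("unknown")))
})

test_that("cumulative ADNP expression sums log2(TPM+1) per sample", {
  v <- matrix(c(3, 0), 1)
  x <- make_gem(v, layer = "tpm", genes = "VGF", obs = c("s1", "s2"))
  got <- cumulative_adnp_expression(x, "VGF")
  expect_equal(unname(got), c(2, 0))  # log2(3+1) = 2; log2(0+1) = 0

  set.seed(31)
  v5 <- matrix(rexp(5 * 4) * 20, 5, 4)
  x5 <- make_gem(v5, layer = "tpm", genes = paste0("ADNP", 1:5),
                 obs = paste0("s", 1:4))
  got5 <- cumulative_adnp_expression(x5, paste0("ADNP", 1:5))
  oracle <- colSums(log2(v5 + 1))
  expect_equal(unname(got5), unname(oracle), tolerance = 1e-12)

  expect_warning(both <- cumulative_adnp_expression(x5, c(paste0("ADNP", 1:5), "MISSING")),
                 "MISSING")
  expect_equal(unname(both), unname(oracle), tolerance = 1e-12)
  expect_error(cumulative_adnp_expression(x5, "NOPE"), "no ADNP genes")

  alt <- cumulative_adnp_expression(x5, paste0("ADNP", 1:5),
                                    aggregate = "log_of_sum")
  expect_equal(unname(alt), unname(log2(colSums(v5) + 1)), tolerance = 1e-12)
})

test_that("partial Spearman reduces to plain Spearman without informative covariates", {
  set.seed(51)
  y <- rnorm(40); age <- rnorm(40, 60, 10)
  plain <- npvuln:::spearman_test(y, age, "two_sided", exact_max = 0L)
  no_cov <- partial_spearman(y, age)
  const <- partial_spearman(y, age, data.frame(rin = rep(7, 40)))
  expect_equal(no_cov$estimate, plain$estimate, tolerance = 1e-12)
  expect_equal(const$estimate, plain$estimate, tolerance = 1e-12)
  expect_equal(no_cov$p_value, plain$p_value, tolerance = 1e-12)
})

test_that("partial Spearman is exact on monotone relationships and rank-invariant", {
  set.seed(52)
  age <- sample(30:79, 50)
  y <- exp(-0.05 * age)                 # strictly decreasing in age
  covs <- data.frame(rin = rnorm(50, 7.5), hardy = sample(0:2, 50, TRUE))
  r <- partial_spearman(y, age, covs)
  expect_equal(r$estimate, -1, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-12)

  y2 <- rnorm(50) + 0.05 * age
  r1 <- partial_spearman(y2, age, covs)
  r2 <- partial_spearman(exp(y2), age^3, covs)   # strictly monotone transforms
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)

  expect_error(partial_spearman(rep(1, 10), 1:10), "constant")
})

test_that("partial Spearman holds its nominal size under the null", {
  set.seed(60)
  reps <- 500
  rho <- p <- numeric(reps)
  for (i in seq_len(reps)) {
    n <- 200
    age <- sample(30:79, n, replace = TRUE)
    rin <- rnorm(n, 7.5, 0.8) + 0.01 * age
    y <- rnorm(n)                              # independent of age
    res <- partial_spearman(y, age, data.frame(rin = rin))
    rho[i] <- res$estimate; p[i] <- res$p_value
  }
  se <- sd(rho) / sqrt(reps)
  expect_lt(abs(mean(rho)), 2 * se + 1e-3)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("permutation p-values agree with the t approximation in regular cases", {
  set.seed(61)
  age <- sample(30:79, 80, replace = TRUE)
  y <- -0.03 * age + rnorm(80, 0, 1)
  covs <- data.frame(rin = rnorm(80, 7.5))
  pt_ <- partial_spearman(y, age, covs, p_method = "t")
  pp <- partial_spearman(y, age, covs, p_method = "permutation",
                         n_perm = 20000L, seed = 2L)
  expect_equal(pt_$estimate, pp$estimate)
  expect_lt(abs(pt_$p_value - pp$p_value), 0.02)
})

test_that("the per-region scan emits one record per qualifying region", {
  a <- generate_aging_cohort(aging_params(
    regions = data.frame(region = c("Hippocampus", "Cerebellum"),
                         trend = c("decline", "null")),
    n_per_region = 40L, exclusion_fraction = 0, seed = 77L))
  scan <- per_region_aging_scan(a$meta, a$matrix, default_adnp_list(),
                                min_n = 20L)
  expect_equal(sort(scan$regional$region), sort(c("Hippocampus", "Cerebellum")))
  expect_true(all(scan$regional$n == 40))
  expect_true(all(abs(scan$regional$partial_rho) <= 1))

  # single-region input -> single record
  single <- a$meta[a$meta$region == "Hippocampus", ]
  s1 <- per_region_aging_scan(single, a$matrix[, single$sample_id],
                              default_adnp_list(), min_n = 20L)
  expect_equal(nrow(s1$regional), 1L)

  # regions below the minimum n are skipped; all-too-small errors
  hip <- a$meta[a$meta$region == "Hippocampus", ]
  cer <- head(a$meta[a$meta$region == "Cerebellum", ], 25)
  uneven <- rbind(hip, cer)
  expect_warning(
    sw <- per_region_aging_scan(uneven, a$matrix[, uneven$sample_id],
                                default_adnp_list(), min_n = 30L),
    "skipped")
  expect_identical(sw$regional$region, "Hippocampus")
  expect_error(suppressWarnings(
    per_region_aging_scan(a$meta, a$matrix, default_adnp_list(), min_n = 500L)),
    "no region")
})

test_that("per-gene scanning flags ADNP genes in decline regions", {
  a <- generate_aging_cohort(aging_params(
    regions = data.frame(region = "Hippocampus", trend = "decline"),
    exclusion_fraction = 0, seed = 13L))
  scan <- per_region_aging_scan(a$meta, a$matrix, default_adnp_list(),
                                np_list = gene_list("np", c(default_adnp_list()$symbols,
                                                            sprintf("ONP%02d", 1:20))))
  pg <- scan$per_gene
  adnp_rows <- pg$gene %in% default_adnp_list()$symbols
  # declining genes should have mostly negative estimates; inert genes should not
  expect_gt(mean(pg$partial_rho[adnp_rows] < 0), 0.8)
  expect_lt(mean(pg$significant[!adnp_rows]), 0.3)
})
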