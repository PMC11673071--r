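# A small hand-built annotation used across these tests.
tiny_annotation <- function() {
  clusters <- data.frame(cluster_id = c("C1", "C2", "C3"),
                         total_cells = c(1000, 500, 800),
                         neurotransmitter = c("GABA", "GABA", NA),
                         subtype = c("s1", "s2", "s3"),
                         mtg_label = c("Inh L1", NA, NA),
                         stringsAsFactors = FALSE)
  adnp <- paste0("AD", 1:8)
  tags <- list(C1 = c(adnp[1:6], "X1", "X2"),      # AHNP: 6 ADNP, 2 non
               C2 = c(adnp[1:7]),                  # AHNP: 7 ADNP, 0 non
               C3 = c(adnp[1:2], "X1", "X2", "X3")) # not AHNP
  pct <- rbind(C1 = c(MEC = 40, LEC = 60, CB = 0),
               C2 = c(MEC = 20, LEC = 0, CB = 70),  # 10% shortfall
               C3 = c(MEC = 100, LEC = 0, CB = 0))
  map <- c(MEC = "cortex", LEC = "cortex", CB = "cerebellum")
  list(ann = cluster_annotation(clusters, tags, pct, map),
       adnp = adnp, np = c(adnp, "X1", "X2", "X3"))
}

test_that("tag splitting counts ADNP and non-ADNP members, excluding unknowns", {
  adnp <- paste0("A", 1:6); np <- c(adnp, "X1", "X2", "X3")
  got <- split_np_tags(c(adnp, "X1", "X2"), adnp, np)
  expect_equal(unname(got[c("adnp", "non_adnp")]), c(6L, 2L))
  expect_equal(as.integer(split_np_tags(character(), adnp, np)), c(0L, 0L))
  odd <- split_np_tags(c("A1", "WEIRD"), adnp, np)
  expect_equal(as.integer(odd), c(1L, 0L))
  expect_identical(attr(odd, "unknown_tags"), "WEIRD")
})

test_that("AHNP classification respects both boundaries and is monotone", {
  tt <- tiny_annotation()
  cls <- classify_ahnp(tt$ann, tt$adnp, tt$np)
  expect_identical(unname(cls), c(TRUE, TRUE, FALSE))

  # boundary decoys: (6,2) true, (6,3) false, (5,0) false
  mk <- function(a, n) {
    tags <- list(B = c(paste0("AD", seq_len(a)),
                       if (n) paste0("X", seq_len(n))))
    cl <- data.frame(cluster_id = "B", total_cells = 10)
    pct <- matrix(100, 1, 1, dimnames = list("B", "MEC"))
    classify_ahnp(cluster_annotation(cl, tags, pct, c(MEC = "cortex")),
                  tt$adnp, tt$np)[["B"]]
  }
  expect_true(mk(6, 2))
  expect_false(mk(6, 3))
  expect_false(mk(5, 0))

  # monotonicity: extra ADNP never un-classifies; extra non-ADNP never classifies
  set.seed(44)
  for (i in 1:30) {
    a <- sample(0:8, 1); n <- sample(0:3, 1)
    base <- mk(max(a, 1), n)
    if (a < 8) expect_true(!base || mk(a + 1, n))
    expect_true(base || !mk(max(a, 1), n))  # removing nothing: consistency
  }
})

test_that("regional estimates attribute cells proportionally without renormalizing", {
  tt <- tiny_annotation()
  est_d <- suppressMessages(
    estimate_regional_counts(tt$ann, tt$adnp, tt$np, level = "dissection"))
  expect_equal(est_d$ahnp_cell_estimate[est_d$region_or_dissection == "MEC"],
               1000 * 0.40 + 500 * 0.20)
  expect_equal(est_d$ahnp_cell_estimate[est_d$region_or_dissection == "LEC"], 600)
  expect_equal(est_d$ahnp_cell_estimate[est_d$region_or_dissection == "CB"], 350)
  # C2's 10% shortfall is left unassigned: totals sum to 1000 + 450
  expect_equal(sum(est_d$ahnp_cell_estimate), 1450)

  est_r <- suppressMessages(estimate_regional_counts(tt$ann, tt$adnp, tt$np))
  expect_equal(est_r$ahnp_cell_estimate[est_r$region_or_dissection == "cortex"],
               1100)
  # region totals equal the sum of their dissection totals
  expect_equal(sum(est_r$ahnp_cell_estimate), sum(est_d$ahnp_cell_estimate))

  # percentage sums above 100 are rejected at construction, naming the cluster
  bad_pct <- rbind(C1 = c(MEC = 60, LEC = 60))
  expect_error(cluster_annotation(data.frame(cluster_id = "C1", total_cells = 10),
                                  list(C1 = "AD1"), bad_pct,
                                  c(MEC = "cortex", LEC = "cortex")),
               "C1")
})

test_that("top-k ranking is stable with alphabetical tie-breaks", {
  rec <- data.frame(region_or_dissection = c("a", "b", "c"),
                    ahnp_cell_estimate = c(10, 30, 20),
                    n_contributing_clusters = 1L)
  expect_identical(rank_top_regions(rec, 2)$region_or_dissection, c("b", "c"))
  tie <- data.frame(region_or_dissection = c("zeta", "alpha"),
                    ahnp_cell_estimate = c(5, 5), n_contributing_clusters = 1L)
  expect_identical(rank_top_regions(tie, 2)$region_or_dissection,
                   c("alpha", "zeta"))
  expect_equal(nrow(rank_top_regions(rec, 99)), 3L)
})

test_that("dissection breakdown selects clusters by percentage rank and groups sums", {
  clusters <- data.frame(cluster_id = c("K1", "K2", "K3"),
                         total_cells = c(800, 1000, 1000),
                         neurotransmitter = c("GABA", "GABA", "GLUT"),
                         stringsAsFactors = FALSE)
  adnp <- paste0("AD", 1:8)
  tags <- list(K1 = adnp[1:6], K2 = adnp[1:7], K3 = adnp[1:6])
  # K1: MEC rank 1; K2: MEC rank 2; K3: MEC rank 4 (excluded at top 3)
  pct <- rbind(K1 = c(MEC = 50, D2 = 30, D3 = 20, D4 = 0),
               K2 = c(MEC = 10, D2 = 5, D3 = 3, D4 = 2),
               K3 = c(MEC = 10, D2 = 30, D3 = 30, D4 = 30))
  map <- setNames(rep("cortex", 4), c("MEC", "D2", "D3", "D4"))
  ann <- cluster_annotation(clusters, tags, pct, map)
  bd <- dissection_membership_breakdown(ann, "MEC", adnp, c(adnp, "X1"),
                                        top_n_dissections = 3)
  # K1 contributes 400, K2 contributes 100 attributed MEC cells, both GABA
  expect_identical(bd$group, "GABA")
  expect_equal(bd$cells, 500)
  expect_error(dissection_membership_breakdown(ann, "NOPE", adnp, c(adnp, "X1")),
               "known: MEC")
})

test_that("synthetic annotations are recovered exactly, decoys and all", {
  g <- generate_cluster_annotation(annotation_params())
  est <- suppressMessages(
    estimate_regional_counts(g$annotation, default_adnp_list(), default_np_panel()))
  planted <- g$truth$region_totals
  got <- setNames(est$ahnp_cell_estimate, est$region_or_dissection)
  expect_equal(got[names(planted)], planted)

  est_d <- suppressMessages(
    estimate_regional_counts(g$annotation, default_adnp_list(), default_np_panel(),
                             level = "dissection"))
  got_d <- setNames(est_d$ahnp_cell_estimate, est_d$region_or_dissection)
  expect_equal(got_d[names(g$truth$dissection_totals)],
               g$truth$dissection_totals)

  # planted ranking is recovered wherever totals are separated
  want <- names(sort(planted, decreasing = TRUE))
  expect_identical(rank_top_regions(est, length(want))$region_or_dissection, want)

  cls <- classify_ahnp(g$annotation, default_adnp_list(), default_np_panel())
  expect_true(all(cls[g$truth$ahnp_cluster_ids]))
  expect_false(any(cls[g$truth$decoy_cluster_ids]))
})

test_that("annotation CSV + map round-trips through the readers", {
  g <- generate_cluster_annotation(annotation_params(seed = 21L))
  d <- withr_like_tempdir()
  f <- file.path(d, "ann.csv"); fm <- file.path(d, "map.tsv")
  write_cluster_annotation(g$annotation, f, fm)
  back <- read_cluster_annotation(f, fm)
  e1 <- suppressMessages(
    estimate_regional_counts(g$annotation, default_adnp_list(), default_np_panel()))
  e2 <- suppressMessages(
    estimate_regional_counts(back, default_adnp_list(), default_np_panel()))
  expect_equal(e1, e2)
})
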