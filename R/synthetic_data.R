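# Seeded synthetic-data generators. Each generator is a pure function of its
# parameter object (seed included): identical parameters give identical
# output. Truth records carry the planted structure so downstream stages can
# be scored without re-deriving ground truth.

#' Default AD-associated neuropeptide (ADNP) panel (synthetic default)
#'
#' Eleven neuropeptide genes repeatedly reported as disrupted in AD
#' entorhinal cortex, used as the generators' default ADNP subset. Real
#' analyses should load their own curated list with [read_gene_list()].
#' @return a `gene_list`.
#' @export
default_adnp_list <- function() {
  gene_list("adnp_default",
            c("VGF", "SST", "TAC1", "NPY", "CHGA", "CHGB",
              "SCG2", "PENK", "PDYN", "CORT", "CCK"))
}

#' Default 100-gene neuropeptide panel (synthetic default)
#'
#' The 11 default ADNPs plus 89 synthetic NP symbols, mirroring the scale of
#' curated NP lists (~100 genes, ~80 expressed per brain region).
#' @return a `gene_list`.
#' @export
default_np_panel <- function() {
  gene_list("np_panel_default",
            c(default_adnp_list()$symbols, sprintf("NP%02d", 1:89)))
}

# --- single-cell generator ----------------------------------------------------

#' Parameters for the synthetic single-cell dataset
#'
#' Defaults encode the study conditions the analyses assume: two conditions
#' (control `CT`, affected `AD`) with 8 donors each and 400 neurons per
#' donor; 70% of cells expressing no NP; a truncated-geometric tail for
#' positive NP co-expression counts; per-NP expression whose mean grows with
#' the co-expression count (`coupling`), producing the strong positive rank
#' correlation between count and summed NP abundance; multiplicative
#' depletion of high-stratum cells in the affected condition
#' (`hnp_depletion`); ADNP-weighted NP identities for 6+ counts; and planted
#' two-fold differentially expressed background genes.
#'
#' @param n_donors_per_condition donors per condition.
#' @param cells_per_donor neurons per donor.
#' @param conditions condition labels; `affected_condition` names the one
#'   receiving depletion and the planted fold changes.
#' @param affected_condition see above.
#' @param np_panel,adnp_subset gene lists; the ADNP subset must lie in the
#'   panel.
#' @param background_genes number of non-NP genes (10 additional `MT-` genes
#'   are always appended for mitochondrial QC).
#' @param zero_np_fraction probability a cell expresses no NP.
#' @param np_count_tail geometric success probability for positive counts.
#' @param coupling strength linking np_count to per-NP expression mean.
#' @param base_mu,nb_size negative-binomial location/dispersion for NP genes.
#' @param hnp_depletion multiplicative reduction of P(high stratum) in the
#'   affected condition, in \[0, 1\].
#' @param adnp_weight sampling weight of ADNP identities for counts >= 6.
#' @param planted_deg named numeric of log2 fold changes
#'   (affected / control) planted on background genes; `NULL` plants
#'   ten 2-fold-up and ten 2-fold-down genes.
#' @param seed RNG seed.
#' @export
sc_params <- function(n_donors_per_condition = 8L,
                      cells_per_donor = 400L,
                      conditions = c("CT", "AD"),
                      affected_condition = "AD",
                      np_panel = default_np_panel(),
                      adnp_subset = default_adnp_list(),
                      background_genes = 500L,
                      zero_np_fraction = 0.70,
                      np_count_tail = 0.35,
                      coupling = 1.5,
                      base_mu = 2,
                      nb_size = 2,
                      hnp_depletion = 0.5,
                      adnp_weight = 5,
                      planted_deg = NULL,
                      seed = 42L) {
  np <- as_symbols(np_panel); adnp <- as_symbols(adnp_subset)
  if (!all(adnp %in% np)) stop_npv("adnp_subset must be contained in np_panel")
  for (f in c(zero_np_fraction, hnp_depletion))
    if (f < 0 || f > 1) stop_npv("fractions must lie in [0, 1]")
  if (np_count_tail <= 0 || np_count_tail >= 1)
    stop_npv("np_count_tail must be in (0, 1)")
  if (!affected_condition %in% conditions)
    stop_npv("affected_condition must be one of the conditions")
  if (is.null(planted_deg)) {
    bg <- sprintf("BG%03d", seq_len(min(20L, background_genes)))
    planted_deg <- if (length(bg))
      setNames(rep(c(1, -1), length.out = length(bg)), bg) else numeric()
  }
  structure(list(n_donors_per_condition = as.integer(n_donors_per_condition),
                 cells_per_donor = as.integer(cells_per_donor),
                 conditions = conditions,
                 affected_condition = affected_condition,
                 np_panel = np, adnp_subset = adnp,
                 background_genes = as.integer(background_genes),
                 zero_np_fraction = zero_np_fraction,
                 np_count_tail = np_count_tail,
                 coupling = coupling, base_mu = base_mu, nb_size = nb_size,
                 hnp_depletion = hnp_depletion, adnp_weight = adnp_weight,
                 planted_deg = planted_deg, seed = as.integer(seed)),
            class = "sc_params")
}

# Draw zero-inflated truncated-geometric NP co-expression counts.
.draw_np_counts <- function(n, zero_frac, tail_p, max_count) {
  cnt <- integer(n)
  pos <- runif(n) >= zero_frac
  k <- sum(pos)
  if (k) {
    draw <- 1L + rgeom(k, tail_p)
    while (any(draw > max_count))
      draw[draw > max_count] <- 1L + rgeom(sum(draw > max_count), tail_p)
    cnt[pos] <- draw
  }
  cnt
}

#' Generate the synthetic single-cell dataset
#'
#' See [sc_params()] for the generative model. Depletion is applied by
#' resampling: a high-count cell in the affected condition keeps its count
#' with probability `1 - hnp_depletion` and otherwise redraws it from the
#' base distribution truncated to the mid/low range, so per-donor cell
#' totals stay fixed and only the stratum proportions shift.
#'
#' @param params an [sc_params()].
#' @param high_threshold counts at or above this are "high" (default 6,
#'   matching the default [stratum_scheme()]).
#' @return list: `matrix` (raw-counts [gem], genes x cells), `meta`
#'   (data.frame: `obs_id`, `donor_id`, `condition`, `braak_stage`,
#'   `cell_type`, `pct_mito`), `truth` (per-cell `np_count`, `stratum`,
#'   planted fold changes, parameters).
#' @export
generate_sc_dataset <- function(params = sc_params(), high_threshold = 6L) {
  stopifnot(inherits(params, "sc_params"))
  p <- params
  n_np <- length(p$np_panel)
  if (n_np < high_threshold)
    stop_npv("np_panel smaller than the high-count threshold")
  with_seed(p$seed, {
    donors <- unlist(lapply(p$conditions, function(cc)
      paste0(cc, seq_len(p$n_donors_per_condition))))
    donor_cond <- rep(p$conditions, each = p$n_donors_per_condition)
    n_cells <- length(donors) * p$cells_per_donor
    cell_donor <- rep(donors, each = p$cells_per_donor)
    cell_cond <- rep(donor_cond, each = p$cells_per_donor)
    obs <- sprintf("cell%05d_%s", seq_len(n_cells), cell_donor)

    cnt <- .draw_np_counts(n_cells, p$zero_np_fraction, p$np_count_tail, n_np)
    # depletion: affected high-count cells resampled into the low/mid range
    hit <- which(cell_cond == p$affected_condition & cnt >= high_threshold &
                   runif(n_cells) < p$hnp_depletion)
    for (i in hit) {
      repeat {
        d <- .draw_np_counts(1L, p$zero_np_fraction, p$np_count_tail, n_np)
        if (d < high_threshold) { cnt[i] <- d; break }
      }
    }

    # NP expression block: identities ADNP-weighted for high counts,
    # values shifted negative binomial (>= 1 so presence matches the count)
    w_base <- rep(1, n_np); names(w_base) <- p$np_panel
    w_high <- w_base; w_high[p$adnp_subset] <- p$adnp_weight
    trip_i <- vector("list", n_cells); trip_x <- vector("list", n_cells)
    for (j in seq_len(n_cells)) {
      if (cnt[j] == 0L) next
      w <- if (cnt[j] >= high_threshold) w_high else w_base
      genes_j <- sample.int(n_np, cnt[j], prob = w)
      mu <- p$base_mu * (1 + p$coupling * cnt[j])
      trip_i[[j]] <- genes_j
      trip_x[[j]] <- 1 + rnbinom(cnt[j], mu = mu, size = p$nb_size)
    }
    lens <- lengths(trip_i)
    np_block <- matrix(0, n_np, n_cells, dimnames = list(p$np_panel, obs))
    if (any(lens > 0))
      np_block[cbind(unlist(trip_i), rep(seq_len(n_cells), lens))] <- unlist(trip_x)

    blocks <- list(np_block)
    if (p$background_genes > 0) {
      bg_names <- sprintf("BG%03d", seq_len(p$background_genes))
      lambda <- exp(rnorm(p$background_genes, log(3), 0.5))
      mu_mat <- matrix(lambda, p$background_genes, n_cells)
      planted <- intersect(names(p$planted_deg), bg_names)
      if (length(planted)) {
        aff <- cell_cond == p$affected_condition
        mu_mat[match(planted, bg_names), aff] <-
          mu_mat[match(planted, bg_names), aff] * 2^p$planted_deg[planted]
      }
      bg <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = p$nb_size),
                   p$background_genes, n_cells,
                   dimnames = list(bg_names, obs))
      blocks <- c(blocks, list(bg))
    }
    n_mito <- 10L
    mito <- matrix(rnbinom(n_mito * n_cells, mu = 4, size = p$nb_size),
                   n_mito, n_cells,
                   dimnames = list(sprintf("MT-G%02d", seq_len(n_mito)), obs))
    blocks <- c(blocks, list(mito))
    m <- Matrix(do.call(rbind, blocks), sparse = TRUE)

    tot <- colSums(m)
    pct_mito <- ifelse(tot == 0, 0, colSums(mito) / tot)
    meta <- data.frame(obs_id = obs, donor_id = cell_donor,
                       condition = cell_cond,
                       braak_stage = NA_integer_,
                       cell_type = "neuron",
                       pct_mito = as.numeric(pct_mito),
                       stringsAsFactors = FALSE)
    scheme <- stratum_scheme(1L, high_threshold - 1L)
    truth <- list(np_count = setNames(cnt, obs),
                  stratum = setNames(
                    ifelse(cnt <= scheme$low_max, "low",
                           ifelse(cnt <= scheme$mid_max, "mid", "high")), obs),
                  planted_deg = p$planted_deg,
                  affected_condition = p$affected_condition,
                  params = p)
    list(matrix = gem(m, "raw_counts"), meta = meta, truth = truth)
  })
}

# --- aging cohort generator ---------------------------------------------------

#' Parameters for the synthetic bulk aging cohort
#'
#' Defaults emulate an 11-region brain survey with four regions carrying a
#' genuine age-related decline of cumulative ADNP expression (hippocampus,
#' frontal cortex, anterior cingulate cortex, amygdala) and seven null
#' regions, 103 clean samples per region (decade age brackets 30-79), RIN
#' and Hardy covariates with optional RIN-age confounding, and a planted
#' fraction of filter violators of each kind so the exclusion rules are
#' exercised.
#'
#' @param regions data.frame with columns `region` and `trend`
#'   (`"decline"` or `"null"`).
#' @param n_per_region clean (post-filter) samples per region.
#' @param age_brackets decade labels to draw from.
#' @param decline_slope cumulative log2 expression change per year in
#'   decline regions (negative).
#' @param noise_sd sample-level sd of cumulative log2 expression.
#' @param gene_noise_sd per-gene residual sd.
#' @param rin_effect,hardy_effect covariate effects on the cumulative
#'   log2 scale.
#' @param covariate_confounding target correlation of RIN with age.
#' @param hardy_probs probabilities of Hardy scores 0-4 (clean samples are
#'   drawn from 0-2 renormalized; violators from 3-4).
#' @param exclusion_fraction per violation type, fraction of `n_per_region`
#'   added as planted filter violators.
#' @param adnp_list ADNP genes; `n_other_np`/`n_background` sizes of the
#'   non-ADNP NP and background blocks.
#' @param n_other_np,n_background see above.
#' @param seed RNG seed.
#' @export
aging_params <- function(regions = NULL,
                         n_per_region = 103L,
                         age_brackets = c("30-39", "40-49", "50-59", "60-69", "70-79"),
                         decline_slope = -0.045,
                         noise_sd = 1.2,
                         gene_noise_sd = 0.15,
                         rin_effect = 0.3,
                         hardy_effect = -0.2,
                         covariate_confounding = 0.3,
                         hardy_probs = c(0.25, 0.35, 0.25, 0.10, 0.05),
                         exclusion_fraction = 0.05,
                         adnp_list = default_adnp_list(),
                         n_other_np = 20L,
                         n_background = 20L,
                         seed = 7L) {
  if (is.null(regions))
    regions <- data.frame(
      region = c("Hippocampus", "Frontal cortex (BA9)",
                 "Anterior cingulate cortex (BA24)", "Amygdala",
                 "Hypothalamus", "Caudate basal ganglia",
                 "Nucleus accumbens basal ganglia", "Putamen basal ganglia",
                 "Substantia nigra", "Cerebellar hemisphere", "Cerebellum"),
      trend = c(rep("decline", 4), rep("null", 7)),
      stringsAsFactors = FALSE)
  stopifnot(all(regions$trend %in% c("decline", "null")))
  if (abs(sum(hardy_probs) - 1) > 1e-9) stop_npv("hardy_probs must sum to 1")
  structure(list(regions = regions, n_per_region = as.integer(n_per_region),
                 age_brackets = age_brackets, decline_slope = decline_slope,
                 noise_sd = noise_sd, gene_noise_sd = gene_noise_sd,
                 rin_effect = rin_effect, hardy_effect = hardy_effect,
                 covariate_confounding = covariate_confounding,
                 hardy_probs = hardy_probs,
                 exclusion_fraction = exclusion_fraction,
                 adnp_list = as_symbols(adnp_list),
                 n_other_np = as.integer(n_other_np),
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "aging_params")
}

#' Generate the synthetic bulk aging cohort
#'
#' Decline regions receive cumulative ADNP log2 expression decreasing with
#' age at `decline_slope` (plus RIN/Hardy effects and noise), shared equally
#' across the ADNP genes; null regions have no age trend; non-ADNP NPs and
#' background genes never trend. Planted filter violators (one block per
#' exclusion rule) are appended and recorded in the truth.
#'
#' @param params an [aging_params()].
#' @return list: `matrix` (a `tpm` [gem], genes x samples), `meta`
#'   (`sample_id`, `subject_id`, `region`, `age` bracket, `sex`, `hardy`,
#'   `rin`), `truth` (violators, per-region trend, params).
#' @export
generate_aging_cohort <- function(params = aging_params()) {
  stopifnot(inherits(params, "aging_params"))
  p <- params
  with_seed(p$seed, {
    genes_adnp <- p$adnp_list
    genes_np <- sprintf("ONP%02d", seq_len(p$n_other_np))
    genes_bg <- sprintf("BGENE%02d", seq_len(p$n_background))
    genes <- c(genes_adnp, genes_np, genes_bg)
    mu_g <- setNames(runif(length(genes), 3, 6), genes)

    n_viol <- if (p$exclusion_fraction > 0)
      max(1L, round(p$exclusion_fraction * p$n_per_region)) else 0L
    meta_rows <- list(); expr_cols <- list(); viol_rows <- list()
    sample_counter <- 0L

    make_samples <- function(region, trend, n, violation) {
      ids <- sprintf("S%05d", sample_counter + seq_len(n))
      sample_counter <<- sample_counter + n
      bracket <- if (violation == "age_20_29") rep("20-29", n)
                 else sample(p$age_brackets, n, replace = TRUE)
      agev <- age_to_numeric(bracket)
      # RIN correlated with age; clean values strictly above 6
      z <- rnorm(n)
      age_std <- (agev - 54.5) / 14.5
      rin_raw <- 7.8 - p$covariate_confounding * age_std * 0.8 +
        sqrt(max(0, 1 - p$covariate_confounding^2)) * 0.8 * z
      rin <- pmin(10, pmax(6.1, rin_raw))
      hardy <- sample(0:2, n, replace = TRUE,
                      prob = p$hardy_probs[1:3] / sum(p$hardy_probs[1:3]))
      sex <- sample(c("M", "F"), n, replace = TRUE)
      if (violation == "hardy_3_4")
        hardy <- sample(3:4, n, replace = TRUE,
                        prob = p$hardy_probs[4:5] / sum(p$hardy_probs[4:5]))
      if (violation == "low_rin") rin <- runif(n, 4.5, 6)
      if (violation == "missing_sex") sex <- rep(NA_character_, n)

      slope <- if (trend == "decline") p$decline_slope else 0
      shared <- slope * (agev - 54.5) + p$rin_effect * (rin - 7.8) +
        p$hardy_effect * hardy + rnorm(n, 0, p$noise_sd)
      n_adnp <- length(genes_adnp)
      x_adnp <- outer(mu_g[genes_adnp], shared / n_adnp, `+`) +
        matrix(rnorm(n_adnp * n, 0, p$gene_noise_sd), n_adnp, n)
      x_rest <- matrix(mu_g[c(genes_np, genes_bg)],
                       length(genes_np) + length(genes_bg), n) +
        matrix(rnorm((length(genes_np) + length(genes_bg)) * n, 0,
                     p$gene_noise_sd + 0.2),
               length(genes_np) + length(genes_bg), n)
      tpm <- pmax(2^rbind(x_adnp, x_rest) - 1, 0)
      dimnames(tpm) <- list(genes, ids)
      meta_rows[[length(meta_rows) + 1L]] <<- data.frame(
        sample_id = ids, subject_id = ids, region = region,
        age = bracket, sex = sex, hardy = hardy, rin = rin,
        stringsAsFactors = FALSE)
      expr_cols[[length(expr_cols) + 1L]] <<- tpm
      if (violation != "none")
        viol_rows[[length(viol_rows) + 1L]] <<- data.frame(
          sample_id = ids, reason = violation, stringsAsFactors = FALSE)
      invisible(NULL)
    }

    for (r in seq_len(nrow(p$regions))) {
      rg <- p$regions$region[r]; tr <- p$regions$trend[r]
      make_samples(rg, tr, p$n_per_region, "none")
      for (v in c("missing_sex", "hardy_3_4", "low_rin", "age_20_29"))
        if (n_viol > 0) make_samples(rg, tr, n_viol, v)
    }
    meta <- do.call(rbind, meta_rows)
    tpm <- do.call(cbind, expr_cols)
    truth <- list(violators = do.call(rbind, viol_rows),
                  regions = p$regions, params = p)
    list(matrix = gem(tpm, "tpm"), meta = meta, truth = truth)
  })
}

# --- cluster annotation generator --------------------------------------------

#' Parameters for the synthetic cluster-annotation table
#'
#' Defaults plant AHNP cell totals mirroring (at one tenth the scale) the
#' ranking observed in whole-brain atlas annotations: cerebral cortex >>
#' amygdala > basal forebrain > hippocampus > hypothalamus, with the MEC the
#' dominant cortical dissection and near-zero cerebellar counts. Decoy
#' clusters each violate exactly one AHNP criterion (5 ADNPs, or 3
#' non-ADNPs) to probe the classification boundaries.
#'
#' @param regions_with_dissections named list: region -> dissection labels.
#' @param planted_ahnp_regions named numeric: region -> target AHNP cell
#'   total (multiples of 10 keep percentage attribution exact).
#' @param max_cluster_cells largest planted cluster (chunking granularity).
#' @param n_filler non-AHNP filler clusters.
#' @param tag_noise probability a cluster gains an irrelevant (non-NP) tag.
#' @param np_panel,adnp_subset the NP universe.
#' @param seed RNG seed.
#' @export
annotation_params <- function(regions_with_dissections = NULL,
                              planted_ahnp_regions = NULL,
                              max_cluster_cells = 3000L,
                              n_filler = 12L,
                              tag_noise = 0.1,
                              np_panel = default_np_panel(),
                              adnp_subset = default_adnp_list(),
                              seed = 11L) {
  if (is.null(regions_with_dissections))
    regions_with_dissections <- list(
      "cerebral cortex" = c("MEC", "M1C", "MTG", "LEC", "A40"),
      "amygdala" = c("CeA", "BLA"),
      "basal forebrain" = c("NBM", "SI"),
      "hippocampus" = c("CA1", "DG"),
      "hypothalamus" = c("HTHma", "HTHtub"),
      "cerebellum" = c("CBV"))
  if (is.null(planted_ahnp_regions))
    planted_ahnp_regions <- c("cerebral cortex" = 21810, "amygdala" = 7230,
                              "basal forebrain" = 4560, "hippocampus" = 4090,
                              "hypothalamus" = 2320, "cerebellum" = 40)
  if (any(planted_ahnp_regions < 0)) stop_npv("planted totals must be >= 0")
  if (!all(names(planted_ahnp_regions) %in% names(regions_with_dissections)))
    stop_npv("planted regions must appear in regions_with_dissections")
  if (any(planted_ahnp_regions %% 10 != 0))
    stop_npv("planted totals must be multiples of 10 for exact attribution")
  structure(list(regions_with_dissections = regions_with_dissections,
                 planted_ahnp_regions = planted_ahnp_regions,
                 max_cluster_cells = as.integer(max_cluster_cells),
                 n_filler = as.integer(n_filler),
                 tag_noise = tag_noise,
                 np_panel = as_symbols(np_panel),
                 adnp_subset = as_symbols(adnp_subset),
                 seed = as.integer(seed)),
            class = "annotation_params")
}

# Random percentages over d dissections, multiples of 10 summing to 100,
# weighted toward the first dissection.
.random_pct_split <- function(d) {
  if (d == 1) return(100)
  repeat {
    w <- c(3, rep(1, d - 1)) * runif(d, 0.5, 1.5)
    raw <- round(10 * w / sum(w)) * 10
    raw[1] <- raw[1] + (100 - sum(raw))
    if (all(raw >= 0) && sum(raw) == 100) return(raw)
  }
}

#' Generate a synthetic cluster-annotation table with planted AHNP totals
#'
#' Planted AHNP clusters (6-9 ADNP tags, 0-2 non-ADNP tags) are distributed
#' across each planted region's dissections with multiple-of-10 percentages
#' and multiple-of-10 cell totals, so [estimate_regional_counts()] recovers
#' the planted per-region totals exactly. Boundary decoys (5 ADNPs/0 non;
#' 6 ADNPs/3 non; 5 ADNPs/3 non) and non-AHNP filler clusters add cells that
#' must not be counted.
#'
#' @param params an [annotation_params()].
#' @return list: `annotation` (a [cluster_annotation()]), `truth`
#'   (planted per-region and per-dissection totals, AHNP/decoy cluster ids,
#'   params).
#' @export
generate_cluster_annotation <- function(params = annotation_params()) {
  stopifnot(inherits(params, "annotation_params"))
  p <- params
  with_seed(p$seed, {
    adnp <- p$adnp_subset
    non_adnp <- setdiff(p$np_panel, adnp)
    all_diss <- unlist(p$regions_with_dissections, use.names = FALSE)
    diss_region <- setNames(
      rep(names(p$regions_with_dissections),
          lengths(p$regions_with_dissections)), all_diss)

    rows <- list(); tag_list <- list(); pct_rows <- list()
    diss_truth <- setNames(numeric(length(all_diss)), all_diss)
    cid <- 0L
    add_cluster <- function(tags, cells, pct_named, nt, subtype, mtg) {
      cid <<- cid + 1L
      id <- sprintf("C%03d", cid)
      rows[[id]] <<- data.frame(cluster_id = id, total_cells = cells,
                                neurotransmitter = nt, subtype = subtype,
                                mtg_label = mtg, stringsAsFactors = FALSE)
      tag_list[[id]] <<- tags
      v <- setNames(numeric(length(all_diss)), all_diss)
      v[names(pct_named)] <- pct_named
      pct_rows[[id]] <<- v
      id
    }
    ahnp_tags <- function() {
      k_adnp <- sample(6:9, 1); k_non <- sample(0:2, 1)
      tg <- c(sample(adnp, k_adnp), if (k_non) sample(non_adnp, k_non))
      if (runif(1) < p$tag_noise) tg <- c(tg, "XXNOISEPEP")
      tg
    }

    ahnp_ids <- character()
    for (rg in names(p$planted_ahnp_regions)) {
      total <- p$planted_ahnp_regions[[rg]]
      if (total == 0) next
      diss <- p$regions_with_dissections[[rg]]
      remaining <- total
      while (remaining > 0) {
        cells <- min(remaining, p$max_cluster_cells)
        cells <- max(10, floor(cells / 10) * 10)
        remaining <- remaining - cells
        split <- .random_pct_split(length(diss))
        names(split) <- diss
        id <- add_cluster(ahnp_tags(), cells, split,
                          nt = sample(c("GABA", "GLUT"), 1, prob = c(0.7, 0.3)),
                          subtype = sample(c("SST-interneuron", "PVALB-interneuron",
                                             "L2-IT", "uncharacterized"), 1),
                          mtg = sample(c("Inh L1-2", "Inh L3-5", "Exc L2-3",
                                         NA_character_), 1))
        ahnp_ids <- c(ahnp_ids, id)
        diss_truth[diss] <- diss_truth[diss] + cells * split / 100
      }
    }

    # boundary decoys: each violates exactly one criterion
    decoy_defs <- list(c(a = 5, n = 0), c(a = 6, n = 3), c(a = 5, n = 3))
    decoy_ids <- vapply(decoy_defs, function(d) {
      tg <- c(sample(adnp, d[["a"]]), if (d[["n"]]) sample(non_adnp, d[["n"]]))
      diss <- p$regions_with_dissections[[1]]
      split <- .random_pct_split(length(diss)); names(split) <- diss
      add_cluster(tg, 5000, split, "GABA", "decoy", NA_character_)
    }, character(1))

    for (i in seq_len(p$n_filler)) {
      tg <- c(sample(adnp, sample(0:2, 1)), sample(non_adnp, sample(3:8, 1)))
      rg <- sample(names(p$regions_with_dissections), 1)
      diss <- p$regions_with_dissections[[rg]]
      split <- .random_pct_split(length(diss)); names(split) <- diss
      add_cluster(tg, sample(10:200, 1) * 10, split,
                  sample(c("GABA", "GLUT", "DOP"), 1), "filler", NA_character_)
    }

    clusters <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    pct <- do.call(rbind, pct_rows)
    rownames(pct) <- clusters$cluster_id
    ann <- cluster_annotation(clusters, tag_list, pct, diss_region)
    region_truth <- p$planted_ahnp_regions
    truth <- list(region_totals = region_truth,
                  dissection_totals = diss_truth,
                  ahnp_cluster_ids = ahnp_ids,
                  decoy_cluster_ids = decoy_ids,
                  params = p)
    list(annotation = ann, truth = truth)
  })
}
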