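# Orchestration of the three analyses - function (mechanism), time
# (progression/aging), space (regional abundance) - from a single declarative
# config, with per-stage logging and a machine-readable JSON run report.
#
# Config entries may be in-memory objects (gem, data.frame, gene_list,
# cluster_annotation) or file paths; paths are resolved through the io
# readers, so the same config works from R or from disk.

resolve_matrix <- function(cfg) {
  if (inherits(cfg, "gem")) return(cfg)
  if (is.list(cfg) && !is.null(cfg$mtx))
    return(read_matrix_market(cfg$mtx, cfg$features, cfg$barcodes))
  if (is.character(cfg) && length(cfg) == 1)
    return(read_dense_table(cfg, layer = "raw_counts"))
  stop_npv("cannot resolve a matrix from the given config entry")
}

resolve_meta <- function(cfg) {
  if (is.data.frame(cfg)) return(cfg)
  if (is.character(cfg)) return(read_metadata_table(cfg))
  stop_npv("cannot resolve metadata from the given config entry")
}

resolve_genes <- function(cfg, name) {
  if (inherits(cfg, "gene_list")) return(cfg)
  if (is.character(cfg) && length(cfg) == 1 && file.exists(cfg))
    return(read_gene_list(cfg, name))
  if (is.character(cfg)) return(gene_list(name, cfg))
  stop_npv("cannot resolve gene list '", name, "'")
}

new_report <- function(config) {
  # echo only the scalar/path parts of the config; in-memory objects are
  # summarized by their class
  echo <- lapply(config, function(v) {
    if (is.atomic(v)) v
    else if (inherits(v, c("stratum_scheme", "qc_thresholds", "dge_filter",
                           "ahnp_criteria"))) unclass(v)
    else paste0("<", class(v)[1], ">")
  })
  list(package_version = as.character(packageVersion("npvuln")),
       config = echo,
       stages = list(), files = character(), skipped = list())
}

add_stage <- function(report, name, info, elapsed) {
  report$stages[[name]] <- c(info, list(seconds = round(elapsed, 3)))
  report
}

finish_report <- function(report, out_dir) {
  path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  report$files <- c(report$files, path)
  report
}

timed <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  val <- expr
  list(value = val, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the mechanistic (function) analysis
#'
#' Executes, in order: cell QC, CPM normalization, log transform, NP
#' co-expression counting on raw counts, stratification, count-abundance
#' Spearman correlation, donor stratum proportions, differential expression
#' (high vs low in the control condition; mid control vs mid affected),
#' regression of the HNP-elevated genes on the NP count, and the
#' hypergeometric overlap of HNP-elevated genes with AD-decreased genes.
#' Degenerate inputs (an empty DGE group) skip that contrast with a logged
#' reason instead of aborting.
#'
#' @param config list with entries `matrix` (gem or paths), `meta`,
#'   `np_list`, and optionally `control_condition` (default `"CT"`),
#'   `affected_condition` (`"AD"`), `scheme`, `qc`, `dge` filter, `alpha`
#'   (0.05), `out_dir`.
#' @return the run report, invisibly; result files are written to `out_dir`.
#' @export
run_function_analysis <- function(config) {
  out_dir <- config$out_dir %||% stop_npv("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- config$scheme %||% stratum_scheme()
  qc <- config$qc %||% qc_thresholds()
  filt <- config$dge %||% dge_filter()
  alpha <- config$alpha %||% 0.05
  ctl <- config$control_condition %||% "CT"
  aff <- config$affected_condition %||% "AD"
  np <- resolve_genes(config$np_list, "np")
  report <- new_report(config)

  x <- resolve_matrix(config$matrix)
  meta <- resolve_meta(config$meta)

  st <- timed(qc_filter(x, meta, qc))
  xq <- st$value
  report <- add_stage(report, "qc", as.list(attr(xq, "qc_log")), st$seconds)

  st <- timed(log_transform(cpm_normalize(xq)))
  xl <- st$value
  report <- add_stage(report, "normalize",
                      list(cells = ncol(xl$values),
                           zero_cells = length(xl$zero_obs)), st$seconds)

  st <- timed(stratify(count_np_coexpression(xq, np), scheme))
  prof <- st$value
  report <- add_stage(report, "np_profile",
                      c(as.list(table(prof$stratum)),
                        list(cells = nrow(prof))), st$seconds)

  st <- timed(np_count_abundance_correlation(prof))
  corr <- st$value
  corr_tab <- data.frame(label = "all_cells", corr, stringsAsFactors = FALSE)
  f_corr <- file.path(out_dir, "np_count_abundance_correlation.tsv")
  write_results_table(corr_tab, f_corr, "association")
  report <- add_stage(report, "correlation",
                      list(rho = corr$estimate, p = corr$p_value), st$seconds)

  props <- stratum_proportions(prof, meta)
  f_props <- file.path(out_dir, "stratum_proportions.tsv")
  write.table(props, f_props, sep = "\t", quote = FALSE, row.names = FALSE)

  cond <- meta$condition[match(prof$obs_id, meta$obs_id)]
  group_of <- function(condition, stratum)
    prof$obs_id[cond == condition & prof$stratum == stratum]

  dge_out <- list()
  contrasts <- list(
    hnp_vs_lnp_control = list(a = group_of(ctl, "high"), b = group_of(ctl, "low")),
    mnp_affected_vs_control = list(a = group_of(aff, "mid"), b = group_of(ctl, "mid")))
  for (nm in names(contrasts)) {
    gr <- contrasts[[nm]]
    if (!length(gr$a) || !length(gr$b)) {
      report$skipped[[nm]] <- sprintf("empty group (A: %d cells, B: %d cells)",
                                      length(gr$a), length(gr$b))
      next
    }
    st <- timed(wilcoxon_dge(xl, gr$a, gr$b, filt))
    dge_out[[nm]] <- st$value
    f <- file.path(out_dir, paste0("dge_", nm, ".tsv"))
    write_results_table(st$value, f, "dge")
    report <- add_stage(report, paste0("dge_", nm),
                        list(n_a = length(gr$a), n_b = length(gr$b),
                             genes_tested = nrow(st$value),
                             significant = sum(st$value$fdr < alpha)),
                        st$seconds)
    report$files <- c(report$files, f)
  }

  if (!is.null(dge_out$hnp_vs_lnp_control)) {
    up_hnp <- dge_out$hnp_vs_lnp_control
    up_hnp <- up_hnp$gene[up_hnp$fdr < alpha & up_hnp$log_fc > 0]
    if (length(up_hnp)) {
      st <- timed(np_count_regression(xl[, cond == ctl],
                                      prof[cond == ctl, ], up_hnp))
      f <- file.path(out_dir, "regression_hnp_genes.tsv")
      write_results_table(st$value, f, "regression")
      report <- add_stage(report, "regression",
                          list(genes = nrow(st$value)), st$seconds)
      report$files <- c(report$files, f)
    } else report$skipped$regression <- "no HNP-elevated genes at the FDR cut-off"
  }

  if (!is.null(dge_out$hnp_vs_lnp_control) &&
      !is.null(dge_out$mnp_affected_vs_control)) {
    d1 <- dge_out$hnp_vs_lnp_control
    d2 <- dge_out$mnp_affected_vs_control
    up_hnp <- d1$gene[d1$fdr < alpha & d1$log_fc > 0]
    down_ad <- d2$gene[d2$fdr < alpha & d2$log_fc < 0]
    universe <- union(d1$gene, d2$gene)
    if (length(up_hnp) && length(down_ad)) {
      ov <- hypergeom_overlap_test(build_overlap_input(up_hnp, down_ad, universe))
      f <- file.path(out_dir, "overlap_test.json")
      jsonlite::write_json(
        list(x = ov$input$x, m = ov$input$m, n = ov$input$n, k = ov$input$k,
             tail = ov$tail, p_value = ov$p_value,
             expected_overlap = ov$expected_overlap,
             fold_enrichment = ov$fold_enrichment),
        f, auto_unbox = TRUE, digits = NA)
      report <- add_stage(report, "overlap",
                          list(x = ov$input$x, p = ov$p_value), 0)
      report$files <- c(report$files, f)
    } else report$skipped$overlap <- "empty gene set on one side of the overlap"
  }

  report$files <- c(report$files, f_corr, f_props)
  report <- finish_report(report, out_dir)
  invisible(report)
}

#' Run the progression/aging (time) analysis
#'
#' Single-cell part (when `matrix`/`meta`/`np_list` are present): stratum
#' proportions per donor and one-tailed rank-sum comparisons of the control
#' against each affected condition, for the low stratum (affected greater)
#' and the high stratum (affected less). Bulk part (when `tpm`/`bulk_meta`/
#' `adnp_list` are present): exclusion filters then the per-region aging
#' scan, written as a region/sample-size/correlation/p/significance table.
#'
#' @param config list; single-cell entries as in [run_function_analysis()]
#'   plus `conditions` (control first), and/or bulk entries `tpm`,
#'   `bulk_meta`, `adnp_list`, `np_list`, `min_region_n`.
#' @return the run report, invisibly.
#' @export
run_time_analysis <- function(config) {
  out_dir <- config$out_dir %||% stop_npv("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha %||% 0.05
  report <- new_report(config)

  if (!is.null(config$matrix)) {
    scheme <- config$scheme %||% stratum_scheme()
    np <- resolve_genes(config$np_list, "np")
    x <- resolve_matrix(config$matrix)
    meta <- resolve_meta(config$meta)
    conds <- config$conditions %||% unique(meta$condition)
    if (!all(conds %in% meta$condition))
      stop_npv("condition label(s) missing from metadata: ",
               paste(setdiff(conds, meta$condition), collapse = ", "))
    ctl <- conds[1]
    xq <- qc_filter(x, meta, config$qc %||% qc_thresholds())
    prof <- stratify(count_np_coexpression(xq, np), scheme)
    props <- stratum_proportions(prof, meta)
    f_props <- file.path(out_dir, "stratum_proportions.tsv")
    write.table(props, f_props, sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- list()
    for (other in setdiff(conds, ctl)) {
      for (spec in list(c("low", "less"), c("high", "greater"))) {
        res <- compare_stratum_proportions(props, ctl, other, spec[1],
                                           alternative = spec[2])
        tests[[length(tests) + 1L]] <- data.frame(
          label = sprintf("%s_vs_%s_%s", ctl, other, spec[1]),
          res, significant = res$p_value < alpha, stringsAsFactors = FALSE)
      }
    }
    tests <- do.call(rbind, tests)
    f_tests <- file.path(out_dir, "stratum_proportion_tests.tsv")
    write_results_table(tests, f_tests, "association")
    report <- add_stage(report, "stratum_tests",
                        list(comparisons = nrow(tests),
                             significant = sum(tests$significant)), 0)
    report$files <- c(report$files, f_props, f_tests)
  }

  if (!is.null(config$tpm)) {
    adnp <- resolve_genes(config$adnp_list, "adnp")
    npb <- if (!is.null(config$np_list)) resolve_genes(config$np_list, "np") else NULL
    tx <- if (inherits(config$tpm, "gem")) config$tpm
          else read_dense_table(config$tpm, layer = "tpm")
    bmeta <- resolve_meta(config$bulk_meta)
    st <- timed({
      kept <- filter_aging_samples(bmeta)
      per_region_aging_scan(kept, tx[, kept$sample_id], adnp, npb,
                            min_n = config$min_region_n %||% 20L,
                            alpha = alpha)
    })
    scan <- st$value
    tab <- scan$regional
    tab$significance <- ifelse(tab$significant, "*", "")
    f_aging <- file.path(out_dir, "aging_scan.tsv")
    write.table(tab[order(tab$region), ], f_aging, sep = "\t",
                quote = FALSE, row.names = FALSE)
    report <- add_stage(report, "aging_scan",
                        list(regions = nrow(tab),
                             significant = sum(tab$significant)), st$seconds)
    report$files <- c(report$files, f_aging)
    if (!is.null(scan$per_gene)) {
      f_gene <- file.path(out_dir, "aging_per_gene.tsv")
      write.table(scan$per_gene, f_gene, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      report$files <- c(report$files, f_gene)
    }
  }
  report <- finish_report(report, out_dir)
  invisible(report)
}

#' Run the regional (space) analysis
#'
#' AHNP classification of annotated clusters, per-region and per-dissection
#' cell estimates, top-k tables, and an optional attribute breakdown of one
#' dissection.
#'
#' @param config list: `annotation` (a [cluster_annotation()] or a list with
#'   `path` and `map_path`), `adnp_list`, `np_list`, optional `criteria`,
#'   `top_k` (5), `breakdown_dissection`, `breakdown_by`, `out_dir`.
#' @return the run report, invisibly.
#' @export
run_space_analysis <- function(config) {
  out_dir <- config$out_dir %||% stop_npv("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- new_report(config)
  ann <- if (inherits(config$annotation, "cluster_annotation")) config$annotation
         else if (is.list(config$annotation))
           read_cluster_annotation(config$annotation$path, config$annotation$map_path)
         else stop_npv("config$annotation missing (need annotation and its dissection->region map)")
  adnp <- resolve_genes(config$adnp_list, "adnp")
  np <- resolve_genes(config$np_list, "np")
  crit <- config$criteria %||% ahnp_criteria()
  k <- config$top_k %||% 5L

  for (lv in c("region", "dissection")) {
    st <- timed(estimate_regional_counts(ann, adnp, np, crit, level = lv))
    est <- st$value
    est$ahnp_cell_estimate <- round(est$ahnp_cell_estimate)
    f <- file.path(out_dir, paste0("ahnp_abundance_", lv, ".tsv"))
    write_results_table(est, f, "regional")
    f_top <- file.path(out_dir, paste0("ahnp_top_", lv, ".tsv"))
    write_results_table(rank_top_regions(est, k), f_top, "regional")
    report <- add_stage(report, paste0("estimate_", lv),
                        list(rows = nrow(est)), st$seconds)
    report$files <- c(report$files, f, f_top)
  }
  if (!is.null(config$breakdown_dissection)) {
    bd <- dissection_membership_breakdown(
      ann, config$breakdown_dissection, adnp, np, crit,
      top_n_dissections = config$breakdown_top_n %||% 3L,
      group_by = config$breakdown_by %||% "neurotransmitter")
    f <- file.path(out_dir, paste0("breakdown_", config$breakdown_dissection,
                                   "_", config$breakdown_by %||% "neurotransmitter",
                                   ".tsv"))
    write.table(bd, f, sep = "\t", quote = FALSE, row.names = FALSE)
    report <- add_stage(report, "breakdown", list(groups = nrow(bd)), 0)
    report$files <- c(report$files, f)
  }
  report <- finish_report(report, out_dir)
  invisible(report)
}
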