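# Regional abundance of high-ADNP (AHNP) neuronal clusters, estimated from a
# cluster-annotation table: clusters tagged with co-expressed NPs, total cell
# counts, and per-dissection percentages, plus a dissection-to-region map.

#' Construct a cluster-annotation object
#'
#' @param clusters data.frame with columns `cluster_id`, `total_cells` and
#'   optionally `neurotransmitter`, `subtype`, `mtg_label`.
#' @param tags named list (by cluster id) of NP gene-symbol vectors the
#'   cluster is tagged with.
#' @param pct numeric matrix, clusters x dissections, percentages in
#'   \[0, 100\]; each row may sum to at most 100 (+1e-6); shortfalls mean the
#'   remainder lies in unlisted dissections and are never renormalized.
#' @param dissection_region named character: dissection -> region.
#' @return object of class `cluster_annotation`.
#' @export
cluster_annotation <- function(clusters, tags, pct, dissection_region) {
  stopifnot(is.data.frame(clusters),
            all(c("cluster_id", "total_cells") %in% names(clusters)))
  clusters$cluster_id <- as.character(clusters$cluster_id)
  if (anyDuplicated(clusters$cluster_id))
    stop_npv("duplicate cluster ids")
  if (any(clusters$total_cells < 0))
    stop_npv("total_cells must be non-negative")
  if (!all(clusters$cluster_id %in% names(tags)))
    stop_npv("every cluster needs a tag entry (possibly empty)")
  pct <- as.matrix(pct)
  if (!identical(rownames(pct), clusters$cluster_id))
    stop_npv("pct rownames must equal the cluster ids, in order")
  if (any(pct < 0) || any(pct > 100 + 1e-6))
    stop_npv("percentages must lie in [0, 100]")
  sums <- rowSums(pct)
  over <- sums > 100 + 1e-6
  if (any(over))
    stop_npv("dissection percentages exceed 100 for cluster(s): ",
             paste(clusters$cluster_id[over], collapse = ", "))
  if (!all(colnames(pct) %in% names(dissection_region)))
    stop_npv("unmapped dissection(s): ",
             paste(setdiff(colnames(pct), names(dissection_region)), collapse = ", "))
  structure(list(clusters = clusters,
                 tags = lapply(tags[clusters$cluster_id], norm_symbols),
                 pct = pct,
                 dissection_region = dissection_region),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat(sprintf("<cluster_annotation> %d clusters, %d dissections, %d regions\n",
              nrow(x$clusters), ncol(x$pct),
              length(unique(x$dissection_region[colnames(x$pct)]))))
  invisible(x)
}

#' Read a cluster-annotation CSV plus its dissection-to-region map
#'
#' Expected columns: `cluster_id`, `np_tags` (delimited list), `total_cells`,
#' one `pct_<dissection>` column per dissection (percentages in 0-100), and
#' optional `neurotransmitter`, `subtype`, `mtg_label`. The map is a TSV with
#' columns `dissection`, `region`.
#'
#' @param path annotation CSV path.
#' @param map_path map TSV path.
#' @param tag_sep delimiter inside `np_tags`.
#' @return a [cluster_annotation()].
#' @export
read_cluster_annotation <- function(path, map_path, tag_sep = ";") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cluster_id", "np_tags", "total_cells")
  if (!all(need %in% names(df)))
    stop_npv("annotation '", path, "' must have columns ", paste(need, collapse = ", "))
  pct_cols <- grep("^pct_", names(df), value = TRUE)
  if (!length(pct_cols)) stop_npv("annotation '", path, "' has no pct_* dissection columns")
  mp <- read.delim(map_path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("dissection", "region") %in% names(mp)))
    stop_npv("map '", map_path, "' must have columns dissection, region")
  pct <- as.matrix(df[, pct_cols, drop = FALSE])
  colnames(pct) <- sub("^pct_", "", pct_cols)
  rownames(pct) <- as.character(df$cluster_id)
  tags <- setNames(lapply(strsplit(ifelse(is.na(df$np_tags), "", df$np_tags), tag_sep, fixed = TRUE),
                          function(t) trimws(t[nzchar(trimws(t))])),
                   df$cluster_id)
  keep_cols <- intersect(c("cluster_id", "total_cells", "neurotransmitter",
                           "subtype", "mtg_label"), names(df))
  cluster_annotation(df[, keep_cols, drop = FALSE], tags, pct,
                     setNames(mp$region, mp$dissection))
}

#' Write a cluster-annotation object to CSV + map TSV
#' @param ann a [cluster_annotation()].
#' @param path,map_path output paths.
#' @param tag_sep tag delimiter.
#' @return the paths, invisibly.
#' @export
write_cluster_annotation <- function(ann, path, map_path, tag_sep = ";") {
  stopifnot(inherits(ann, "cluster_annotation"))
  df <- ann$clusters
  df$np_tags <- vapply(ann$tags[df$cluster_id],
                       function(t) paste(t, collapse = tag_sep), character(1))
  pct <- ann$pct
  colnames(pct) <- paste0("pct_", colnames(pct))
  out <- cbind(df[, c("cluster_id", "np_tags", "total_cells")],
               df[, setdiff(names(df), c("cluster_id", "np_tags", "total_cells")), drop = FALSE],
               as.data.frame(pct))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  write.table(data.frame(dissection = colnames(ann$pct),
                         region = unname(ann$dissection_region[colnames(ann$pct)])),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, map_path))
}

#' Count ADNP and non-ADNP tags of a cluster
#'
#' `adnp_count` is the number of tags on the ADNP list; `non_adnp_count` the
#' number on the NP list but not the ADNP list. Tags outside the NP universe
#' are excluded from both counts (and reported via attribute
#' `"unknown_tags"`).
#'
#' @param tags character vector of NP tags (or a single cluster's entry of a
#'   [cluster_annotation()]'s `tags`).
#' @param adnp_list,np_list gene lists; `adnp_list` must be a subset of
#'   `np_list` conceptually (symbols not shared are treated as ADNP anyway).
#' @return integer vector `c(adnp, non_adnp)`.
#' @export
split_np_tags <- function(tags, adnp_list, np_list) {
  tags <- unique(norm_symbols(tags))
  adnp <- as_symbols(adnp_list)
  np <- union(as_symbols(np_list), adnp)
  known <- intersect(tags, np)
  out <- c(adnp = length(intersect(known, adnp)),
           non_adnp = length(setdiff(known, adnp)))
  attr(out, "unknown_tags") <- setdiff(tags, np)
  out
}

#' AHNP classification criteria
#'
#' A cluster is AHNP when it carries at least `min_adnp` ADNP tags and
#' strictly fewer than `max_non_adnp_exclusive` non-ADNP NP tags. Defaults:
#' 6+ ADNPs and <3 non-ADNPs.
#'
#' @param min_adnp inclusive lower bound on ADNP tags.
#' @param max_non_adnp_exclusive exclusive upper bound on non-ADNP tags.
#' @export
ahnp_criteria <- function(min_adnp = 6L, max_non_adnp_exclusive = 3L) {
  if (min_adnp < 1 || max_non_adnp_exclusive < 1)
    stop_npv("criteria bounds must be >= 1")
  structure(list(min_adnp = as.integer(min_adnp),
                 max_non_adnp_exclusive = as.integer(max_non_adnp_exclusive)),
            class = "ahnp_criteria")
}

#' Classify clusters as AHNP
#'
#' @param ann a [cluster_annotation()].
#' @param adnp_list,np_list gene lists.
#' @param criteria an [ahnp_criteria()].
#' @return named logical vector over clusters.
#' @export
classify_ahnp <- function(ann, adnp_list, np_list, criteria = ahnp_criteria()) {
  stopifnot(inherits(ann, "cluster_annotation"), inherits(criteria, "ahnp_criteria"))
  vapply(ann$tags, function(t) {
    ct <- split_np_tags(t, adnp_list, np_list)
    ct[["adnp"]] >= criteria$min_adnp &&
      ct[["non_adnp"]] < criteria$max_non_adnp_exclusive
  }, logical(1))
}

#' Estimate AHNP cell abundance per region or dissection
#'
#' Each qualifying cluster's cells are attributed to dissections as
#' `total_cells * percentage / 100` and summed over the chosen level.
#' Percentage shortfalls below 100 are not renormalized (the residual lies in
#' unlisted dissections). Results are sorted by descending estimate with an
#' alphabetical tie-break.
#'
#' @param ann a [cluster_annotation()].
#' @param adnp_list,np_list gene lists.
#' @param criteria an [ahnp_criteria()].
#' @param only_ahnp restrict to AHNP clusters (default) or use all clusters.
#' @param level `"region"` or `"dissection"`.
#' @return data.frame: `region_or_dissection`, `ahnp_cell_estimate`
#'   (real; round only at report time), `n_contributing_clusters`.
#' @export
estimate_regional_counts <- function(ann, adnp_list, np_list,
                                     criteria = ahnp_criteria(),
                                     only_ahnp = TRUE,
                                     level = c("region", "dissection")) {
  stopifnot(inherits(ann, "cluster_annotation"))
  level <- match.arg(level)
  qual <- if (only_ahnp) classify_ahnp(ann, adnp_list, np_list, criteria)
          else rep(TRUE, nrow(ann$clusters))
  pct <- ann$pct[qual, , drop = FALSE]
  cells <- ann$clusters$total_cells[qual]
  attributed <- pct * cells / 100           # clusters x dissections
  shortfall <- cells * (1 - rowSums(pct) / 100)
  if (any(shortfall > 1e-6))
    message(sum(shortfall > 1e-6), " qualifying cluster(s) attribute < 100% of cells; ",
            "shortfall of ", round(sum(shortfall)), " cells left unassigned")
  if (level == "dissection") {
    est <- colSums(attributed)
    ncl <- colSums(attributed > 0)
    labels <- colnames(pct)
  } else {
    reg <- ann$dissection_region[colnames(pct)]
    est <- tapply(colSums(attributed), reg, sum)
    contrib <- t(rowsum(t(attributed > 0) * 1, reg)) > 0  # clusters x regions
    ncl <- colSums(contrib)[names(est)]
    labels <- names(est)
  }
  out <- data.frame(region_or_dissection = labels,
                    ahnp_cell_estimate = as.numeric(est),
                    n_contributing_clusters = as.integer(ncl),
                    stringsAsFactors = FALSE)
  out[order(-out$ahnp_cell_estimate, out$region_or_dissection), , drop = FALSE]
}

#' Top-k regions or dissections by AHNP abundance
#'
#' @param records output of [estimate_regional_counts()].
#' @param k rows to keep (all if fewer exist).
#' @return the top-k rows, descending estimate, alphabetical tie-break.
#' @export
rank_top_regions <- function(records, k = 5L) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  ord <- order(-records$ahnp_cell_estimate, records$region_or_dissection)
  head(records[ord, , drop = FALSE], k)
}

#' Break down AHNP membership of one dissection by an annotation attribute
#'
#' Restricts to AHNP clusters for which the target dissection ranks within
#' the top `top_n_dissections` by percentage, attributes
#' `total_cells * pct(target)/100` cells to the dissection, and sums them per
#' attribute group (`neurotransmitter`, `subtype`, or `mtg_label`); clusters
#' missing the attribute are grouped as `"unannotated"`.
#'
#' @param ann a [cluster_annotation()].
#' @param dissection target dissection label.
#' @param adnp_list,np_list gene lists.
#' @param criteria an [ahnp_criteria()].
#' @param top_n_dissections rank cut-off for inclusion.
#' @param group_by attribute column to group by.
#' @return data.frame `group`, `cells`, descending cells, alphabetical ties.
#' @export
dissection_membership_breakdown <- function(ann, dissection, adnp_list, np_list,
                                            criteria = ahnp_criteria(),
                                            top_n_dissections = 3L,
                                            group_by = c("neurotransmitter", "subtype", "mtg_label")) {
  stopifnot(inherits(ann, "cluster_annotation"))
  group_by <- match.arg(group_by)
  if (!dissection %in% colnames(ann$pct))
    stop_npv("unknown dissection '", dissection, "'; known: ",
             paste(colnames(ann$pct), collapse = ", "))
  ahnp <- classify_ahnp(ann, adnp_list, np_list, criteria)
  keep <- which(ahnp)
  if (!length(keep)) return(data.frame(group = character(), cells = numeric()))
  include <- vapply(keep, function(i) {
    p <- ann$pct[i, ]
    if (p[dissection] <= 0) return(FALSE)
    rank(-p, ties.method = "min")[dissection] <= top_n_dissections
  }, logical(1))
  keep <- keep[include]
  if (!length(keep)) return(data.frame(group = character(), cells = numeric()))
  cells <- ann$clusters$total_cells[keep] * ann$pct[keep, dissection] / 100
  grp <- if (group_by %in% names(ann$clusters)) as.character(ann$clusters[[group_by]][keep])
         else rep(NA_character_, length(keep))
  grp[is.na(grp) | !nzchar(grp)] <- "unannotated"
  agg <- tapply(cells, grp, sum)
  out <- data.frame(group = names(agg), cells = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[order(-out$cells, out$group), , drop = FALSE]
}
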