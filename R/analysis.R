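hull_area_nm2 <- function(x, y) {
  # convex-hull area by the shoelace formula; undefined (0) below 3 points
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  xa <- x[h]; ya <- y[h]
  0.5 * abs(sum(xa * c(ya[-1], ya[1]) - ya * c(xa[-1], xa[1])))
}

#' Per-cluster and per-ROI statistics of a labeling
#'
#' For each cluster: localization count, convex-hull area (um^2; 0 for
#' clusters of fewer than 3 points, which are excluded from area and density
#' summaries but still counted), and density (count / area). For the ROI:
#' number of clusters, percent of localizations in clusters, and the relative
#' density `(n_clustered / sum(areas)) / (n_background / (A_roi - sum(areas)))`
#' comparing localization density inside vs. outside clusters. With no
#' clusters (or no positive cluster area) the relative density is `NA`.
#'
#' @param tbl a [localization_table()].
#' @param labels integer labels (0 = background).
#' @param roi an [roi()].
#' @return A `cluster_stats` object: `clusters` data frame (`label`,
#'   `n_locs`, `area_um2`, `density_um2`) and `summary` list (`n`,
#'   `n_clusters`, `n_clustered`, `n_background`, `percent_clustered`,
#'   `percent_background`, `relative_density`, `mean_area_um2`).
#' @export
cluster_statistics <- function(tbl, labels, roi) {
  tbl <- validate_localizations(tbl)
  stopifnot(length(labels) == nrow(tbl), inherits(roi, "roi"))
  labels <- as.integer(labels)
  n <- nrow(tbl)
  ks <- sort(unique(labels[labels > 0L]))
  clusters <- data.frame(label = ks,
                         n_locs = integer(length(ks)),
                         area_um2 = numeric(length(ks)),
                         density_um2 = numeric(length(ks)))
  for (i in seq_along(ks)) {
    sel <- labels == ks[i]
    clusters$n_locs[i] <- sum(sel)
    a <- hull_area_nm2(tbl$x_nm[sel], tbl$y_nm[sel]) / 1e6
    clusters$area_um2[i] <- a
    clusters$density_um2[i] <- if (a > 0) clusters$n_locs[i] / a else NA_real_
  }
  n_clustered <- sum(labels > 0L)
  n_background <- n - n_clustered
  sum_area <- sum(clusters$area_um2)
  A <- roi_area_um2(roi)
  rel <- if (n_clustered > 0 && sum_area > 0 && n_background > 0 &&
             A > sum_area) {
    (n_clustered / sum_area) / (n_background / (A - sum_area))
  } else NA_real_
  measurable <- clusters$n_locs >= 3 & clusters$area_um2 > 0
  structure(list(
    clusters = clusters,
    summary = list(
      n = n, n_clusters = length(ks), n_clustered = n_clustered,
      n_background = n_background,
      percent_clustered = if (n) 100 * n_clustered / n else NA_real_,
      percent_background = if (n) 100 * n_background / n else NA_real_,
      relative_density = rel,
      mean_area_um2 = if (any(measurable))
        mean(clusters$area_um2[measurable]) else NA_real_
    )
  ), class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cluster_stats> %d clusters, %.1f%% clustered (n = %d)\n",
              s$n_clusters, s$percent_clustered, s$n))
  if (!is.na(s$relative_density))
    cat(sprintf("  relative density in/out: %.2f, mean area %.4f um^2\n",
                s$relative_density, s$mean_area_um2))
  invisible(x)
}

#' Summaries across a batch of datasets
#'
#' Mean and standard deviation of every per-ROI metric across datasets, plus
#' the pooled list of per-cluster areas (the input for cumulative area
#' distributions and violin plots).
#'
#' @param stats_list a non-empty list of [cluster_statistics()] results.
#' @return A data frame (`metric`, `mean`, `sd`) with the pooled per-cluster
#'   areas (clusters of >= 3 points) in attribute `pooled_areas_um2`.
#' @export
batch_summary <- function(stats_list) {
  stopifnot(length(stats_list) >= 1,
            all(vapply(stats_list, inherits, TRUE, "cluster_stats")))
  metrics <- c("n_clusters", "percent_clustered", "relative_density",
               "mean_area_um2")
  vals <- sapply(metrics, function(m)
    vapply(stats_list, function(s) as.numeric(s$summary[[m]]), 0))
  vals <- matrix(vals, nrow = length(stats_list))
  out <- data.frame(
    metric = metrics,
    mean = apply(vals, 2, mean, na.rm = TRUE),
    sd = apply(vals, 2, function(v) if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
  )
  rownames(out) <- NULL
  pooled <- unlist(lapply(stats_list, function(s) {
    cl <- s$clusters
    cl$area_um2[cl$n_locs >= 3]
  }), use.names = FALSE)
  attr(out, "pooled_areas_um2") <- pooled %||% numeric(0)
  out
}

#' Cumulative distributions of cluster areas per group
#'
#' Right-continuous empirical CDFs, tabulated on the pooled support of all
#' groups so the groups can be overlaid and exported as text.
#'
#' @param groups named list of numeric area vectors (um^2), each non-empty.
#' @return A list with `ecdf` (one [stats::ecdf()] per group) and `table`
#'   (columns `group`, `area_um2`, `cumulative_fraction`).
#' @export
cumulative_area_distribution <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)),
            all(nzchar(names(groups))),
            all(vapply(groups, length, 0L) >= 1))
  support <- sort(unique(unlist(groups, use.names = FALSE)))
  fns <- lapply(groups, stats::ecdf)
  tab <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(group = g, area_um2 = support,
               cumulative_fraction = fns[[g]](support))))
  rownames(tab) <- NULL
  list(ecdf = fns, table = tab)
}

#' Compare cluster-area distributions between groups
#'
#' Kruskal-Wallis rank-sum test (with tie correction and chi-square
#' p-value) of the null hypothesis that all groups share one distribution.
#'
#' @param groups named list of at least two numeric vectors.
#' @return A list: `statistic` (H), `df`, `p_value`, `method`.
#' @export
compare_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 0L) >= 1))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, method = "Kruskal-Wallis rank sum test")
}
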