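# CSR neighbor structure shared by all three clusterers; exact fixed-radius
# search (closed ball, Euclidean metric, no boundary correction).
build_neighbors <- function(tbl, r_nm) {
  stopifnot(r_nm > 0)
  .nbr_csr_cpp(tbl$x_nm, tbl$y_nm, as.numeric(r_nm))
}

#' Per-point neighbor counts
#'
#' Number of other localizations within Euclidean distance `r_nm` of each
#' localization (the point itself is not counted; no boundary correction).
#' This is the shared density primitive of the three clusterers.
#'
#' @param tbl a [localization_table()].
#' @param r_nm search radius in nm, positive.
#' @return Integer vector of counts, one per localization.
#' @export
neighbor_counts <- function(tbl, r_nm) {
  nb <- build_neighbors(validate_localizations(tbl), r_nm)
  diff(nb$ptr)
}

#' Ripley's-K-based clustering
#'
#' Localizations whose neighbor count at radius `r_nm` reaches the threshold
#' `T` are declared clustered; clusters are the `r_nm`-connected components
#' of the clustered subset. All other localizations are background (label 0).
#'
#' @param tbl a [localization_table()].
#' @param r_nm search radius in nm.
#' @param T minimum neighbor count (self excluded) for a clustered point.
#' @param neighbors optional precomputed neighbor structure (internal reuse).
#' @return Integer labels, 0 = background, clusters numbered 1..K.
#' @export
cluster_ripley <- function(tbl, r_nm, T, neighbors = NULL) {
  nb <- neighbors %||% build_neighbors(validate_localizations(tbl), r_nm)
  .ripley_cpp(nb$ptr, nb$idx, as.integer(T))
}

#' DBSCAN clustering
#'
#' Standard DBSCAN with `eps = r_nm` and `minPts` (a core point has at least
#' `minPts` points within `eps`, itself included). Border points join the
#' first core cluster that reaches them in deterministic scan order; noise is
#' labeled 0.
#'
#' @inheritParams cluster_ripley
#' @param minPts minimum number of points (including the point itself) within
#'   `eps` for a core point.
#' @return Integer labels, 0 = noise.
#' @export
cluster_dbscan <- function(tbl, r_nm, minPts, neighbors = NULL) {
  nb <- neighbors %||% build_neighbors(validate_localizations(tbl), r_nm)
  .dbscan_cpp(nb$ptr, nb$idx, as.integer(minPts))
}

#' ToMATo persistence-based clustering
#'
#' Mode seeking on the `r_nm`-neighborhood graph with the neighbor count as
#' the density estimate. Points are processed in decreasing density; each
#' point either founds a density peak or joins its highest-density neighbor's
#' cluster, and when two clusters meet, the one whose peak prominence
#' (peak density minus merge density) is below `tau` is absorbed into the
#' higher-peak cluster. Surviving clusters whose peak density is below `tau`
#' are background. Ties in density are broken by lower row index.
#'
#' @inheritParams cluster_ripley
#' @param tau persistence threshold in density (neighbor-count) units.
#' @return Integer labels, 0 = background.
#' @export
cluster_tomato <- function(tbl, r_nm, tau, neighbors = NULL) {
  nb <- neighbors %||% build_neighbors(validate_localizations(tbl), r_nm)
  dens <- as.numeric(diff(nb$ptr))
  .tomato_cpp(nb$ptr, nb$idx, dens, as.numeric(tau))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cluster_fun <- function(method) {
  switch(method,
         ripley = function(nb, T) .ripley_cpp(nb$ptr, nb$idx, as.integer(T)),
         dbscan = function(nb, T) .dbscan_cpp(nb$ptr, nb$idx, as.integer(T)),
         tomato = function(nb, T) .tomato_cpp(nb$ptr, nb$idx,
                                              as.numeric(diff(nb$ptr)),
                                              as.numeric(T)),
         stop("unknown clustering method: ", method, call. = FALSE))
}
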