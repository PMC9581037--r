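#' Configuration for the ground-truth cluster simulation
#'
#' Defaults reproduce the benchmark recipe: 10 Gaussian clusters of 100
#' localizations each (isotropic sd 50 nm), cluster centers uniform on a
#' 3000 x 3000 nm field of view and at least 100 nm apart, background
#' localizations equal to 50% of the total, and per-localization precisions
#' drawn from a gamma law with shape 5 and rate 0.166667 nm^-1 (mean 30 nm).
#'
#' @param n_clusters number of clusters.
#' @param locs_per_cluster localizations drawn per cluster.
#' @param cluster_sd_nm isotropic Gaussian standard deviation of a cluster, nm.
#' @param min_center_sep_nm minimum pairwise distance between cluster centers.
#' @param background_fraction fraction of all localizations that are
#'   background, in `[0, 1)`.
#' @param roi an [roi()]; the field of view.
#' @param precision_shape,precision_rate gamma parameters of the precision law
#'   (rate in 1/nm).
#' @param apply_precision_error if `TRUE` (default), each clustered
#'   localization is displaced by an additional isotropic Gaussian error with
#'   its own drawn precision, so the observed position is molecule spread
#'   plus localization error — the generative model the Bayesian score
#'   assumes (per-point variance `sigma^2 + sd_i^2`). Set to `FALSE` to draw
#'   positions from the cluster spread alone.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return A `ground_truth_config`.
#' @export
ground_truth_config <- function(n_clusters = 10, locs_per_cluster = 100,
                                cluster_sd_nm = 50, min_center_sep_nm = 100,
                                background_fraction = 0.5,
                                roi = smlmclust::roi(3000, 3000),
                                precision_shape = 5,
                                precision_rate = 0.166667,
                                apply_precision_error = TRUE,
                                seed = NULL) {
  stopifnot(n_clusters >= 1, locs_per_cluster >= 1, cluster_sd_nm > 0,
            min_center_sep_nm >= 0,
            background_fraction >= 0, background_fraction < 1,
            precision_shape > 0, precision_rate > 0, inherits(roi, "roi"))
  structure(as.list(environment()), class = "ground_truth_config")
}

# rejection-sample points in [lo, w-lo] x [lo, h-lo] with pairwise distance
# >= min_sep (and, if disc_d > 0, non-overlapping discs of diameter disc_d)
place_centers <- function(n, roi, min_sep, margin = 0, disc_d = 0,
                          max_attempts = 1e6) {
  cx <- numeric(n); cy <- numeric(n)
  sep <- max(min_sep, disc_d)
  k <- 0L; attempts <- 0L
  while (k < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " cluster centers after ", max_attempts,
           " attempts; enlarge the ROI or relax the separation", call. = FALSE)
    px <- runif(1, margin, roi$width_nm - margin)
    py <- runif(1, margin, roi$height_nm - margin)
    if (k == 0L || all((cx[1:k] - px)^2 + (cy[1:k] - py)^2 >= sep^2)) {
      k <- k + 1L
      cx[k] <- px; cy[k] <- py
    }
  }
  cbind(x = cx, y = cy)
}

#' Simulate a ground-truth clustered localization table
#'
#' Draws `locs_per_cluster` localizations from an isotropic 2D normal around
#' each cluster center, adds `round(f/(1-f) * n_clustered)` uniform background
#' localizations (`f` = `background_fraction`), and assigns each localization
#' a precision drawn i.i.d. from the configured gamma law. `true_label` is 0
#' for background and the cluster index otherwise.
#'
#' @param config a [ground_truth_config()].
#' @return A [localization_table()] with `true_label`.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "ground_truth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  centers <- place_centers(config$n_clusters, config$roi,
                           config$min_center_sep_nm)
  m <- config$locs_per_cluster
  n_clustered <- config$n_clusters * m
  cl_x <- rep(centers[, "x"], each = m) + rnorm(n_clustered, 0, config$cluster_sd_nm)
  cl_y <- rep(centers[, "y"], each = m) + rnorm(n_clustered, 0, config$cluster_sd_nm)
  f <- config$background_fraction
  n_bg <- round(f / (1 - f) * n_clustered)
  bg_x <- runif(n_bg, 0, config$roi$width_nm)
  bg_y <- runif(n_bg, 0, config$roi$height_nm)
  n <- n_clustered + n_bg
  sd_nm <- rgamma(n, shape = config$precision_shape,
                  rate = config$precision_rate)
  if (isTRUE(config$apply_precision_error)) {
    cl_x <- cl_x + rnorm(n_clustered, 0, sd_nm[seq_len(n_clustered)])
    cl_y <- cl_y + rnorm(n_clustered, 0, sd_nm[seq_len(n_clustered)])
  }
  localization_table(
    x_nm = c(cl_x, bg_x), y_nm = c(cl_y, bg_y),
    sd_nm = sd_nm,
    true_label = c(rep(seq_len(config$n_clusters), each = m),
                   integer(n_bg))
  )
}

#' Configuration for the blinking-fluorophore emulation
#'
#' Defaults follow the dSTORM-style recipe: 40 non-overlapping disc-shaped
#' clusters of 50 nm diameter at least 500 nm from every border of a
#' 25 x 25 um field of view, molecule counts per cluster Poisson with the
#' given mean, background molecules Poisson with the given areal density,
#' two-state blinking with k_on = 0.01 s^-1 and k_off = 10 s^-1 at 10 ms
#' exposure over 50,000 frames.
#'
#' @param n_clusters number of disc-shaped clusters.
#' @param cluster_diameter_nm disc diameter in nm.
#' @param molecules_per_cluster_mean Poisson mean of molecules per cluster.
#' @param background_molecule_density_um2 background molecule density, um^-2.
#' @param k_on,k_off switching rates in s^-1 (`k_on >= 0`, `k_off > 0`).
#' @param exposure_s frame exposure time in seconds.
#' @param n_frames number of acquisition frames.
#' @param min_cluster_margin_nm minimum distance of a cluster center from any
#'   ROI border.
#' @param roi an [roi()].
#' @param precision_shape,precision_rate gamma parameters of the precision law.
#' @param seed RNG seed, or `NULL`.
#' @return A `blink_config`.
#' @export
blink_config <- function(n_clusters = 40, cluster_diameter_nm = 50,
                         molecules_per_cluster_mean = 49,
                         background_molecule_density_um2 = 346,
                         k_on = 0.01, k_off = 10, exposure_s = 0.01,
                         n_frames = 50000, min_cluster_margin_nm = 500,
                         roi = smlmclust::roi(25000, 25000),
                         precision_shape = 5, precision_rate = 0.166667,
                         seed = NULL) {
  stopifnot(n_clusters >= 1, cluster_diameter_nm > 0,
            molecules_per_cluster_mean > 0,
            background_molecule_density_um2 >= 0,
            k_on >= 0, k_off > 0, exposure_s > 0, n_frames >= 1,
            min_cluster_margin_nm >= 0, inherits(roi, "roi"),
            precision_shape > 0, precision_rate > 0)
  structure(as.list(environment()), class = "blink_config")
}

# on-frame indices for one molecule: alternating geometric sojourns of the
# discrete two-state chain with per-frame switch probabilities
# p(on->off) = 1 - exp(-k_off * dt), p(off->on) = 1 - exp(-k_on * dt),
# initial state from the chain's stationary law
blink_on_frames <- function(n_frames, p_off_on, p_on_off) {
  if (p_off_on <= 0) return(integer(0))  # stationary state is off forever
  on <- runif(1) < p_off_on / (p_off_on + p_on_off)
  f <- 1L
  out <- integer(0)
  while (f <= n_frames) {
    run <- 1L + rgeom(1, if (on) p_on_off else p_off_on)
    if (on) out <- c(out, f:min(f + run - 1L, n_frames))
    f <- f + run
    on <- !on
  }
  out
}

#' Simulate blinking SMLM acquisition at the localization level
#'
#' Places molecules (uniform within each disc-shaped cluster; a Poisson number
#' of background molecules uniform on the ROI outside all discs), switches
#' each molecule between a fluorescent on state and a dark off state as a
#' discrete two-state chain across frames, and emits one localization per
#' on-frame at the molecule position plus isotropic Gaussian error with a
#' precision drawn from the configured gamma law. No camera image is rendered;
#' the emulation works directly on localizations.
#'
#' @param config a [blink_config()].
#' @return A [localization_table()] with `frame`, `molecule_id` and
#'   `true_label` (0 = background molecule), sorted by frame.
#' @export
simulate_blinking <- function(config) {
  stopifnot(inherits(config, "blink_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  R <- config$cluster_diameter_nm / 2
  centers <- place_centers(config$n_clusters, config$roi, min_sep = 0,
                           margin = config$min_cluster_margin_nm,
                           disc_d = config$cluster_diameter_nm)

  # molecules inside the discs
  n_per <- rpois(config$n_clusters, config$molecules_per_cluster_mean)
  rad <- R * sqrt(runif(sum(n_per)))
  th <- runif(sum(n_per), 0, 2 * pi)
  mol_x <- rep(centers[, "x"], n_per) + rad * cos(th)
  mol_y <- rep(centers[, "y"], n_per) + rad * sin(th)
  mol_lab <- rep(seq_len(config$n_clusters), n_per)

  # background molecules: Poisson count at the configured density over the
  # ROI area outside the discs, placed by rejection against the discs
  area_out_um2 <- roi_area_um2(config$roi) -
    config$n_clusters * pi * R^2 / 1e6
  n_bg <- rpois(1, config$background_molecule_density_um2 * area_out_um2)
  bx <- numeric(0); by <- numeric(0)
  while (length(bx) < n_bg) {
    need <- n_bg - length(bx)
    px <- runif(need, 0, config$roi$width_nm)
    py <- runif(need, 0, config$roi$height_nm)
    ok <- rep(TRUE, need)
    for (k in seq_len(config$n_clusters)) {
      ok <- ok & ((px - centers[k, "x"])^2 + (py - centers[k, "y"])^2 > R^2)
    }
    bx <- c(bx, px[ok]); by <- c(by, py[ok])
  }
  mol_x <- c(mol_x, bx); mol_y <- c(mol_y, by)
  mol_lab <- c(mol_lab, integer(n_bg))

  p_on_off <- 1 - exp(-config$k_off * config$exposure_s)
  p_off_on <- 1 - exp(-config$k_on * config$exposure_s)
  frames <- lapply(seq_along(mol_x), function(i)
    blink_on_frames(config$n_frames, p_off_on, p_on_off))
  n_locs <- lengths(frames)
  mol_of <- rep(seq_along(mol_x), n_locs)
  frame <- unlist(frames, use.names = FALSE)
  n <- length(frame)
  sd_nm <- rgamma(n, shape = config$precision_shape,
                  rate = config$precision_rate)
  tbl <- localization_table(
    x_nm = mol_x[mol_of] + rnorm(n, 0, sd_nm),
    y_nm = mol_y[mol_of] + rnorm(n, 0, sd_nm),
    sd_nm = sd_nm, frame = frame, molecule_id = mol_of,
    true_label = mol_lab[mol_of]
  )
  ord <- order(tbl$frame, tbl$molecule_id)
  tbl <- tbl[ord, , drop = FALSE]
  rownames(tbl) <- NULL
  validate_localizations(tbl)
}

#' Group spatio-temporally adjacent localizations
#'
#' Chains localizations that are at most `dX_nm` apart and at most `dT`
#' frames apart (with `dT = 1` only detections in adjacent frames merge;
#' larger `dT` lets a fluorophore pass through dark frames and still be
#' counted as the same activation). Each chain is replaced by a
#' single localization at the precision-weighted mean position, with combined
#' precision `1/sqrt(sum(1/sd_i^2))` and the first frame of the chain.
#' Localizations in the same frame are never merged. Chaining is greedy in
#' frame order: each localization joins the nearest eligible chain (ties to
#' the chain started at the lower row index) or starts a new one.
#'
#' @param tbl a [localization_table()] with a `frame` column.
#' @param dT maximum frame difference between consecutive detections of a
#'   chain.
#' @param dX_nm maximum distance (nm) between consecutive detections of a
#'   chain. The default 96 nm corresponds to one camera pixel.
#' @return A [localization_table()] with one row per chain.
#' @export
group_localizations <- function(tbl, dT = 1, dX_nm = 96) {
  tbl <- validate_localizations(tbl)
  if (!"frame" %in% names(tbl))
    stop("group_localizations() needs a frame column", call. = FALSE)
  if (nrow(tbl) == 0) return(tbl)
  ord <- order(tbl$frame, seq_len(nrow(tbl)))
  s <- tbl[ord, , drop = FALSE]
  chain <- .group_chains_cpp(s$x_nm, s$y_nm, as.integer(s$frame),
                             as.integer(dT), as.numeric(dX_nm))
  w <- 1 / s$sd_nm^2
  sw <- as.numeric(tapply(w, chain, sum))
  keys <- sort(unique(chain))
  first <- match(keys, chain)  # rows are frame-ordered, so first = chain start
  x <- as.numeric(tapply(w * s$x_nm, chain, sum)) / sw
  y <- as.numeric(tapply(w * s$y_nm, chain, sum)) / sw
  sd <- 1 / sqrt(sw)
  # single-member chains pass through bit-identically
  one <- tabulate(chain)[keys] == 1L
  x[one] <- s$x_nm[first[one]]
  y[one] <- s$y_nm[first[one]]
  sd[one] <- s$sd_nm[first[one]]
  localization_table(
    x_nm = x, y_nm = y, sd_nm = sd,
    frame = s$frame[first],
    molecule_id = if ("molecule_id" %in% names(s)) s$molecule_id[first] else NULL,
    true_label = if ("true_label" %in% names(s)) s$true_label[first] else NULL
  )
}
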