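STORE_VERSION <- "1.0"

# Single-file HDF5 layout:
#   /               attrs: store_version, valid (0 while a write is in flight)
#   /localizations  one dataset per column
#   /roi            attrs width_nm, height_nm
#   /proposals/<method>/<r>_<T>/labels
#   /proposals/<method>/scores        one row per grid point
#   /best           attrs method, r_nm, T, log_score
#   /stats          per-cluster statistics table

h5_root_attr <- function(path, name, value) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  gid <- rhdf5::H5Gopen(fid, "/")
  on.exit(rhdf5::H5Gclose(gid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, gid, name)
  invisible(NULL)
}

h5_group_attrs <- function(path, group, values) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  gid <- rhdf5::H5Gopen(fid, group)
  on.exit(rhdf5::H5Gclose(gid), add = TRUE, after = FALSE)
  for (nm in names(values)) rhdf5::h5writeAttribute(values[[nm]], gid, nm)
  invisible(NULL)
}

#' Open (or create) an analysis store
#'
#' All artifacts of one analysis run — the localization table, the ROI, the
#' scores and labels of every cluster proposal, the selected best proposal,
#' and the cluster statistics — live in a single HDF5 file.
#'
#' @param path path to the HDF5 file.
#' @param mode `"rw"` creates the file if absent; `"r"` requires it to exist.
#' @return A store handle of class `smlm_store`.
#' @export
open_store <- function(path, mode = c("rw", "r")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    if (mode == "r") stop("store not found: ", path, call. = FALSE)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "proposals")
    h5_root_attr(path, "store_version", STORE_VERSION)
    h5_root_attr(path, "valid", 1L)
  } else {
    at <- rhdf5::h5readAttributes(path, "/")
    ver <- at[["store_version"]]
    if (is.null(ver) || !identical(as.character(ver), STORE_VERSION))
      stop("incompatible store version in ", path, ": found ",
           if (is.null(ver)) "<none>" else as.character(ver),
           ", need ", STORE_VERSION, call. = FALSE)
    if (!is.null(at[["valid"]]) && !identical(as.integer(at[["valid"]]), 1L))
      stop("store ", path, " is flagged invalid (interrupted write); ",
           "regenerate it", call. = FALSE)
  }
  structure(list(path = path, mode = mode), class = "smlm_store")
}

#' @export
print.smlm_store <- function(x, ...) {
  cat("<smlm_store> ", x$path, "\n", sep = "")
  print(rhdf5::h5ls(x$path, recursive = 2L))
  invisible(x)
}

store_write <- function(store, fun) {
  # flag the store invalid for the duration of a write, so an interrupted
  # write is detectable on the next open
  stopifnot(inherits(store, "smlm_store"))
  if (store$mode == "r") stop("store opened read-only", call. = FALSE)
  h5_root_attr(store$path, "valid", 0L)
  fun()
  h5_root_attr(store$path, "valid", 1L)
  invisible(store)
}

# link existence check that tolerates nested paths ("a/b/c")
h5_exists <- function(path, name) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  so_far <- ""
  for (p in parts) {
    so_far <- paste0(so_far, "/", p)
    if (!rhdf5::H5Lexists(fid, so_far)) return(FALSE)
  }
  TRUE
}

h5_replace <- function(path, name, value) {
  if (h5_exists(path, name)) rhdf5::h5delete(path, name)
  rhdf5::h5write(value, path, name)
}

#' Store and retrieve the localization table
#'
#' @param store an [open_store()] handle.
#' @param tbl a [localization_table()].
#' @return `get_table()` returns the table; writers return the store,
#'   invisibly.
#' @export
put_table <- function(store, tbl) {
  tbl <- validate_localizations(tbl)
  store_write(store, function() {
    if (h5_exists(store$path, "localizations"))
      rhdf5::h5delete(store$path, "localizations")
    rhdf5::h5createGroup(store$path, "localizations")
    for (col in names(tbl))
      rhdf5::h5write(tbl[[col]], store$path, paste0("localizations/", col))
  })
}

#' @rdname put_table
#' @export
get_table <- function(store) {
  if (!h5_exists(store$path, "localizations"))
    stop("store has no localization table", call. = FALSE)
  grp <- rhdf5::h5read(store$path, "localizations")
  ordered <- intersect(c("x_nm", "y_nm", "sd_nm", "frame", "molecule_id",
                         "true_label"), names(grp))
  do.call(localization_table, grp[ordered])
}

#' Store and retrieve the ROI
#' @param store an [open_store()] handle.
#' @param r an [roi()].
#' @export
put_roi <- function(store, r) {
  stopifnot(inherits(r, "roi"))
  store_write(store, function() {
    if (!h5_exists(store$path, "roi"))
      rhdf5::h5createGroup(store$path, "roi")
    h5_group_attrs(store$path, "roi",
                   list(width_nm = r$width_nm, height_nm = r$height_nm))
  })
}

#' @rdname put_roi
#' @export
get_roi <- function(store) {
  if (!h5_exists(store$path, "roi"))
    stop("store has no ROI", call. = FALSE)
  at <- rhdf5::h5readAttributes(store$path, "roi")
  roi(as.numeric(at$width_nm), as.numeric(at$height_nm))
}

proposal_key <- function(r_nm, T) {
  paste0(format(r_nm, trim = TRUE, scientific = FALSE), "_",
         format(T, trim = TRUE, scientific = FALSE))
}

#' Store and retrieve scored cluster proposals
#'
#' Writes one labels dataset per grid point under
#' `/proposals/<method>/<r>_<T>/labels` plus a per-method score table, and
#' reads them back as a [run_engine()]-style result.
#'
#' @param store an [open_store()] handle.
#' @param scored a `scored_proposals` object from [run_engine()].
#' @param method clustering method name (`"ripley"`, `"dbscan"`, `"tomato"`).
#' @export
put_scored_proposals <- function(store, scored) {
  stopifnot(inherits(scored, "scored_proposals"))
  store_write(store, function() {
    for (m in unique(scored$scores$method)) {
      rows <- which(scored$scores$method == m)
      base <- paste0("proposals/", m)
      if (h5_exists(store$path, base)) rhdf5::h5delete(store$path, base)
      rhdf5::h5createGroup(store$path, base)
      sc <- scored$scores[rows, c("r_nm", "T", "n_clusters", "log_score")]
      rhdf5::h5write(sc, store$path, paste0(base, "/scores"))
      for (i in rows) {
        key <- proposal_key(scored$scores$r_nm[i], scored$scores$T[i])
        rhdf5::h5createGroup(store$path, paste0(base, "/", key))
        rhdf5::h5write(as.integer(scored$labels[[i]]), store$path,
                       paste0(base, "/", key, "/labels"))
      }
    }
  })
}

#' @rdname put_scored_proposals
#' @export
get_scored_proposals <- function(store, method) {
  base <- paste0("proposals/", method)
  if (!h5_exists(store$path, base))
    stop("store has no proposals for method '", method, "'", call. = FALSE)
  sc <- rhdf5::h5read(store$path, paste0(base, "/scores"))
  sc <- data.frame(method = method, r_nm = as.numeric(sc$r_nm),
                   T = as.numeric(sc$T),
                   n_clusters = as.integer(sc$n_clusters),
                   log_score = as.numeric(sc$log_score))
  labels <- lapply(seq_len(nrow(sc)), function(i) {
    as.integer(rhdf5::h5read(store$path, paste0(
      base, "/", proposal_key(sc$r_nm[i], sc$T[i]), "/labels")))
  })
  structure(list(scores = sc, labels = labels), class = "scored_proposals")
}

#' Store and retrieve the selected best proposal
#' @param store an [open_store()] handle.
#' @param best the result of [select_best()].
#' @export
put_best <- function(store, best) {
  store_write(store, function() {
    if (!h5_exists(store$path, "best"))
      rhdf5::h5createGroup(store$path, "best")
    h5_group_attrs(store$path, "best",
                   list(method = best$method, r_nm = best$r_nm, T = best$T,
                        log_score = best$log_score))
    h5_replace(store$path, "best/labels", as.integer(best$labels))
  })
}

#' @rdname put_best
#' @export
get_best <- function(store) {
  if (!h5_exists(store$path, "best"))
    stop("store has no best proposal", call. = FALSE)
  at <- rhdf5::h5readAttributes(store$path, "best")
  list(method = as.character(at$method), r_nm = as.numeric(at$r_nm),
       T = as.numeric(at$T), log_score = as.numeric(at$log_score),
       labels = as.integer(rhdf5::h5read(store$path, "best/labels")))
}

#' Store and retrieve per-cluster statistics
#' @param store an [open_store()] handle.
#' @param stats the `clusters` data frame of a [cluster_statistics()] result.
#' @export
put_stats <- function(store, stats) {
  store_write(store, function() h5_replace(store$path, "stats", stats))
}

#' @rdname put_stats
#' @export
get_stats <- function(store) {
  if (!h5_exists(store$path, "stats"))
    stop("store has no statistics", call. = FALSE)
  df <- rhdf5::h5read(store$path, "stats")
  as.data.frame(lapply(df, as.vector))
}
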