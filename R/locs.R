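#' Localization tables
#'
#' A localization table is a data frame with one row per localization:
#' `x_nm`, `y_nm` (position in nanometres), `sd_nm` (localization precision,
#' the standard deviation reported by the localization software), and
#' optionally `frame` (non-negative acquisition frame), `molecule_id` and
#' `true_label` (ground truth; `true_label = 0` means background). Positions
#' are always in nm with the ROI origin at (0, 0) and y increasing upward.
#'
#' @param x_nm,y_nm numeric positions in nm.
#' @param sd_nm positive localization precisions in nm.
#' @param frame optional integer frame numbers (all rows or none).
#' @param molecule_id,true_label optional integer ground-truth annotations.
#' @return A `localization_table` (also a `data.frame`).
#' @export
localization_table <- function(x_nm, y_nm, sd_nm, frame = NULL,
                               molecule_id = NULL, true_label = NULL) {
  tbl <- data.frame(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                    sd_nm = as.numeric(sd_nm))
  if (!is.null(frame)) tbl$frame <- as.integer(frame)
  if (!is.null(molecule_id)) tbl$molecule_id <- as.integer(molecule_id)
  if (!is.null(true_label)) tbl$true_label <- as.integer(true_label)
  class(tbl) <- c("localization_table", "data.frame")
  validate_localizations(tbl)
}

#' Validate a localization table
#'
#' Checks the structural invariants: finite coordinates, strictly positive
#' precisions, and a frame column that is either absent or complete.
#'
#' @param tbl a data frame with at least `x_nm`, `y_nm`, `sd_nm`.
#' @return The validated table, invisibly classed as `localization_table`.
#' @export
validate_localizations <- function(tbl) {
  need <- c("x_nm", "y_nm", "sd_nm")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("localization table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(tbl)) {
    if (any(!is.finite(tbl$x_nm)) || any(!is.finite(tbl$y_nm)))
      stop("non-finite coordinates in localization table", call. = FALSE)
    bad <- which(!is.finite(tbl$sd_nm) | tbl$sd_nm <= 0)
    if (length(bad))
      stop("non-positive localization precision (STDEV) at row ", bad[1],
           call. = FALSE)
    if ("frame" %in% names(tbl) && any(is.na(tbl$frame)))
      stop("frame column must be present for all rows or none", call. = FALSE)
  }
  if (!inherits(tbl, "localization_table"))
    class(tbl) <- c("localization_table", "data.frame")
  tbl
}

#' Read a localization table from a delimited text file
#'
#' Accepts the `[X (nm), Y (nm), STDEV (nm)]` format produced by common
#' localization software, with an optional frame column. Column headers
#' `X (nm)` / `Y (nm)` / `STDEV (nm)` / `frame` are matched
#' case-insensitively (whitespace ignored); a headerless file is read
#' positionally as X, Y, STDEV(, frame). All values must already be in nm.
#'
#' @param path path to a CSV or TSV file.
#' @param dialect `"auto"` (sniff the separator), `"csv"` or `"tsv"`.
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- switch(dialect, auto = "auto", csv = ",", tsv = "\t")
  dt <- data.table::fread(path, sep = sep, header = "auto",
                          data.table = FALSE, showProgress = FALSE)
  if (nrow(dt) == 0 && ncol(dt) == 0) {
    # fread drops everything for a header-only file read positionally; retry
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, showProgress = FALSE)
  }
  norm <- function(s) gsub("[[:space:]]", "", tolower(s))
  nms <- norm(names(dt))
  find_col <- function(key) {
    hit <- which(nms == norm(key))
    if (length(hit)) hit[1] else NA_integer_
  }
  ix <- find_col("X (nm)"); iy <- find_col("Y (nm)"); is <- find_col("STDEV (nm)")
  named <- !is.na(ix) && !is.na(iy) && !is.na(is)
  if (!named) {
    # positional fallback: first three columns are X, Y, STDEV
    if (any(!is.na(c(ix, iy, is))))
      stop("file format error: expected columns 'X (nm)', 'Y (nm)', ",
           "'STDEV (nm)' but only found some of them in ", path, call. = FALSE)
    if (ncol(dt) < 3)
      stop("file format error: need at least 3 columns (X, Y, STDEV) in ",
           path, call. = FALSE)
    ix <- 1L; iy <- 2L; is <- 3L
  }
  ifr <- find_col("frame")
  if (!named && is.na(ifr) && ncol(dt) >= 4) ifr <- 4L
  localization_table(
    x_nm = dt[[ix]], y_nm = dt[[iy]], sd_nm = dt[[is]],
    frame = if (!is.na(ifr)) dt[[ifr]] else NULL
  )
}

#' Write a localization table to CSV
#'
#' @param tbl a [localization_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(tbl, path) {
  out <- data.frame(`X (nm)` = tbl$x_nm, `Y (nm)` = tbl$y_nm,
                    `STDEV (nm)` = tbl$sd_nm, check.names = FALSE)
  if ("frame" %in% names(tbl)) out$frame <- tbl$frame
  data.table::fwrite(out, path)
  invisible(path)
}

#' Rectangular region of interest
#'
#' The ROI is the rectangular field of view with its origin at (0, 0).
#'
#' @param width_nm,height_nm side lengths in nm, both positive.
#' @return An object of class `roi`.
#' @export
roi <- function(width_nm, height_nm) {
  stopifnot(is.numeric(width_nm), is.numeric(height_nm),
            width_nm > 0, height_nm > 0)
  structure(list(width_nm = as.numeric(width_nm),
                 height_nm = as.numeric(height_nm)), class = "roi")
}

#' @rdname roi
#' @param x an `roi`.
#' @export
roi_area_nm2 <- function(x) x$width_nm * x$height_nm

#' @rdname roi
#' @export
roi_area_um2 <- function(x) roi_area_nm2(x) / 1e6
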