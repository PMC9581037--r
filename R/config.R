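#' Read a simulation configuration from a YAML file
#'
#' The file mirrors the fields of [ground_truth_config()] or
#' [blink_config()]; a top-level `type: ground_truth` or `type: blinking`
#' selects the recipe, and `roi: {width_nm, height_nm}` is expanded to an
#' [roi()]. Omitted fields keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A `ground_truth_config` or `blink_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  type <- cfg$type
  if (is.null(type) || !type %in% c("ground_truth", "blinking"))
    stop("config must declare type: ground_truth or type: blinking",
         call. = FALSE)
  cfg$type <- NULL
  if (!is.null(cfg$roi)) cfg$roi <- roi(cfg$roi$width_nm, cfg$roi$height_nm)
  maker <- if (type == "ground_truth") ground_truth_config else blink_config
  unknown <- setdiff(names(cfg), names(formals(maker)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(maker, cfg)
}
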