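#' Left/right vocal-fold trajectory pair
#'
#' Container for a pair of uniformly sampled medial-edge distance signals
#' (distance of each fold's edge from the glottal midline at the
#' mid-membranous position), as extracted from high-speed videoendoscopy or
#' produced by the model.
#'
#' @param left,right Non-negative numeric vectors of equal length.
#' @param sample_rate Sampling rate in Hz (default 4000).
#' @param unit `"cm"` or `"px"`.
#' @param px_scale Optional metric size of one pixel (cm/px), recorded after
#'   conversion.
#' @param meta Optional named list of extra metadata (sex, subject id,
#'   ground truth for synthetic subjects, ...).
#' @return Object of class `trajectory_pair`.
#' @export
trajectory_pair <- function(left, right, sample_rate = 4000,
                            unit = c("cm", "px"), px_scale = NA_real_,
                            meta = list()) {
  unit <- match.arg(unit)
  left <- as.numeric(left); right <- as.numeric(right)
  if (length(left) != length(right))
    stop("left and right trajectories must have equal length", call. = FALSE)
  if (length(left) < 2) stop("trajectories too short", call. = FALSE)
  if (any(!is.finite(left)) || any(!is.finite(right)))
    stop("trajectories must be finite", call. = FALSE)
  if (min(left) < 0 || min(right) < 0)
    stop("edge distances must be non-negative", call. = FALSE)
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive", call. = FALSE)
  structure(list(left = left, right = right, sample_rate = sample_rate,
                 unit = unit, px_scale = px_scale, meta = meta),
            class = "trajectory_pair")
}

#' @export
print.trajectory_pair <- function(x, ...) {
  cat(sprintf("Trajectory pair: %d samples at %g Hz [%s]\n",
              length(x$left), x$sample_rate, x$unit))
  cat(sprintf("  left : mean %.4g, range [%.4g, %.4g]\n",
              mean(x$left), min(x$left), max(x$left)))
  cat(sprintf("  right: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$right), min(x$right), max(x$right)))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.trajectory_pair <- function(x) length(x$left)

#' Convert a pixel trajectory pair to metric units
#'
#' High-speed videoendoscopy yields trajectories in pixels. Using an assumed
#' vibrating vocal-fold length -- 10 mm for women, 16 mm for men, the average
#' membranous lengths reported in the morphometry literature -- and the
#' glottal-axis length in pixels, the metric size of one pixel is estimated
#' and applied.
#'
#' @param pair A `trajectory_pair` in pixel units.
#' @param axis_length_px Glottal-axis length in pixels (> 0).
#' @param sex `"female"` or `"male"` (assumed fold length 1.0 / 1.6 cm).
#' @return A `trajectory_pair` in cm with `px_scale` recorded.
#' @examples
#' px <- trajectory_pair(c(10, 12, 11), c(9, 11, 10), unit = "px")
#' pixel_to_metric(px, axis_length_px = 160, sex = "male")$px_scale  # 0.01
#' @export
pixel_to_metric <- function(pair, axis_length_px, sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(inherits(pair, "trajectory_pair"))
  if (!is.finite(axis_length_px) || axis_length_px <= 0)
    stop("axis_length_px must be > 0", call. = FALSE)
  assumed_cm <- if (sex == "female") 1.0 else 1.6
  scale <- assumed_cm / axis_length_px
  trajectory_pair(pair$left * scale, pair$right * scale,
                  sample_rate = pair$sample_rate, unit = "cm",
                  px_scale = scale,
                  meta = c(pair$meta, list(sex = sex)))
}

#' Estimate subject-specific rest geometry from a trajectory pair
#'
#' The model's rest half-gaps are tied to the recording by setting both
#' x01 and x02 to the time- and side-averaged edge distance, and the rest
#' areas to a0i = 2 l x0i (the rectangular-glottis identity the reference
#' parameter set itself satisfies).
#'
#' @param pair A `trajectory_pair` in metric units.
#' @param std A `tmm_params` set providing the fold length `l`.
#' @return A `tmm_params` set with updated `x01`, `x02`, `a01`, `a02`.
#' @export
estimate_rest_geometry <- function(pair, std) {
  stopifnot(inherits(pair, "trajectory_pair"), inherits(std, "tmm_params"))
  if (pair$unit != "cm") stop("convert to metric units first", call. = FALSE)
  x0 <- mean(c(mean(pair$left), mean(pair$right)))
  if (x0 <= 0) stop("degenerate input: all-zero trajectories", call. = FALSE)
  std$x01 <- std$x02 <- x0
  std$a01 <- std$a02 <- 2 * std$l * x0
  validate_parameters(std)
  std
}

#' Read / write trajectory CSV files
#'
#' The on-disk format is a plain CSV with header `frame,time_ms,left,right`
#' preceded by `#`-prefixed metadata lines: `# unit=px|cm`, `# fps=4000`,
#' and optionally `# axis_length_px=...`, `# sex=F|M`, `# px_scale=...`,
#' plus arbitrary `# key=value` pairs (ground-truth parameters of synthetic
#' subjects are stored this way). Frames must be consecutive integers and
#' sampling uniform.
#'
#' @param path File path.
#' @return `read_trajectory_csv()` returns a `trajectory_pair`;
#'   `write_trajectory_csv()` invisibly returns `path`.
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (i in which(is_meta)) {
    kv <- sub("^#\\s*", "", lines[i])
    m <- regmatches(kv, regexec("^([^=]+)=(.*)$", kv))[[1]]
    if (length(m) != 3)
      stop("malformed metadata at line ", i, ": ", lines[i], call. = FALSE)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  for (req in c("unit", "fps")) {
    if (is.null(meta[[req]]))
      stop("missing required metadata line '# ", req, "=...'", call. = FALSE)
  }
  body <- lines[!is_meta]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("frame", "time_ms", "left", "right")
  if (!all(need %in% names(df)))
    stop("CSV header must contain frame,time_ms,left,right", call. = FALSE)
  if (nrow(df) < 2) stop("too few samples", call. = FALSE)
  if (any(diff(df$frame) != 1)) {
    bad <- which(diff(df$frame) != 1)[1]
    stop("non-consecutive frames near data row ", bad + 1, call. = FALSE)
  }
  dt <- diff(df$time_ms)
  if (max(abs(dt - dt[1])) > 1e-6 * max(abs(dt[1]), 1e-12))
    stop("non-uniform sampling in time_ms column", call. = FALSE)
  if (abs(dt[1] - 1000 / meta$fps) > 1e-6)
    stop("time step inconsistent with '# fps' metadata", call. = FALSE)
  if (min(df$left) < 0 || min(df$right) < 0) {
    bad <- which(df$left < 0 | df$right < 0)[1]
    stop("negative edge distance at data row ", bad, call. = FALSE)
  }
  unit <- as.character(meta$unit)
  keep <- setdiff(names(meta), c("unit", "fps", "px_scale"))
  trajectory_pair(df$left, df$right, sample_rate = meta$fps, unit = unit,
                  px_scale = if (is.null(meta$px_scale)) NA_real_
                             else meta$px_scale,
                  meta = meta[keep])
}

#' @rdname read_trajectory_csv
#' @param pair A `trajectory_pair` to write.
#' @export
write_trajectory_csv <- function(pair, path) {
  stopifnot(inherits(pair, "trajectory_pair"))
  hdr <- c(sprintf("# unit=%s", pair$unit),
           sprintf("# fps=%s", format(pair$sample_rate, digits = 15)))
  if (!is.na(pair$px_scale))
    hdr <- c(hdr, sprintf("# px_scale=%s", format(pair$px_scale, digits = 15)))
  for (k in names(pair$meta)) {
    v <- pair$meta[[k]]
    if (is.numeric(v)) v <- format(v, digits = 15)
    hdr <- c(hdr, sprintf("# %s=%s", k, v))
  }
  n <- length(pair$left)
  frame <- seq_len(n) - 1L
  rows <- sprintf("%d,%.17g,%.17g,%.17g", frame,
                  frame * 1000 / pair$sample_rate, pair$left, pair$right)
  writeLines(c(hdr, "frame,time_ms,left,right", rows), path)
  invisible(path)
}
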