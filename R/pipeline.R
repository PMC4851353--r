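# End-to-end orchestration: configuration with provenance flags, frame and
# table I/O, and the three-stage detect -> track -> relink workflow.

#' Tracker configuration
#'
#' All tunables of the detection, tracking and relinking stages with their
#' defaults. Parameters marked `"calibrated"` in the `provenance` field
#' have no published value and were fixed once by calibration on the
#' synthetic generator; the others are the published model constants.
#'
#' @param spec body-model [rect_spec()].
#' @param threshold binarization threshold on the background difference,
#'   gray levels.
#' @param min_area minimum blob area, px (smaller components are dropped).
#' @param spacing boundary resampling spacing, px of arc.
#' @param neighbor_arc arc offset of the curvature/tangent support points, px.
#' @param kappa_min curvature threshold for nose/tail candidates, rad/px.
#' @param nms_window non-maximum-suppression window on the boundary, px.
#' @param nose_margin nose-to-head-front-edge margin, px.
#' @param n_pb candidate angles per body rectangle.
#' @param cover_min minimum admissible cover ratio.
#' @param k von Mises concentration for orientation similarity.
#' @param k_body von Mises concentration of body-tracking angle draws.
#' @param thr_ncc,thr_v association gates on NCC and orientation similarity.
#' @param kalman_q,kalman_r diagonals of the Kalman state/observation noise.
#' @param kalman_p0 initial covariance scale (times Q).
#' @param lost_max frames a tracker may coast before termination.
#' @param region_radius search radius (px) when locating the foreground
#'   component around a tracked head joint.
#' @param max_interf,max_interd relinking gates: maximum frame gap and
#'   endpoint distance (both exclusive).
#' @param tol_px nose-correctness tolerance for evaluation, px.
#' @return A `fishchain_config` list.
#' @export
fishchain_config <- function(spec = rect_spec(),
                             threshold = 80, min_area = NULL,
                             spacing = 1, neighbor_arc = 8,
                             kappa_min = 0.08, nms_window = 40,
                             nose_margin = 10, n_pb = 128, cover_min = 0.8,
                             k = 4, k_body = 4,
                             thr_ncc = 0.6, thr_v = 0.05,
                             kalman_q = c(1, 1, 0.01),
                             kalman_r = c(2, 2, 0.02), kalman_p0 = 1,
                             lost_max = 5L, region_radius = 2L,
                             max_interf = 6, max_interd = 80,
                             tol_px = 10) {
  if (is.null(min_area)) {
    min_area <- round(0.25 * sum(spec$lengths * spec$widths))
  }
  structure(list(
    spec = spec, threshold = threshold, min_area = min_area,
    spacing = spacing, neighbor_arc = neighbor_arc, kappa_min = kappa_min,
    nms_window = nms_window, nose_margin = nose_margin, n_pb = n_pb,
    cover_min = cover_min, k = k, k_body = k_body,
    thr_ncc = thr_ncc, thr_v = thr_v,
    kalman_q = kalman_q, kalman_r = kalman_r, kalman_p0 = kalman_p0,
    lost_max = as.integer(lost_max), region_radius = as.integer(region_radius),
    max_interf = max_interf, max_interd = max_interd, tol_px = tol_px,
    provenance = c(
      threshold = "calibrated", min_area = "calibrated",
      spacing = "calibrated", kappa_min = "calibrated",
      nms_window = "calibrated", nose_margin = "calibrated",
      n_pb = "calibrated", thr_ncc = "calibrated", thr_v = "calibrated",
      kalman_q = "calibrated", kalman_r = "calibrated",
      kalman_p0 = "calibrated", region_radius = "calibrated",
      neighbor_arc = "published", cover_min = "published",
      k = "published", k_body = "published", lost_max = "published",
      max_interf = "published", max_interd = "published",
      tol_px = "published")
  ), class = "fishchain_config")
}

#' Write / read a configuration as YAML
#'
#' @param config a [fishchain_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a `fishchain_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$spec <- list(n_r = config$spec$n_r, lengths = config$spec$lengths,
                 widths = config$spec$widths)
  x$provenance <- as.list(config$provenance)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- rect_spec(x$spec$n_r, unlist(x$spec$lengths), unlist(x$spec$widths))
  args <- x[setdiff(names(x), c("spec", "provenance"))]
  do.call(fishchain_config, c(list(spec = spec), args))
}

# --- frame I/O -------------------------------------------------------------

#' Read a directory of grayscale frames
#'
#' Frames are read in lexicographic filename order; PNG and TIFF are
#' supported. Values are rescaled to 0-255.
#'
#' @param dir directory of numbered image files.
#' @param pattern filename filter.
#' @return A list of grayscale matrices.
#' @export
read_frames <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("no frames found in ", dir)
  lapply(files, read_frame)
}

read_frame <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    img <- tiff_read(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * 255
}

tiff_read <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF requires the 'tiff' package")
  }
  tiff::readTIFF(path)
}

#' Write frames as numbered PNG files
#'
#' @param frames a list of matrices or a lazy `frame_seq`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return The vector of written paths, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- frames_length(frames)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf("%s_%05d.png", prefix, i))
    png::writePNG(pmin(pmax(frame_get(frames, i) / 255, 0), 1), paths[i])
  }
  invisible(paths)
}

#' Write / read a pose or trajectory table as CSV
#'
#' @param tab a pose table (see [poses_to_table()]).
#' @param path file path.
#' @return `write_poses` returns `path` invisibly; `read_poses` a tibble.
#' @export
write_poses <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_poses
#' @export
read_poses <- function(path) {
  as_tibble(read.csv(path))
}

# --- pipeline --------------------------------------------------------------

#' Run the full tracking pipeline
#'
#' Detection and tracking alternate per frame over the sequence; relinking
#' runs once as a postprocess. If ground truth is supplied the standard
#' metrics are computed. When `output_dir` is given, the trajectory table,
#' the link audit and a run manifest (configuration snapshot, seed,
#' package version) are written there.
#'
#' @param frames a list of matrices, a lazy `frame_seq`, or a directory
#'   path of image files.
#' @param config a [fishchain_config()].
#' @param background optional background image; estimated from the frames
#'   when NULL.
#' @param seed integer seed for the per-frame random draws.
#' @param n_fish optional known fish count passed to [relink()].
#' @param truth,events optional ground truth and occlusion log for
#'   evaluation.
#' @param output_dir optional directory for artifacts.
#' @return A list with `trajectories` (tibble), `tracklets` (pre-relinking),
#'   `links` (audit tibble), `metrics` (a `fish_metrics` or NULL), and
#'   `manifest`.
#' @export
run_pipeline <- function(frames, config = fishchain_config(),
                         background = NULL, seed = 1L, n_fish = NULL,
                         truth = NULL, events = NULL, output_dir = NULL) {
  if (is.character(frames)) frames <- read_frames(frames)
  if (frames_length(frames) == 0L) stop("empty frame sequence")
  tracklets <- track_sequence(frames, background, config, seed)
  rl <- relink(tracklets, config, n_fish = n_fish)
  trajectories <- trajectories_table(rl, config$spec)
  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- evaluate_tracking(trajectories, truth, events, config$tol_px)
  }
  manifest <- list(
    package = "fishchain",
    version = as.character(utils::packageVersion("fishchain")),
    seed = seed,
    n_frames = frames_length(frames),
    n_tracklets = length(tracklets),
    n_links = nrow(rl$links),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_poses(trajectories, file.path(output_dir, "trajectories.csv"))
    write_config(config, file.path(output_dir, "config.yaml"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (nrow(rl$links)) {
      jsonlite::write_json(rl$links, file.path(output_dir, "links.json"),
                           pretty = TRUE)
    }
    if (!is.null(metrics)) {
      jsonlite::write_json(glance(metrics),
                           file.path(output_dir, "metrics.json"),
                           pretty = TRUE)
    }
  }
  list(trajectories = trajectories, tracklets = tracklets, links = rl$links,
       metrics = metrics, manifest = manifest)
}
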