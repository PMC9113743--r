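# File interchange: multi-page TIFF stacks with JSON metadata sidecars,
# CSV tables for traces, tracks and summaries. TIFF pixel data are scaled
# into [0, 1] for storage; the sidecar records the scale so round trips
# are exact to the stored bit depth.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a frame stack as multi-page 16-bit TIFF + JSON sidecar
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  sc <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(t) stack$frames[, , t] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(type = "frame_stack", frame_rate_hz = stack$frame_rate_hz,
         pixel_size_mm = stack$pixel_size_mm, intensity_scale = sc),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path with `<path>.json` sidecar.
#' @return a `frame_stack`.
#' @export
read_frame_stack <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * meta$intensity_scale
  frame_stack(frames, meta$frame_rate_hz, meta$pixel_size_mm)
}

#' Write a BFI movie as multi-page 32-bit TIFF + JSON sidecar
#'
#' @param movie a `bfi_movie`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_bfi_movie <- function(movie, path) {
  stopifnot(inherits(movie, "bfi_movie"))
  sc <- max(movie$bfi, 1e-12)
  pages <- lapply(seq_len(dim(movie$bfi)[3]), function(t) movie$bfi[, , t] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  jsonlite::write_json(
    list(type = "bfi_movie", sample_rate_hz = movie$sample_rate_hz,
         window_len = movie$window_len, stride = movie$stride,
         bfi_cap = movie$bfi_cap, pixel_size_mm = movie$pixel_size_mm,
         bfi_scale = sc),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a BFI movie written by [write_bfi_movie()]
#'
#' @param path TIFF path with `<path>.json` sidecar.
#' @return a `bfi_movie`.
#' @export
read_bfi_movie <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  bfi <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) bfi[, , t] <- pages[[t]] * meta$bfi_scale
  structure(list(bfi = bfi, sample_rate_hz = meta$sample_rate_hz,
                 window_len = meta$window_len, stride = meta$stride,
                 bfi_cap = meta$bfi_cap, pixel_size_mm = meta$pixel_size_mm,
                 time_s = (seq_along(pages) - 1) / meta$sample_rate_hz),
            class = "bfi_movie")
}

#' Write vessel traces as CSV (time column + one column per vessel)
#'
#' @param traces a `vessel_traces`.
#' @param path CSV path.
#' @param what `"rbf"` (default) or `"traces"` (raw BFI).
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, what = c("rbf", "traces")) {
  stopifnot(inherits(traces, "vessel_traces"))
  what <- match.arg(what)
  m <- t(traces[[what]])
  colnames(m) <- paste0("v", seq_len(ncol(m)))
  utils::write.csv(data.frame(time_s = traces$time_s, m), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a traces CSV into a matrix (vessels x time)
#'
#' @param path CSV written by [write_traces_csv()].
#' @param sample_rate_hz sampling rate; inferred from the time column when
#'   NULL.
#' @return a `vessel_traces` (with `traces` == `rbf` renormalized).
#' @export
read_traces_csv <- function(path, sample_rate_hz = NULL) {
  df <- utils::read.csv(path)
  tm <- df$time_s
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  fs <- sample_rate_hz %||% (1 / stats::median(diff(tm)))
  structure(list(traces = m, rbf = m / rowMeans(m), time_s = tm,
                 sample_rate_hz = fs, centroids_mm = NULL),
            class = "vessel_traces")
}

#' Write a vessel map as labeled TIFF + centroid CSV
#'
#' @param vmap a `vessel_map`.
#' @param path_prefix writes `<prefix>_labels.tif` (+ sidecar) and
#'   `<prefix>_vessels.csv` (label, centroid_x_mm, centroid_y_mm, area_px).
#' @return `path_prefix`, invisibly.
#' @export
write_vessel_map <- function(vmap, path_prefix) {
  stopifnot(inherits(vmap, "vessel_map"))
  n <- max(1L, length(vmap$areas_px))
  tiff::writeTIFF(vmap$labels / n, paste0(path_prefix, "_labels.tif"),
                  bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(type = "vessel_labels", n_labels = length(vmap$areas_px),
         pixel_size_mm = vmap$pixel_size_mm),
    sidecar_path(paste0(path_prefix, "_labels.tif")),
    auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(label = seq_along(vmap$areas_px),
               centroid_x_mm = vmap$centroids_mm[, 1],
               centroid_y_mm = vmap$centroids_mm[, 2],
               area_px = vmap$areas_px),
    paste0(path_prefix, "_vessels.csv"), row.names = FALSE)
  invisible(path_prefix)
}

#' Write ground truth as CSV schedule + labeled TIFF
#'
#' @param truth a `ground_truth`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vm <- vessel_map_from_labels(truth$labels, truth$config$pixel_size_mm)
  write_vessel_map(vm, file.path(dir, "truth"))
  utils::write.csv(
    data.frame(vessel = seq_along(truth$cluster_labels),
               cluster = truth$cluster_labels,
               centroid_x_mm = truth$centroids_mm[, 1],
               centroid_y_mm = truth$centroids_mm[, 2]),
    file.path(dir, "truth_vessels.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = truth$time_s,
               t(truth$freq_schedule_hz)),
    file.path(dir, "truth_freq_schedule_hz.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a run bundle's tables and manifest
#'
#' Emits the S(t) series, cluster-membership histograms, distance table,
#' phase-pair table, wave fits and per-run metrics as CSV plus a JSON
#' manifest echoing every parameter. Identical bundle -> byte-identical
#' files.
#'
#' @param bundle a `run_bundle` from [run_all()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "run_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(time_s = bundle$match$time_s,
                              S = bundle$sync$S_t),
                   file.path(dir, "sync_degree.csv"), row.names = FALSE)
  utils::write.csv(bundle$sync$cluster_prob,
                   file.path(dir, "cluster_probability.csv"), row.names = FALSE)
  utils::write.csv(bundle$sync$cluster_prob_filtered,
                   file.path(dir, "cluster_probability_filtered.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$sync$duration_by_distance,
                   file.path(dir, "duration_by_distance.csv"), row.names = FALSE)
  utils::write.csv(bundle$sync$phase_pairs,
                   file.path(dir, "phase_pairs.csv"), row.names = FALSE)
  if (!is.null(bundle$waves))
    utils::write.csv(bundle$waves, file.path(dir, "wave_fits.csv"),
                     row.names = FALSE)
  utils::write.csv(bundle$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  write_vessel_map(bundle$vessel_map, file.path(dir, "segmented"))
  write_traces_csv(bundle$traces, file.path(dir, "rbf_traces.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
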