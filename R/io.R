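# Session readers/writers.  A session on disk is a directory with one
# multi-page 32-bit TIFF per condition (pages ordered trial-major:
# page = (trial-1)*n_frames + frame), a `session.json` metadata sidecar,
# and optionally `ground_truth.json` plus mask TIFFs.  TIFF pages are
# stored affinely normalised to [0, 1]; the affine (vmin, vmax) per
# condition lives in the sidecar, so values round-trip to ~1e-10 of the
# data range while metadata round-trips exactly.

tiff_normalise <- function(x) {
  vmin <- min(x); vmax <- max(x)
  scale <- if (vmax > vmin) vmax - vmin else 1
  list(pages = (x - vmin) / scale, vmin = vmin, vmax = vmax)
}

write_stack_tiff <- function(arr, path) {
  d <- dim(arr)
  norm <- tiff_normalise(arr)
  pages <- vector("list", d[3] * d[4])
  for (tr in seq_len(d[4])) for (f in seq_len(d[3]))
    pages[[(tr - 1L) * d[3] + f]] <- norm$pages[, , f, tr]
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  list(vmin = norm$vmin, vmax = norm$vmax, n_frames = d[3], n_trials = d[4],
       n_rows = d[1], n_cols = d[2])
}

read_stack_tiff <- function(path, meta) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_frames * meta$n_trials)
    stop(sprintf("%s: %d pages found, %d expected (%d frames x %d trials)",
                 path, length(pages), meta$n_frames * meta$n_trials,
                 meta$n_frames, meta$n_trials), call. = FALSE)
  arr <- array(0, dim = c(meta$n_rows, meta$n_cols, meta$n_frames,
                          meta$n_trials))
  for (tr in seq_len(meta$n_trials)) for (f in seq_len(meta$n_frames)) {
    pg <- pages[[(tr - 1L) * meta$n_frames + f]]
    if (!all(dim(pg) == c(meta$n_rows, meta$n_cols)))
      stop(sprintf("%s: page shape %s does not match declared %dx%d",
                   path, paste(dim(pg), collapse = "x"),
                   meta$n_rows, meta$n_cols), call. = FALSE)
    arr[, , f, tr] <- pg
  }
  arr * (meta$vmax - meta$vmin) + meta$vmin
}

#' Write an imaging session to disk
#'
#' @param session An [imaging_session()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path (`session.json`).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "imaging_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cond_meta <- list()
  for (nm in conditions(session)) {
    file <- paste0("cond_", nm, ".tiff")
    meta <- write_stack_tiff(session$data[[nm]], file.path(dir, file))
    meta$file <- file
    meta$spec <- unclass(session$condition_table[[nm]])
    cond_meta[[nm]] <- meta
  }
  manifest <- list(
    format = "curvmap-session-1",
    frame_rate_hz = session$frame_rate_hz,
    n_prestim_frames = session$n_prestim_frames,
    stim_duration_s = session$stim_duration_s,
    pixel_size_mm = session$pixel_size_mm,
    seed = session$seed,
    conditions = cond_meta)
  path <- file.path(dir, "session.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(session$ground_truth))
    write_ground_truth(session$ground_truth, dir)
  invisible(path)
}

write_ground_truth <- function(model, dir) {
  gt <- list(
    pixel_size_mm = model$pixel_size_mm,
    seed = model$seed,
    domains = model$domains,
    planted_progressions = model$planted_progressions,
    pinwheel_centers = model$pinwheel_centers)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tiff::writeTIFF(model$curvature_domain_mask * 1,
                  file.path(dir, "ground_truth_curvature_mask.tiff"),
                  bits.per.sample = 8L)
  invisible(NULL)
}

#' Read an imaging session from disk
#'
#' Validates the manifest (file existence, page counts, page shapes) and
#' reconstructs the [imaging_session()]; metadata round-trips exactly and
#' data to ~1e-10 of the per-condition range.
#'
#' @param dir Session directory or path to its `session.json`.
#' @return An [imaging_session()].
#' @export
read_session <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "session.json") else dir
  if (!file.exists(path))
    stop("no session manifest at ", path, call. = FALSE)
  man <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  base <- dirname(path)
  data <- list()
  condition_table <- list()
  for (nm in names(man$conditions)) {
    meta <- man$conditions[[nm]]
    fp <- file.path(base, meta$file)
    if (!file.exists(fp))
      stop("session file missing: ", fp, call. = FALSE)
    data[[nm]] <- read_stack_tiff(fp, meta)
    sp <- meta$spec
    condition_table[[nm]] <- structure(
      list(kind = sp$kind, curvature_ratio = as.numeric(sp$curvature_ratio),
           curve_orientation = sp$curve_orientation,
           orientation_deg = as.numeric(sp$orientation_deg),
           sf_cpd = as.numeric(sp$sf_cpd),
           size_deg = as.numeric(sp$size_deg),
           drift_speed_deg_s = as.numeric(sp$drift_speed_deg_s),
           phase = as.numeric(sp$phase),
           line_width_deg = as.numeric(sp$line_width_deg),
           chromatic = isTRUE(sp$chromatic),
           n_scramble_subunits = as.integer(sp$n_scramble_subunits),
           seed = as.integer(sp$seed)),
      class = "stimulus_spec")
  }
  imaging_session(data = data, condition_table = condition_table,
                  frame_rate_hz = as.numeric(man$frame_rate_hz),
                  n_prestim_frames = as.numeric(man$n_prestim_frames),
                  stim_duration_s = as.numeric(man$stim_duration_s),
                  pixel_size_mm = as.numeric(man$pixel_size_mm),
                  seed = if (is.null(man$seed)) NA_integer_ else
                    as.integer(man$seed))
}

write_map_tiff <- function(values, path) {
  norm <- tiff_normalise(values)
  tiff::writeTIFF(norm$pages, path, bits.per.sample = 32L,
                  compression = "none")
  list(vmin = norm$vmin, vmax = norm$vmax)
}

#' Write analysis outputs with a run manifest
#'
#' Maps go out as normalised 32-bit TIFFs (affine recorded in the
#' manifest), label images as 16-bit TIFFs, tables as CSV; the JSON run
#' manifest lists every produced file with its md5 checksum plus the full
#' parameter echo, so identical runs produce byte-identical CSVs and
#' manifests (modulo the timestamp-free design: no clock is recorded).
#'
#' @param maps Named list of matrices or `response_map`s.
#' @param domains Named list of `domain_set`s.
#' @param tables Named list of data.frames.
#' @param out_dir Output directory.
#' @param parameters List echoed verbatim into the manifest (thresholds,
#'   seeds, ...).
#' @return Invisibly, the manifest as a list (also written to
#'   `run_manifest.json`).
#' @export
write_outputs <- function(maps = list(), domains = list(), tables = list(),
                          out_dir, parameters = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (nm in names(maps)) {
    f <- paste0("map_", nm, ".tiff")
    aff <- write_map_tiff(map_values(maps[[nm]]), file.path(out_dir, f))
    files[[f]] <- c(aff, type = "map")
  }
  for (nm in names(domains)) {
    ds <- domains[[nm]]
    f <- paste0("labels_", nm, ".tiff")
    tiff::writeTIFF(ds$label_image / 65535, file.path(out_dir, f),
                    bits.per.sample = 16L)
    files[[f]] <- list(type = "labels", n_domains = nrow(ds$domains))
    ft <- paste0("domains_", nm, ".csv")
    utils::write.csv(ds$domains, file.path(out_dir, ft), row.names = FALSE)
    files[[ft]] <- list(type = "table")
  }
  for (nm in names(tables)) {
    f <- paste0("table_", nm, ".csv")
    utils::write.csv(tables[[nm]], file.path(out_dir, f), row.names = FALSE)
    files[[f]] <- list(type = "table")
  }
  for (f in names(files))
    files[[f]]$md5 <- unname(tools::md5sum(file.path(out_dir, f)))
  manifest <- list(format = "curvmap-run-1", parameters = parameters,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
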