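# File formats: spike datasets as a directory of CSV tables plus a YAML/JSON
# condition file; ROI tables and light fields as CSV/JSON. CSV dialect:
# comma-separated, UTF-8, header row, '.' decimal; times in seconds,
# distances in um on disk (mm appears only in reports).

#' Write a spike dataset to a directory of CSV tables
#'
#' Produces `units.csv`, `spikes.csv`, `trials.csv`, `conditions.yaml`,
#' optionally `waveforms.csv` (long format: unit_id, sample_idx, value), and
#' `metadata.json` (seed, trial window, sampling rate).
#'
#' @param dataset a `spike_dataset`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_spike_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$units, file.path(path, "units.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$spikes, file.path(path, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  conds <- lapply(dataset$conditions, function(cond) {
    cond <- unclass(cond)
    cond$center <- as.list(cond$center)
    cond
  })
  yaml::write_yaml(conds, file.path(path, "conditions.yaml"))
  if (!is.null(dataset$waveforms)) {
    wf <- dataset$waveforms
    long <- data.frame(
      unit_id = rep(dataset$units$unit_id, each = ncol(wf)),
      sample_idx = rep(seq_len(ncol(wf)), times = nrow(wf)),
      value = as.vector(t(wf)))
    utils::write.csv(long, file.path(path, "waveforms.csv"),
                     row.names = FALSE)
  }
  meta <- dataset$metadata
  meta$sampling_rate_hz <- dataset$sampling_rate_hz
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a spike dataset from a directory of CSV tables
#'
#' Counterpart of [write_spike_dataset()]. Schema and referential integrity
#' are validated; violations are reported with row numbers.
#'
#' @param path directory containing the tables.
#' @return A `spike_dataset`.
#' @export
read_spike_dataset <- function(path) {
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing file: ", fp, call. = FALSE)
    fp
  }
  units <- utils::read.csv(need("units.csv"))
  spikes <- utils::read.csv(need("spikes.csv"))
  trials <- utils::read.csv(need("trials.csv"))
  cond_file <- file.path(path, "conditions.yaml")
  if (!file.exists(cond_file)) cond_file <- file.path(path, "conditions.json")
  if (!file.exists(cond_file))
    stop("missing conditions.yaml/.json in ", path, call. = FALSE)
  raw <- if (grepl("json$", cond_file)) jsonlite::read_json(cond_file) else
    yaml::read_yaml(cond_file)
  conditions <- lapply(raw, function(cond) {
    photostim_protocol(
      wavelength_nm = cond$wavelength_nm,
      avg_power_mw = cond$avg_power_mw,
      beam_diameter_4sigma_um = cond$beam_diameter_4sigma_um,
      temporal_profile = cond$temporal_profile,
      duration_s = cond$duration_s,
      ramp_ms = cond$ramp_ms,
      center = unlist(cond$center))
  })
  waveforms <- NULL
  wf_file <- file.path(path, "waveforms.csv")
  if (file.exists(wf_file)) {
    long <- utils::read.csv(wf_file)
    ns <- max(long$sample_idx)
    waveforms <- matrix(NA_real_, nrow = nrow(units), ncol = ns)
    row <- match(long$unit_id, units$unit_id)
    waveforms[cbind(row, long$sample_idx)] <- long$value
  }
  meta_file <- file.path(path, "metadata.json")
  metadata <- if (file.exists(meta_file))
    jsonlite::read_json(meta_file, simplifyVector = TRUE) else list()
  srate <- metadata$sampling_rate_hz %||% 19531.25
  metadata$sampling_rate_hz <- NULL
  spike_dataset(units = units, spikes = spikes, trials = trials,
                conditions = conditions, waveforms = waveforms,
                sampling_rate_hz = srate, metadata = metadata)
}

#' Write an ROI table to CSV
#'
#' @param rois an `roi_table`.
#' @param file output CSV path; dose and wavelength metadata are stored as
#'   `# key: value` comment lines before the header.
#' @return `file`, invisibly.
#' @export
write_roi_table <- function(rois, file) {
  stopifnot(inherits(rois, "roi_table"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# dose_mw_min: %s", attr(rois, "dose_mw_min")), con)
  writeLines(sprintf("# wavelength_nm: %s", attr(rois, "wavelength_nm")), con)
  utils::write.csv(as.data.frame(rois), con, row.names = FALSE)
  invisible(file)
}

#' Read an ROI table from CSV
#'
#' @param file CSV with columns `x_um`, `y_um`, `z_um`, `F`; `# key: value`
#'   comment lines carry dose/wavelength metadata.
#' @return An `roi_table`.
#' @export
read_roi_table <- function(file) {
  hdr <- readLines(file, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    ln <- grep(paste0("# ", key, ":"), meta, value = TRUE, fixed = TRUE)
    if (length(ln) == 0L) return(NA_real_)
    suppressWarnings(as.numeric(sub(".*: ", "", ln[1L])))
  }
  df <- utils::read.csv(file, comment.char = "#")
  roi_table(df, dose_mw_min = get_meta("dose_mw_min"),
            wavelength_nm = get_meta("wavelength_nm"))
}

#' Write a light field to CSV + JSON metadata
#'
#' Long-format CSV (`x_um`, `y_um`, `z_um`, `intensity`) with a JSON sidecar
#' recording voxel size, origin and grid dimensions. A TIFF stack can be
#' written instead via the `tiff` package when available
#' (`format = "tiff"`).
#'
#' @param field a `light_field`.
#' @param file output path (`.csv`; metadata goes to `<file>.json`).
#' @param format `"csv"` (default) or `"tiff"`.
#' @return `file`, invisibly.
#' @export
write_light_field <- function(field, file, format = c("csv", "tiff")) {
  stopifnot(inherits(field, "light_field"))
  format <- match.arg(format)
  meta <- list(voxel_um = field$voxel_um, origin_um = field$origin_um,
               dims = dim(field$grid), normalization = "max = 1")
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("TIFF output requires the `tiff` package", call. = FALSE)
    d <- dim(field$grid)
    pages <- lapply(seq_len(d[3]), function(iz) field$grid[, , iz])
    tiff::writeTIFF(pages, file, bits.per.sample = 32L)
  } else {
    ax <- light_field_axes(field)
    df <- expand.grid(x_um = ax$x, y_um = ax$y, z_um = ax$z)
    df$intensity <- as.vector(field$grid)
    utils::write.csv(df, file, row.names = FALSE)
  }
  invisible(file)
}

#' Read an image stack from a multi-page TIFF with a JSON sidecar
#'
#' @param file TIFF path; voxel size is read from `<file>.json`
#'   (`voxel_um`).
#' @return List with `stack` (3-D array) and `voxel_um`.
#' @export
read_image_stack <- function(file) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the `tiff` package", call. = FALSE)
  sidecar <- paste0(file, ".json")
  if (!file.exists(sidecar))
    stop("missing voxel-size metadata sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$voxel_um))
    stop("sidecar lacks `voxel_um`", call. = FALSE)
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  list(stack = stack, voxel_um = meta$voxel_um)
}
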