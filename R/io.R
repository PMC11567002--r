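# Readers and writers for every artifact the pipeline touches: movies as
# multi-frame TIFF with a JSON calibration sidecar, CSV tables with
# schema validation, and JSON configs. All CSVs are UTF-8 with a header
# row and '.' as the decimal separator; units are part of column names.

# --- CSV schema validation -------------------------------------------------

# Read a CSV, check required columns, and coerce numeric columns with
# line-numbered errors. Rejects locale-style decimal commas.
.readCsvChecked <- function(path, required, numericCols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")))
  for (col in intersect(numericCols, names(df))) {
    raw <- df[[col]]
    commas <- grepl("^\\s*-?[0-9]+,[0-9]+\\s*$", raw)
    if (any(commas))
      stop(sprintf(paste0("%s, column '%s', line %d: decimal comma '%s' ",
                          "found; use '.' as the decimal separator"),
                   basename(path), col, which(commas)[1] + 1L,
                   raw[which(commas)[1]]))
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & nzchar(raw))
    if (length(bad))
      stop(sprintf("%s, column '%s', line %d: '%s' is not a number",
                   basename(path), col, bad[1] + 1L, raw[bad[1]]))
    df[[col]] <- num
  }
  df
}

# --- movies ---------------------------------------------------------------

#' Write a movie as multi-frame TIFF with a JSON calibration sidecar
#'
#' Photon-count movies are written as 16-bit integer TIFF (values must be
#' integers in 0..65535; non-integer movies are rounded with a warning).
#' Spatial and temporal calibration goes to `<path>.json`, never to TIFF
#' tags.
#'
#' @param movie a [Movie-class].
#' @param path output TIFF path.
#'
#' @return `path`, invisibly.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "Movie"))
  arr <- frames(movie)
  if (max(arr) > 65535)
    stop("pixel values exceed 65535; cannot be written as 16-bit TIFF")
  if (any(arr != round(arr))) {
    warning("non-integer pixel values rounded for 16-bit TIFF output")
    arr <- round(arr)
  }
  frameList <- lapply(seq_len(dim(arr)[3]), function(t) arr[, , t] / 65535)
  tiff::writeTIFF(frameList, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_nm = pixelSize(movie),
         frame_interval_s = frameInterval(movie)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-frame TIFF movie
#'
#' Calibration (pixel size, frame interval) is taken from the
#' `<path>.json` sidecar, or from the explicit arguments, which take
#' precedence; it is never guessed. A missing calibration is an error.
#'
#' @param path TIFF path.
#' @param pixelSizeNm,frameIntervalS explicit calibration overrides.
#'
#' @return A [Movie-class].
#' @export
readMovie <- function(path, pixelSizeNm = NULL, frameIntervalS = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  fl <- try(tiff::readTIFF(path, all = TRUE, as.is = TRUE), silent = TRUE)
  if (inherits(fl, "try-error"))
    stop(sprintf("not a readable TIFF (corrupt or truncated?): %s", path))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixelSizeNm)) pixelSizeNm <- meta$pixel_size_nm
    if (is.null(frameIntervalS)) frameIntervalS <- meta$frame_interval_s
  }
  if (is.null(pixelSizeNm) || is.null(frameIntervalS))
    stop(paste0("movie calibration missing: provide pixelSizeNm and ",
                "frameIntervalS explicitly or in a '", basename(sidecar),
                "' sidecar"))
  arr <- array(0, dim = c(dim(fl[[1]])[1], dim(fl[[1]])[2], length(fl)))
  for (t in seq_along(fl)) arr[, , t] <- fl[[t]]
  Movie(arr, pixelSizeNm = pixelSizeNm, frameIntervalS = frameIntervalS)
}

# --- ROIs -----------------------------------------------------------------

#' Read / write synapse ROI polygons
#'
#' CSV schema: `synapse_id`, `vertex` (1-based order within polygon),
#' `x_nm`, `y_nm`. Polygons are validated (unique ids, simple polygons).
#'
#' @param path CSV path.
#'
#' @return [readRois()] returns a [RoiSet-class]; [writeRois()] returns
#'   `path` invisibly.
#' @export
readRois <- function(path) {
  df <- .readCsvChecked(path, c("synapse_id", "vertex", "x_nm", "y_nm"),
                        c("vertex", "x_nm", "y_nm"))
  ids <- unique(df$synapse_id)
  polys <- lapply(ids, function(id) {
    sub <- df[df$synapse_id == id, , drop = FALSE]
    sub <- sub[order(sub$vertex), , drop = FALSE]
    cbind(x = sub$x_nm, y = sub$y_nm)
  })
  RoiSet(ids, polys)
}

#' @rdname readRois
#' @param rois a [RoiSet-class].
#' @export
writeRois <- function(rois, path) {
  stopifnot(is(rois, "RoiSet"))
  rowsList <- lapply(seq_along(roiIds(rois)), function(i) {
    p <- roiPolygons(rois)[[i]]
    data.frame(synapse_id = roiIds(rois)[i], vertex = seq_len(nrow(p)),
               x_nm = p[, 1], y_nm = p[, 2])
  })
  utils::write.csv(do.call(rbind, rowsList), path, row.names = FALSE)
  invisible(path)
}

# --- event / site / AZ tables --------------------------------------------

#' Read / write localized-event tables
#'
#' CSV schema: `synapse_id` (may be empty for unassigned events),
#' `frame`, `x_nm`, `y_nm`, `amplitude`, `background`, `sigma_nm`,
#' `precision_nm`, `n_kernels`.
#'
#' @param events event data.frame.
#' @param path CSV path.
#'
#' @return [readEventTable()] returns the data.frame;
#'   [writeEventTable()] returns `path` invisibly.
#' @export
writeEventTable <- function(events, path) {
  cols <- c("synapse_id", "frame", "x_nm", "y_nm", "amplitude",
            "background", "sigma_nm", "precision_nm", "n_kernels")
  if (!"synapse_id" %in% names(events)) events$synapse_id <- NA_character_
  utils::write.csv(events[, intersect(cols, names(events)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  .readCsvChecked(path, c("frame", "x_nm", "y_nm"),
                  c("frame", "x_nm", "y_nm", "amplitude", "background",
                    "sigma_nm", "precision_nm", "n_kernels"))
}

#' Write a release-site table
#'
#' CSV schema: `synapse_id`, `site_id`, `n_events`, `centroid_x_nm`,
#' `centroid_y_nm`, `diameter_nm`.
#'
#' @param sets list of [ReleaseSiteSet-class] objects.
#' @param path CSV path.
#'
#' @return `path`, invisibly. [readSiteTable()] returns the data.frame.
#' @export
writeSiteTable <- function(sets, path) {
  rowsList <- lapply(sets, function(s) {
    k <- nSites(s)
    data.frame(synapse_id = synapseId(s), site_id = seq_len(k),
               n_events = tabulate(siteAssignments(s), nbins = k),
               centroid_x_nm = siteCentroids(s)[, 1],
               centroid_y_nm = siteCentroids(s)[, 2],
               diameter_nm = siteDiameters(s))
  })
  utils::write.csv(do.call(rbind, rowsList), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  .readCsvChecked(path, c("synapse_id", "site_id", "n_events",
                          "centroid_x_nm", "centroid_y_nm", "diameter_nm"),
                  c("site_id", "n_events", "centroid_x_nm",
                    "centroid_y_nm", "diameter_nm"))
}

#' Write an active-zone geometry table
#'
#' CSV schema: `synapse_id`, `area_nm2`, `center_x_nm`, `center_y_nm`,
#' `n_events`, `degenerate`.
#'
#' @param geoms list of [AZGeometry-class] objects.
#' @param path CSV path.
#'
#' @return `path`, invisibly.
#' @export
writeAZTable <- function(geoms, path) {
  df <- data.frame(
    synapse_id = vapply(geoms, synapseId, character(1)),
    area_nm2 = vapply(geoms, azArea, numeric(1)),
    center_x_nm = vapply(geoms, function(g) azCenter(g)[1], numeric(1)),
    center_y_nm = vapply(geoms, function(g) azCenter(g)[2], numeric(1)),
    n_events = vapply(geoms, function(g) g@nEvents, integer(1)),
    degenerate = vapply(geoms, isDegenerate, logical(1))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- traces ---------------------------------------------------------------

#' Read / write fluorescence-trace tables
#'
#' CSV schema: `time_s`, `value`, `channel`, `roi_id`; one trace per
#' (roi_id, channel) pair, frames in time order. Windows are frame
#' ranges shared by all traces in the file.
#'
#' @param path CSV path.
#' @param baselineWindow,stimulusWindow integer(2) frame ranges applied
#'   to every trace read.
#'
#' @return [readTraces()] returns a named list of [Trace-class] objects
#'   (names `roi_id` or `roi_id.channel`); [writeTraces()] returns
#'   `path` invisibly.
#' @export
readTraces <- function(path, baselineWindow, stimulusWindow) {
  df <- .readCsvChecked(path, c("time_s", "value", "channel", "roi_id"),
                        c("time_s", "value"))
  key <- paste(df$roi_id, df$channel, sep = ".")
  oneChannel <- length(unique(df$channel)) == 1L
  out <- lapply(split(df, key), function(sub) {
    sub <- sub[order(sub$time_s), , drop = FALSE]
    dt <- stats::median(diff(sub$time_s))
    Trace(sub$value, frameIntervalS = dt,
          baselineWindow = baselineWindow, stimulusWindow = stimulusWindow)
  })
  if (oneChannel)
    names(out) <- sub("\\.[^.]*$", "", names(out))
  out
}

#' @rdname readTraces
#' @param traces named list of [Trace-class] objects.
#' @param channel channel label written for every trace.
#' @export
writeTraces <- function(traces, path, channel = "ch1") {
  stopifnot(length(traces) >= 1L, !is.null(names(traces)))
  rowsList <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    data.frame(time_s = (seq_along(traceValues(tr)) - 1) * frameInterval(tr),
               value = traceValues(tr), channel = channel, roi_id = id)
  })
  utils::write.csv(do.call(rbind, rowsList), path, row.names = FALSE)
  invisible(path)
}

# --- protocols and ground truth ------------------------------------------

#' Read / write a stimulus protocol as JSON
#'
#' @param protocol a [StimulusProtocol-class].
#' @param path JSON path.
#'
#' @return [readProtocol()] returns a [StimulusProtocol-class];
#'   [writeProtocol()] returns `path` invisibly.
#' @export
writeProtocol <- function(protocol, path) {
  stopifnot(is(protocol, "StimulusProtocol"))
  jsonlite::write_json(
    list(n_pulses = nPulses(protocol),
         frequency_hz = stimulusFrequency(protocol),
         frame_interval_s = frameInterval(protocol),
         n_baseline_frames = nBaselineFrames(protocol)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("n_pulses", "frequency_hz", "frame_interval_s",
            "n_baseline_frames")
  missing <- setdiff(need, names(j))
  if (length(missing))
    stop(sprintf("%s: missing protocol field(s): %s", basename(path),
                 paste(missing, collapse = ", ")))
  StimulusProtocol(j$n_pulses, j$frequency_hz, j$frame_interval_s,
                   j$n_baseline_frames)
}

#' Write / read synthetic ground truth
#'
#' The event stream goes to CSV (columns as in [sampleEvents()]); the
#' hidden AZ parameters go to a JSON sidecar `<path>.json` so recovery
#' tests can reload both.
#'
#' @param events event stream from [sampleEvents()].
#' @param az the generating [GroundTruthAZ-class].
#' @param path CSV path.
#'
#' @return [readGroundTruth()] returns `list(events, az)`;
#'   [writeGroundTruth()] returns `path` invisibly.
#' @export
writeGroundTruth <- function(events, az, path) {
  stopifnot(is(az, "GroundTruthAZ"))
  utils::write.csv(events, path, row.names = FALSE)
  jsonlite::write_json(
    list(site_x_nm = sitePositions(az)[, 1],
         site_y_nm = sitePositions(az)[, 2],
         site_rates = siteRates(az),
         az_radius_nm = azRadius(az),
         localization_sigma_nm = localizationSigma(az)),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  events <- .readCsvChecked(
    path, c("site", "pulse", "time_s", "frame", "x_true_nm", "y_true_nm",
            "x_nm", "y_nm"),
    c("site", "pulse", "time_s", "frame", "x_true_nm", "y_true_nm",
      "x_nm", "y_nm"))
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  az <- new("GroundTruthAZ",
            sitePositions = cbind(x = j$site_x_nm, y = j$site_y_nm),
            siteRates = j$site_rates, azRadiusNm = j$az_radius_nm,
            localizationSigmaNm = j$localization_sigma_nm)
  list(events = events, az = az)
}
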