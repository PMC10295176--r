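# File formats: ROI JSON/CSV, point and track CSV (columns fixed: x_um,
# y_um, channel, frame, t_s; 0-based frames), curve CSV with JSON sidecar,
# TIFF images.  All writes are atomic (temp file + rename).

.atomicWrite <- function(path, writer) {
  tmp <- tempfile(pattern = ".tmp-", tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  ok <- TRUE
  invisible(path)
}

#' Read a region of interest from JSON or CSV
#'
#' JSON layout: \code{{"outer": [[x,y],...], "holes": [[[x,y],...],...],
#' "units": "um"}}.  CSV layout: columns ring, x, y with ring 0 (or
#' "outer") for the outer boundary and 1, 2, ... for holes.
#'
#' @param path file path (.json or .csv)
#' @return a [RegionOfInterest-class]
#' @export
readROI <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    holes <- j$holes
    if (is.null(holes)) holes <- list()
    if (is.matrix(holes)) holes <- list(holes)
    if (is.array(holes) && length(dim(holes)) == 3)
      holes <- lapply(seq_len(dim(holes)[1]), function(i) holes[i, , ])
    return(RegionOfInterest(j$outer, holes = holes))
  }
  df <- read.csv(path)
  names(df) <- tolower(names(df))
  if (!all(c("ring", "x", "y") %in% names(df)))
    stop("ROI CSV needs columns ring, x, y: ", path)
  rid <- as.character(df$ring)
  isOuter <- rid %in% c("0", "outer")
  if (!any(isOuter)) stop("ROI CSV has no outer ring (ring = 0): ", path)
  outer <- cbind(df$x[isOuter], df$y[isOuter])
  holes <- lapply(split(df[!isOuter, ], rid[!isOuter]),
                  function(h) cbind(h$x, h$y))
  RegionOfInterest(outer, holes = unname(holes))
}

#' Write a region of interest as JSON
#' @param roi a [RegionOfInterest-class]
#' @param path output path
#' @export
writeROI <- function(roi, path) {
  .atomicWrite(path, function(tmp) {
    jsonlite::write_json(
      list(outer = roi@outer, holes = roi@holes, units = "um"),
      tmp, auto_unbox = TRUE, digits = NA)
  })
}

#' Read point patterns from CSV
#'
#' Expects columns x_um, y_um, channel (frame optional).  Points outside
#' the ROI are dropped with a warning (or raise an error).
#'
#' @param path CSV path
#' @param roi shared [RegionOfInterest-class]
#' @param onOutside "drop" (default, with warning) or "error"
#' @return named list of [PointPattern-class], one per channel
#' @export
readPointsCSV <- function(path, roi, onOutside = c("drop", "error")) {
  onOutside <- match.arg(onOutside)
  df <- read.csv(path)
  if (!all(c("x_um", "y_um", "channel") %in% names(df)))
    stop("points CSV needs columns x_um, y_um, channel: ", path)
  inside <- roiContains(roi, df$x_um, df$y_um)
  if (any(!inside)) {
    msg <- sprintf("%d point(s) outside the ROI in %s", sum(!inside), path)
    if (onOutside == "error") stop(msg)
    warning(msg, "; dropped")
    df <- df[inside, , drop = FALSE]
  }
  lapply(split(df, as.character(df$channel)), function(d)
    pointPattern(d$x_um, d$y_um, roi = roi, channel = d$channel[1]))
}

#' Write spot centres / points as CSV
#' @param df data.frame with at least x_um, y_um (channel, frame optional)
#' @param path output path
#' @export
writePointsCSV <- function(df, path) {
  .atomicWrite(path, function(tmp)
    write.csv(df, tmp, row.names = FALSE))
}

#' Read a detection series from CSV (frame, t_s, x_um, y_um)
#' @param path CSV path
#' @return data.frame
#' @export
readDetectionsCSV <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("detections CSV needs columns ", paste(need, collapse = ", "),
         ": ", path)
  df
}

#' Write a track set as CSV (track_id, frame, t_s, x_um, y_um)
#' @param ts a [TrackSet-class]
#' @param path output path
#' @export
writeTracksCSV <- function(ts, path) {
  .atomicWrite(path, function(tmp)
    write.csv(ts@tracks, tmp, row.names = FALSE))
}

#' Read a track set from CSV
#' @param path CSV path
#' @return a [TrackSet-class]
#' @export
readTracksCSV <- function(path) {
  df <- read.csv(path)
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("tracks CSV needs columns ", paste(need, collapse = ", "),
         ": ", path)
  uf <- sort(unique(df$frame))
  ut <- df$t_s[match(uf, df$frame)]
  dt <- if (length(uf) > 1) median(diff(ut) / diff(uf)) else 1
  new("TrackSet", tracks = df, dt = dt)
}

#' Write a summary curve or envelope as CSV with a JSON metadata sidecar
#'
#' @param x a [SummaryCurve-class] or [EnvelopeResult-class]
#' @param path CSV output path; the sidecar is written to
#'   paste0(path, ".json")
#' @export
writeCurveCSV <- function(x, path) {
  df <- as.data.frame(x)
  meta <- if (is(x, "EnvelopeResult")) {
    tst <- envelopeTest(x)
    list(statistic = x@statistic, nsim = x@nsim, alpha = x@alpha,
         intervals = x@intervals, reject = tst$reject,
         verdict = tst$verdict)
  } else {
    c(list(statistic = x@statistic), x@metadata)
  }
  .atomicWrite(path, function(tmp) write.csv(df, tmp, row.names = FALSE))
  .atomicWrite(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Read a single-channel TIFF as a calibrated image
#'
#' Calibration comes from `pixelSize` or, when NULL, from the TIFF
#' x-resolution tag (pixels per unit); an explicit error is raised when
#' neither is available.
#'
#' @param path TIFF path
#' @param pixelSize um per pixel, overrides any TIFF tag
#' @param channel channel label
#' @return a [CalibratedImage-class]
#' @export
readImageTIFF <- function(path, pixelSize = NULL, channel = "1") {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (is.null(pixelSize)) {
    xres <- attr(img, "x.resolution")
    if (is.null(xres) || !is.numeric(xres) || xres <= 0)
      stop("no pixel-size calibration: pass pixelSize or store TIFF ",
           "resolution tags (", path, ")")
    pixelSize <- 1 / xres
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  calibratedImage(as.matrix(img), pixelSize, channel)
}

#' Write a matrix (image or mask) as TIFF
#' @param m numeric matrix; values are rescaled to [0, 1]
#' @param path output path
#' @export
writeImageTIFF <- function(m, path) {
  m <- as.matrix(m) * 1.0
  hi <- max(m)
  if (hi > 0) m <- m / hi
  .atomicWrite(path, function(tmp) tiff::writeTIFF(m, tmp))
}
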