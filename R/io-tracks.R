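# Track file io: plain CSV (track_id, frame, t_s, x_um, y_um) and a
# TrackMate-dialect XML (Model/AllSpots/AllTracks with physical units).

#' Read single-particle tracks
#'
#' CSV files carry columns `track_id`, `frame` and either physical
#' coordinates (`x_um`, `y_um`) or pixel coordinates (`x`, `y`, requiring
#' `pixelSize`). TrackMate-dialect XML stores spots in physical units with
#' the frame interval in its image settings. Frame gaps are preserved;
#' windowed statistics downstream skip windows spanning a gap. Missing
#' calibration is an explicit error.
#'
#' @param path track file.
#' @param dialect `"csv"` or `"trackmate_xml"`.
#' @param pixelSize um/px, required for pixel-coordinate CSVs.
#' @param frameInterval s; required when the file does not carry it.
#' @return A [TrackSet-class].
#' @export
readTracks <- function(path, dialect = c("csv", "trackmate_xml"),
                       pixelSize = NULL, frameInterval = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("track_id", "frame") %in% names(d))) {
      stop("track CSV needs columns track_id and frame")
    }
    if (all(c("x_um", "y_um") %in% names(d))) {
      # already physical units
    } else if (all(c("x", "y") %in% names(d))) {
      if (is.null(pixelSize)) {
        stop("track CSV has pixel coordinates: provide pixelSize (um/px)")
      }
      d$x_um <- d$x * pixelSize
      d$y_um <- d$y * pixelSize
    } else {
      stop("track CSV needs x_um/y_um or x/y columns")
    }
    if (is.null(frameInterval)) {
      if ("t_s" %in% names(d)) {
        df <- diff(d$frame); dtv <- diff(d$t_s)
        ok <- df > 0
        if (!any(ok)) stop("cannot infer frame interval from a single frame")
        frameInterval <- stats::median(dtv[ok] / df[ok])
      } else {
        stop("provide frameInterval (s): CSV has no t_s column")
      }
    }
    if (!"t_s" %in% names(d)) d$t_s <- d$frame * frameInterval
    TrackSet(d[, c("track_id", "frame", "t_s", "x_um", "y_um")],
             frameInterval = frameInterval)
  } else {
    doc <- xml2::read_xml(path)
    spots <- xml2::xml_find_all(doc, ".//Model/AllSpots//Spot")
    if (!length(spots)) stop("no Spot elements under Model/AllSpots in ", path)
    sid <- xml2::xml_attr(spots, "ID")
    st <- data.frame(
      id = sid,
      frame = as.integer(xml2::xml_attr(spots, "FRAME")),
      x_um = as.numeric(xml2::xml_attr(spots, "POSITION_X")),
      y_um = as.numeric(xml2::xml_attr(spots, "POSITION_Y")),
      stringsAsFactors = FALSE)
    if (anyNA(st$x_um) || anyNA(st$y_um) || anyNA(st$frame)) {
      stop("malformed Spot element (missing FRAME/POSITION_X/POSITION_Y) in ",
           path)
    }
    if (is.null(frameInterval)) {
      ti <- xml2::xml_attr(
        xml2::xml_find_first(doc, ".//Settings/ImageData"), "timeinterval")
      if (is.na(ti)) {
        stop("no timeinterval in Settings/ImageData: provide frameInterval")
      }
      frameInterval <- as.numeric(ti)
    }
    tracks <- xml2::xml_find_all(doc, ".//Model/AllTracks/Track")
    rows <- lapply(tracks, function(tr) {
      tid <- xml2::xml_attr(tr, "TRACK_ID")
      edges <- xml2::xml_find_all(tr, "./Edge")
      ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                      xml2::xml_attr(edges, "SPOT_TARGET_ID")))
      miss <- setdiff(ids, st$id)
      if (length(miss)) {
        stop(sprintf("Track %s references unknown spot id(s): %s", tid,
                     paste(miss, collapse = ", ")))
      }
      td <- st[st$id %in% ids, ]
      data.frame(track_id = tid, frame = td$frame,
                 t_s = td$frame * frameInterval,
                 x_um = td$x_um, y_um = td$y_um, stringsAsFactors = FALSE)
    })
    TrackSet(do.call(rbind, rows), frameInterval = frameInterval)
  }
}

#' Write single-particle tracks
#'
#' @param tracks A [TrackSet-class].
#' @param path output file.
#' @param dialect `"csv"` or `"trackmate_xml"`.
#' @return Invisibly, `path`.
#' @export
writeTracks <- function(tracks, path, dialect = c("csv", "trackmate_xml")) {
  stopifnot(is(tracks, "TrackSet"))
  dialect <- match.arg(dialect)
  d <- trackData(tracks)
  if (dialect == "csv") {
    utils::write.csv(d, path, row.names = FALSE)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("TrackMate", version = "7.0")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "micron",
                               timeunits = "sec")
  allSpots <- xml2::xml_add_child(model, "AllSpots")
  d$spot_id <- seq_len(nrow(d))
  for (fr in sort(unique(d$frame))) {
    sf <- xml2::xml_add_child(allSpots, "SpotsInFrame",
                              frame = as.character(fr))
    sub <- d[d$frame == fr, ]
    for (i in seq_len(nrow(sub))) {
      xml2::xml_add_child(sf, "Spot", ID = as.character(sub$spot_id[i]),
                          FRAME = as.character(sub$frame[i]),
                          POSITION_T = as.character(sub$t_s[i]),
                          POSITION_X = as.character(sub$x_um[i]),
                          POSITION_Y = as.character(sub$y_um[i]))
    }
  }
  allTracks <- xml2::xml_add_child(model, "AllTracks")
  for (tid in unique(d$track_id)) {
    sub <- d[d$track_id == tid, ]
    tr <- xml2::xml_add_child(allTracks, "Track",
                              TRACK_ID = as.character(tid))
    if (nrow(sub) > 1L) {
      for (i in seq_len(nrow(sub) - 1L)) {
        xml2::xml_add_child(tr, "Edge",
                            SPOT_SOURCE_ID = as.character(sub$spot_id[i]),
                            SPOT_TARGET_ID = as.character(sub$spot_id[i + 1]))
      }
    }
  }
  settings <- xml2::xml_add_child(doc, "Settings")
  xml2::xml_add_child(settings, "ImageData", pixelwidth = "1",
                      timeinterval = as.character(frameInterval(tracks)))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Dwell durations of each track as a DwellDataset
#'
#' The observed dwell of a molecule is the number of frames its track was
#' followed times the lapse interval.
#'
#' @param tracks A [TrackSet-class] acquired at one lapse interval.
#' @param integrationTime exposure per frame, s.
#' @return A [DwellDataset-class].
#' @export
dwellFromTracks <- function(tracks, integrationTime) {
  stopifnot(is(tracks, "TrackSet"))
  d <- trackData(tracks)
  nF <- vapply(split(d$frame, d$track_id), length, integer(1))
  DwellDataset(lapseInterval = frameInterval(tracks),
               integrationTime = integrationTime,
               durations = nF * frameInterval(tracks))
}
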