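#' @import methods
#' @import stats
#' @importFrom graphics hist
#' @importFrom utils packageVersion read.csv write.csv
NULL

#' Frame stack of an image series
#'
#' @param x An [ImageSeries-class] object.
#' @return A numeric array with dimensions height x width x frames.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Pixel size in micrometres per pixel
#'
#' @param x An object carrying spatial calibration.
#' @return Numeric scalar, um/px.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Frame interval in seconds
#'
#' @param x An object carrying temporal calibration.
#' @return Numeric scalar, s.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Number of frames
#'
#' @param x An [ImageSeries-class] object.
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Channel label
#'
#' @param x An [ImageSeries-class] object.
#' @return Character label.
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' Track table of a TrackSet
#'
#' @param x A [TrackSet-class] object.
#' @return A data.frame with columns `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`.
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))

#' Track identifiers
#'
#' @param x A [TrackSet-class] object.
#' @return Vector of track ids.
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' Number of tracks
#'
#' @param x A [TrackSet-class] object.
#' @return Integer count.
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' Fitted parameter values
#'
#' @param x A [FitResult-class] object.
#' @return Named numeric vector of parameter estimates.
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' Standard errors of fitted parameters
#'
#' @param x A [FitResult-class] object.
#' @return Named numeric vector of standard errors.
#' @export
setGeneric("fitStderr", function(x) standardGeneric("fitStderr"))

#' Did the fit converge cleanly?
#'
#' @param x A [FitResult-class] object.
#' @return Logical scalar; `FALSE` flags degenerate or non-converged fits.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
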