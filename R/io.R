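# Serialization helpers beyond the per-class writers: centerline polyline
# JSON, cross-section report rows, and a key-value measurement config.

#' Centerline polyline JSON round trip
#'
#' @param centerline a \linkS4class{Centerline}.
#' @param path .json path.
#' @return \code{writeCenterlineJSON}: the path, invisibly;
#'   \code{readCenterline}: a \linkS4class{Centerline} (reads both the JSON
#'   polyline and the CSV written by [writeCenterline()]).
#' @export
writeCenterlineJSON <- function(centerline, path) {
    out <- list(points = as.data.frame(centerline@points,
                                       col.names = c("x", "y", "z")),
                radius = centerline@radius,
                cumLength = centerline@cumLength,
                curveType = centerline@curveType)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCenterlineJSON
#' @export
readCenterline <- function(path) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        js <- jsonlite::read_json(path, simplifyVector = TRUE)
        return(Centerline(as.matrix(js$points), radius = js$radius,
                          curveType = if (is.null(js$curveType)) NA_integer_
                                      else js$curveType))
    }
    df <- utils::read.csv(path)
    Centerline(as.matrix(df[, c("x", "y", "z")]), radius = df$radius,
               curveType = df$type[1])
}

#' One CSV-ready report row for a measured cross-section
#'
#' @param cs a \linkS4class{CrossSection}.
#' @param id model or vessel identifier.
#' @return data.frame with id, center position, diameters, area and the
#'   count of flagged rays.
#' @export
crossSectionReport <- function(cs, id = NA_character_) {
    data.frame(id = id, x = cs@center[1], y = cs@center[2], z = cs@center[3],
               d_min = cs@dMin, d_max = cs@dMax, d_avg = cs@dAvg,
               PPP = cs@area, flagged = sum(cs@flags != 0L))
}

#' Load measurement configuration from a YAML key-value file
#'
#' Recognized top-level blocks: \code{crossSection}, \code{tracking},
#' \code{zone}; each holds arguments for [crossSectionConfig()],
#' [trackingConfig()] and [zoneConfig()]. Missing keys keep the package
#' defaults.
#'
#' @param path YAML file.
#' @return list(crossSection, tracking, zone) of validated config lists.
#' @export
readMeasurementConfig <- function(path) {
    y <- yaml::read_yaml(path)
    list(crossSection = do.call(crossSectionConfig,
                                as.list(y$crossSection %||% list())),
         tracking = do.call(trackingConfig, as.list(y$tracking %||% list())),
         zone = do.call(zoneConfig, as.list(y$zone %||% list())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
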