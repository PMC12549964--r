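## Plain-text serialization: footprint sets and ejecta as JSON array
## containers, cutoff/variance reports as JSON, run configs as YAML.

#' Write a footprint set to a JSON container
#'
#' Each footprint is stored with its raw counts, orientation quaternion
#' (w, x, y, z), efficiency and source label.
#'
#' @param footprints list of \linkS4class{Footprint}s.
#' @param path output file.
#' @export
writeFootprints <- function(footprints, path) {
  recs <- lapply(footprints, function(fp) list(
    counts = fp@counts,
    orientation = fp@orientation,
    efficiency = fp@efficiency,
    sourceLabel = fp@sourceLabel))
  jsonlite::write_json(recs, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a footprint set from a JSON container
#' @param path file written by \code{\link{writeFootprints}}.
#' @return list of \linkS4class{Footprint}s.
#' @export
readFootprints <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    cnt <- do.call(rbind, lapply(r$counts, unlist))
    cnt <- matrix(as.integer(cnt), nrow(cnt), ncol(cnt))
    new("Footprint", counts = cnt,
        orientation = as.numeric(unlist(r$orientation)),
        efficiency = as.numeric(r$efficiency),
        nDetected = sum(cnt),
        sourceLabel = as.character(r$sourceLabel))
  })
}

#' Write ion ejecta to a JSON container
#' @param ejecta an \linkS4class{IonEjecta}.
#' @param path output file.
#' @export
writeEjecta <- function(ejecta, path) {
  jsonlite::write_json(list(
    directions = ejecta@directions,
    speeds = ejecta@speeds,
    charges = ejecta@charges,
    masses = ejecta@masses,
    sourceLabel = ejecta@sourceLabel,
    realizationSeed = ejecta@realizationSeed),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor",
    na = "null")
  invisible(path)
}

#' Read ion ejecta from a JSON container
#' @param path file written by \code{\link{writeEjecta}}.
#' @return an \linkS4class{IonEjecta}.
#' @export
readEjecta <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = TRUE)
  new("IonEjecta", directions = x$directions, speeds = x$speeds,
      charges = as.integer(x$charges), masses = x$masses,
      sourceLabel = x$sourceLabel,
      realizationSeed = if (length(x$realizationSeed) &&
                            !is.na(x$realizationSeed))
        as.integer(x$realizationSeed) else NA_integer_)
}

#' Serialize a CutoffReport to a plain list (for JSON output)
#' @param report a \linkS4class{CutoffReport}.
#' @return named list.
#' @export
reportAsList <- function(report) {
  list(x_cutoff = report@xCutoff,
       mean_angle_under = report@meanAngleUnder,
       n_pairs_under = report@nPairsUnder,
       n_pairs_total = report@nPairsTotal,
       efficiency = report@efficiency,
       label = report@sourceLabel,
       valid = report@valid)
}

#' Write cutoff reports as JSON
#' @param reports a \linkS4class{CutoffReport} or list of them.
#' @param path output file.
#' @export
writeReports <- function(reports, path) {
  if (is(reports, "CutoffReport")) reports <- list(reports)
  jsonlite::write_json(lapply(reports, reportAsList), path,
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}
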