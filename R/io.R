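#' @include strain-synth.R
NULL

#' Write / read strain-trace containers (HDF5)
#'
#' The on-disk container for strain traces: dataset \code{/strain}
#' (frames x sites) with \code{unit}, \code{frame_rate_hz} and
#' \code{start_ms} attributes, the per-site table under \code{/sites}, and
#' the reference ECG under \code{/ecg}. Times are always ms, lengths mm,
#' strain dimensionless; a container without the unit and rate attributes
#' is rejected rather than silently assumed.
#'
#' @param movie a \linkS4class{StrainMovie}.
#' @param path file path (.h5).
#' @return \code{writeStrainHDF5} returns \code{path} invisibly;
#'   \code{readStrainHDF5} returns the \linkS4class{StrainMovie} (without
#'   the mask, which is not serialized).
#' @export
writeStrainHDF5 <- function(movie, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(movie@frames, path, "strain")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "strain")
  rhdf5::h5writeAttribute("dimensionless", did, "unit")
  rhdf5::h5writeAttribute(movie@frameRate, did, "frame_rate_hz")
  rhdf5::h5writeAttribute(movie@startMs, did, "start_ms")
  rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  rhdf5::h5createGroup(path, "sites")
  for (cn in names(movie@sites))
    rhdf5::h5write(movie@sites[[cn]], path, paste0("sites/", cn))
  rhdf5::h5createGroup(path, "ecg")
  rhdf5::h5write(movie@ecg@samples, path, "ecg/samples")
  rhdf5::h5write(c(movie@ecg@rate, movie@ecg@qrsOnset,
    movie@ecg@pacingSpike), path, "ecg/meta")
  rhdf5::h5write(movie@ecg@beatType, path, "ecg/beat_type")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname writeStrainHDF5
#' @export
readStrainHDF5 <- function(path) {
  if (!file.exists(path)) stop("no such container: ", path)
  at <- rhdf5::h5readAttributes(path, "strain")
  for (a in c("unit", "frame_rate_hz", "start_ms"))
    if (is.null(at[[a]]))
      stop("container schema error: attribute '", a, "' absent on /strain")
  frames <- rhdf5::h5read(path, "strain")
  cols <- rhdf5::h5ls(path)
  cols <- cols$name[cols$group == "/sites"]
  sites <- as.data.frame(lapply(stats::setNames(cols, cols), function(cn)
    as.vector(rhdf5::h5read(path, paste0("sites/", cn)))),
    stringsAsFactors = FALSE)
  std <- c("pixel", "row", "col", "x", "y", "segment", "wallDepth", "trueAt")
  sites <- sites[, intersect(std, names(sites)), drop = FALSE]
  meta <- rhdf5::h5read(path, "ecg/meta")
  ecg <- new("ECGTrace", samples = as.numeric(rhdf5::h5read(path,
      "ecg/samples")), rate = meta[1], qrsOnset = meta[2],
    pacingSpike = meta[3],
    beatType = as.character(rhdf5::h5read(path, "ecg/beat_type")))
  rhdf5::h5closeAll()
  new("StrainMovie", frames = frames, frameRate = as.numeric(at$frame_rate_hz),
    startMs = as.numeric(at$start_ms), sites = sites, mask = NULL, ecg = ecg)
}

#' Read a CSV table against a declared schema
#'
#' @param path CSV path (header row required).
#' @param required character vector of required column names.
#' @return data.frame; a missing column raises an error naming it.
#' @export
readTableChecked <- function(path, required) {
  if (!file.exists(path)) stop("no such table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("table schema error in ", basename(path), ": missing column(s) ",
      paste(miss, collapse = ", "))
  df
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path file ending in .yaml/.yml or .json, or a list passed through.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  if (is.list(path)) return(path)
  if (!file.exists(path)) stop("no such config: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path,
    simplifyVector = TRUE)
  else stop("config must be YAML or JSON")
}
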