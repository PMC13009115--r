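#' @include AllClasses.R
NULL

setMethod("show", "ViewGeometry", function(object) {
  cat("ViewGeometry '", object@viewName, "': ", object@nLines, " lines / ",
    object@sectorAngle, " deg, depth ", object@depthMax, " mm, ",
    object@frameRate, " fps\n", sep = "")
})

setMethod("show", "MyocardialMask", function(object) {
  cat("MyocardialMask ", nrow(object@mask), "x", ncol(object@mask),
    " @ ", object@spacing, " mm; ", sum(object@mask), " mask pixels, ",
    length(object@segmentLabels), " segment(s)\n", sep = "")
})

setMethod("show", "ActivationField", function(object) {
  a <- object@at[object@mask@mask]
  cat("ActivationField: AT range [", round(min(a, na.rm = TRUE), 2), ", ",
    round(max(a, na.rm = TRUE), 2), "] ms; source ", object@source@segment,
    " (", object@source@layer, ")\n", sep = "")
})

setMethod("show", "StrainMovie", function(object) {
  cat("StrainMovie: ", nrow(object@frames), " frames x ", ncol(object@frames),
    " sites @ ", object@frameRate, " fps (", object@startMs, " ms start)\n",
    sep = "")
})

setMethod("show", "UnipolarEGM", function(object) {
  cat("UnipolarEGM ", object@nodeId, ": ", length(object@samples),
    " samples @ ", object@rate, " Hz",
    if (object@filtered) " (100 Hz low-passed)" else " (unfiltered)",
    "\n", sep = "")
})

setMethod("show", "ECGIMap", function(object) {
  cat("ECGIMap: ", nrow(object@nodes), " epicardial nodes over ",
    length(unique(object@nodes$segment)), " segments\n", sep = "")
})

setMethod("show", "IsochroneMap", function(object) {
  a <- object@at[object@mask@mask]
  cat("IsochroneMap (", object@method, "): AT range [",
    round(min(a), 2), ", ", round(max(a), 2), "] ms; ",
    sum(object@extrapolated, na.rm = TRUE), " extrapolated px\n", sep = "")
})

setMethod("show", "SoOEstimate", function(object) {
  cat("SoOEstimate: segment ", object@segment, ", layer ", object@layer,
    ", earliest ", round(object@earliestTime, 2), " ms",
    if (object@diffuse) " [diffuse]" else "", " (view ", object@view, ")\n",
    sep = "")
})

setMethod("show", "SegmentBullseye", function(object) {
  v <- object@values
  cat("SegmentBullseye [", object@modality, "]: ", sum(!is.na(v)),
    "/24 segments covered; mean ", round(mean(v, na.rm = TRUE), 1),
    " ms\n", sep = "")
})

setMethod("show", "EMDModel", function(object) {
  cat("EMDModel (", object@subgroup, "): ", object@globalMean, " +/- ",
    object@globalSd, " ms, ", object@drawLevel, "-level draws\n", sep = "")
})

setMethod("show", "RFFrames", function(object) {
  d <- dim(object@data)
  cat("RFFrames: ", d[1], " frames x ", d[2], " lines x ", d[3],
    " samples @ fs ", object@fs / 1e6, " MHz\n", sep = "")
})
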