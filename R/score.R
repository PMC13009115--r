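#' @include segments.R
NULL

#' Score localization calls against the gold standard
#'
#' Turns per-map EWI and ECGI site-of-origin calls plus the per-map gold
#' standard (contact map or pacing site) into exact-match booleans: correct
#' anatomical segment per modality and, for EWI, correct transmural layer
#' (a diffuse EWI call counts as axially incorrect). Maps without an EWI
#' call (e.g. no ectopy during the scan) carry NA for the EWI booleans.
#'
#' @param estimates data.frame with columns map, ewiSegment, ewiLayer,
#'   ewiDiffuse (logical), ecgiSegment; EWI columns may be NA.
#' @param truth data.frame with columns map, segment, layer.
#' @param model segment model; truth segments must belong to it.
#' @return boolean table (one row per map): map, layer,
#'   ewiCorrect, ecgiCorrect, ewiAxialCorrect.
#' @seealso \code{\link{aggregateLocalization}}
#' @export
scoreLocalization <- function(estimates, truth, model = buildSegmentModel()) {
  stopifnot(all(c("map", "segment", "layer") %in% names(truth)))
  bad <- setdiff(truth$segment, model$segment)
  if (length(bad))
    stop("truth segment(s) not in the model: ", paste(bad, collapse = ", "))
  i <- match(truth$map, estimates$map)
  if (anyNA(i)) stop("estimate missing for map(s): ",
    paste(truth$map[is.na(i)], collapse = ", "))
  e <- estimates[i, ]
  ewiCorrect <- ifelse(is.na(e$ewiSegment), NA, e$ewiSegment == truth$segment)
  ecgiCorrect <- e$ecgiSegment == truth$segment
  ewiAxial <- ifelse(is.na(e$ewiSegment), NA,
    !e$ewiDiffuse & !is.na(e$ewiLayer) & e$ewiLayer == truth$layer)
  data.frame(map = truth$map, layer = truth$layer,
    ewiCorrect = ewiCorrect, ecgiCorrect = ecgiCorrect,
    ewiAxialCorrect = ewiAxial, stringsAsFactors = FALSE)
}

binomCI <- function(k, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(k, n)$conf.int) * 100
}

#' Aggregate localization booleans into accuracy proportions
#'
#' Computes, on the percent scale with exact (Clopper-Pearson) binomial 95%
#' confidence intervals: segmental accuracy per modality (NA maps excluded
#' from that modality's denominator), EWI axial accuracy overall and per
#' true layer, the proportion of maps on which both modalities agreed on
#' the correct segment, and the proportion on which both modalities failed
#' (both present and both wrong); the last two use all maps as denominator.
#'
#' @param scores boolean table from \code{\link{scoreLocalization}} (columns
#'   map, layer, ewiCorrect, ecgiCorrect, ewiAxialCorrect).
#' @return list of proportions (percent), counts and CIs.
#' @export
aggregateLocalization <- function(scores) {
  n <- nrow(scores)
  prop <- function(x) {                       # x logical with NA allowed
    k <- sum(x, na.rm = TRUE); m <- sum(!is.na(x))
    list(pct = 100 * k / m, k = k, n = m, ci = binomCI(k, m))
  }
  bothCorrect <- !is.na(scores$ewiCorrect) & scores$ewiCorrect &
    scores$ecgiCorrect
  bothFailed <- !is.na(scores$ewiCorrect) & !scores$ewiCorrect &
    !scores$ecgiCorrect
  layers <- intersect(c("endo", "mid", "epi"), unique(scores$layer))
  axialByLayer <- lapply(stats::setNames(layers, layers), function(l)
    prop(scores$ewiAxialCorrect[scores$layer == l]))
  list(
    ewiSegment = prop(scores$ewiCorrect),
    ecgiSegment = prop(scores$ecgiCorrect),
    ewiAxial = prop(scores$ewiAxialCorrect),
    agreementCorrect = list(pct = 100 * sum(bothCorrect) / n,
      k = sum(bothCorrect), n = n, ci = binomCI(sum(bothCorrect), n)),
    bothFailed = list(pct = 100 * sum(bothFailed) / n,
      k = sum(bothFailed), n = n, ci = binomCI(sum(bothFailed), n)),
    axialByLayer = axialByLayer,
    nMaps = n)
}
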