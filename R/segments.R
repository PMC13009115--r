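#' @include utils.R
NULL

#' The biventricular 24-segment model
#'
#' Enumerates the 24 segments used for anatomical site-of-origin
#' localization and bullseye comparison: 16 LV segments in the AHA style
#' (6 basal, 6 mid, 4 apical) and 8 RV segments (3 basal, 3 mid, 2 apical).
#' Six segments are septal (basal and mid antero-/inferoseptal, LV apical
#' septal, RV apical septal); septal segments are not covered by ECGI, which
#' reconstructs the epicardial surface only. The segment adjacency graph
#' (rings within a level, links across levels, RV-LV junctions) is attached
#' as the "edges" attribute and drives segment-scale wavefront propagation
#' in cohort phantoms.
#'
#' @return data.frame with columns segment, chamber ("LV"/"RV"), level
#'   ("basal"/"mid"/"apical"), sector, septal (logical), ecgiCovered
#'   (logical); attribute "edges" holds a two-column data.frame of adjacent
#'   segment pairs.
#' @examples
#' model <- buildSegmentModel()
#' nrow(model)            # 24
#' sum(model$septal)      # 6
#' @export
buildSegmentModel <- function() {
  lvSect <- c("anterior", "anteroseptal", "inferoseptal", "inferior",
    "inferolateral", "anterolateral")
  lvApx <- c("anterior", "septal", "inferior", "lateral")
  rvSect <- c("anterior", "lateral", "inferior")
  rvApx <- c("free", "septal")
  seg <- rbind(
    data.frame(chamber = "LV", level = "basal", sector = lvSect),
    data.frame(chamber = "LV", level = "mid", sector = lvSect),
    data.frame(chamber = "LV", level = "apical", sector = lvApx),
    data.frame(chamber = "RV", level = "basal", sector = rvSect),
    data.frame(chamber = "RV", level = "mid", sector = rvSect),
    data.frame(chamber = "RV", level = "apical", sector = rvApx))
  seg$segment <- paste(seg$chamber, seg$level, seg$sector, sep = ".")
  seg$septal <- with(seg,
    (chamber == "LV" & level %in% c("basal", "mid") &
       sector %in% c("anteroseptal", "inferoseptal")) |
    (chamber == "LV" & level == "apical" & sector == "septal") |
    (chamber == "RV" & level == "apical" & sector == "septal"))
  seg$ecgiCovered <- !seg$septal
  seg <- seg[, c("segment", "chamber", "level", "sector", "septal",
    "ecgiCovered")]

  ring <- function(labels, closed = TRUE) {
    n <- length(labels)
    to <- if (closed) c(labels[-1], labels[1]) else labels[-1]
    from <- if (closed) labels else labels[-n]
    data.frame(from = from, to = to)
  }
  lvB <- paste("LV.basal", lvSect, sep = ".")
  lvM <- paste("LV.mid", lvSect, sep = ".")
  lvA <- paste("LV.apical", lvApx, sep = ".")
  rvB <- paste("RV.basal", rvSect, sep = ".")
  rvM <- paste("RV.mid", rvSect, sep = ".")
  midToApex <- c(anterior = "LV.apical.anterior",
    anteroseptal = "LV.apical.septal", inferoseptal = "LV.apical.septal",
    inferior = "LV.apical.inferior", inferolateral = "LV.apical.lateral",
    anterolateral = "LV.apical.lateral")
  edges <- rbind(
    ring(lvB), ring(lvM), ring(lvA),
    data.frame(from = lvB, to = lvM),
    data.frame(from = lvM, to = unname(midToApex[lvSect])),
    ring(rvB, closed = FALSE), ring(rvM, closed = FALSE),
    data.frame(from = rvB, to = rvM),
    data.frame(from = rvM, to = c("RV.apical.free", "RV.apical.free",
      "RV.apical.septal")),
    data.frame(from = "RV.apical.free", to = "RV.apical.septal"),
    # RV free wall abuts the LV septum at the insertion points
    data.frame(from = c("RV.basal.anterior", "RV.basal.inferior",
        "RV.mid.anterior", "RV.mid.inferior", "RV.apical.septal"),
      to = c("LV.basal.anteroseptal", "LV.basal.inferoseptal",
        "LV.mid.anteroseptal", "LV.mid.inferoseptal", "LV.apical.septal")))
  attr(seg, "edges") <- edges
  seg
}

#' Segment hop distances on the adjacency graph
#'
#' Shortest-path hop counts from one segment to all segments on the model's
#' adjacency graph; the segment-scale analogue of geodesic wavefront
#' propagation.
#'
#' @param model segment model from \code{\link{buildSegmentModel}}.
#' @param from source segment label.
#' @return named numeric vector of hop counts.
#' @export
segmentDistances <- function(model, from) {
  if (!from %in% model$segment) stop("unknown segment '", from, "'")
  e <- attr(model, "edges")
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
    vertices = model$segment)
  d <- igraph::distances(g, v = from)[1, ]
  d[model$segment]
}

#' Standard view-to-segment allocation
#'
#' Artifact-defined partition of the 24 segments over the six standard
#' views (4 segments per view, jointly exhaustive and mutually exclusive).
#'
#' @return named list mapping view name to 4 segment labels.
#' @export
viewSegmentMap <- function() {
  list(
    "4ch" = c("LV.basal.inferoseptal", "LV.mid.inferoseptal",
      "LV.basal.anterolateral", "LV.mid.anterolateral"),
    "2ch" = c("LV.basal.anterior", "LV.mid.anterior",
      "LV.basal.inferior", "LV.mid.inferior"),
    "3ch" = c("LV.basal.anteroseptal", "LV.mid.anteroseptal",
      "LV.basal.inferolateral", "LV.mid.inferolateral"),
    "5ch" = c("LV.apical.anterior", "LV.apical.septal",
      "LV.apical.inferior", "LV.apical.lateral"),
    "RVIT" = c("RV.basal.anterior", "RV.basal.lateral",
      "RV.basal.inferior", "RV.mid.inferior"),
    "3.5ch" = c("RV.mid.anterior", "RV.mid.lateral",
      "RV.apical.free", "RV.apical.septal"))
}
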