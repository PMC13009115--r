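#' @include bullseye.R
NULL

#' Per-segment electromechanical delay between EWI and ECGI
#'
#' Segmental activation-time difference delta = EWI_AT - ECGI_AT over the
#' segments both modalities cover. Because the zero crossing marks
#' mechanical onset and the maximum negative dV/dt marks electrical
#' depolarization, a positive delta means ECGI precedes EWI.
#'
#' @param ewi EWI \linkS4class{SegmentBullseye}.
#' @param ecgi ECGI \linkS4class{SegmentBullseye} of the same subject.
#' @param model segment model (adds level/chamber columns).
#' @return data.frame with columns subject, segment, level, chamber, delta
#'   (ms); attributes "meanDelta", "sdDelta", "fracPositive" carry the
#'   global summary.
#' @export
computeEMD <- function(ewi, ecgi, model = buildSegmentModel()) {
  if (!identical(names(ewi@values), names(ecgi@values)))
    stop("bullseyes use different segment models")
  if (!identical(ewi@subject, ecgi@subject) &&
      !(is.na(ewi@subject) || is.na(ecgi@subject)))
    warning("bullseyes come from different subjects: ", ewi@subject,
      " vs ", ecgi@subject)
  joint <- !is.na(ewi@values) & !is.na(ecgi@values)
  if (!any(joint)) stop("no jointly covered segments")
  seg <- names(ewi@values)[joint]
  delta <- unname(ewi@values[joint] - ecgi@values[joint])
  i <- match(seg, model$segment)
  out <- data.frame(subject = ewi@subject, segment = seg,
    level = model$level[i], chamber = model$chamber[i], delta = delta,
    stringsAsFactors = FALSE)
  attr(out, "meanDelta") <- mean(delta)
  attr(out, "sdDelta") <- stats::sd(delta)
  attr(out, "fracPositive") <- mean(delta > 0)
  out
}

cellStat <- function(d) {
  if (!length(d)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
  c(mean = mean(d), sd = stats::sd(d), n = length(d))
}

#' Subgroup analysis of segmental electromechanical delays
#'
#' Summarizes per-segment EWI-ECGI activation-time differences in the
#' standard report shape: mean +/- SD per cell of {Global, Basal, Mid,
#' Apical, RV, LV} x {All, LGE+ve, LVSD&LGE-ve, normal}, a one-way ANOVA
#' across structural subgroups per row, Bonferroni-corrected pairwise
#' t-tests between subgroups on the global deltas, and a basal/mid/apical
#' level ANOVA (plus RV-vs-LV t-test) within each column. Segment-level
#' deltas are pooled across subjects within each cell.
#'
#' @param emd data.frame as stacked \code{\link{computeEMD}} rows with an
#'   added \code{subgroup} column.
#' @return list with \code{cells} (data.frame of mean/sd/n per cell),
#'   \code{anovaP} (per row), \code{pairwiseP} (matrix from global deltas),
#'   \code{levelP} and \code{chamberP} (per column).
#' @export
subgroupAnalysis <- function(emd) {
  stopifnot(all(c("segment", "level", "chamber", "delta", "subgroup")
    %in% names(emd)))
  allGroups <- c("LGE+ve", "LVSD&LGE-ve", "normal")
  present <- intersect(allGroups, unique(emd$subgroup))
  dropped <- setdiff(unique(emd$subgroup), allGroups)
  if (length(dropped))
    warning("unknown subgroup(s) dropped: ", paste(dropped, collapse = ", "))
  emd <- emd[emd$subgroup %in% present, , drop = FALSE]

  rows <- list(Global = rep(TRUE, nrow(emd)),
    Basal = emd$level == "basal", Mid = emd$level == "mid",
    Apical = emd$level == "apical",
    RV = emd$chamber == "RV", LV = emd$chamber == "LV")
  cols <- c(list(All = rep(TRUE, nrow(emd))),
    stats::setNames(lapply(present, function(g) emd$subgroup == g), present))

  cells <- do.call(rbind, lapply(names(rows), function(r)
    do.call(rbind, lapply(names(cols), function(cl) {
      s <- cellStat(emd$delta[rows[[r]] & cols[[cl]]])
      data.frame(row = r, column = cl, mean = s[["mean"]], sd = s[["sd"]],
        n = s[["n"]])
    }))))

  anovaOk <- length(present) >= 2 &&
    all(table(emd$subgroup) >= 2)
  anovaP <- vapply(names(rows), function(r) {
    d <- emd[rows[[r]], ]
    if (!anovaOk || length(unique(d$subgroup)) < 2) return(NA_real_)
    summary(stats::aov(delta ~ factor(subgroup), data = d))[[1]][["Pr(>F)"]][1]
  }, numeric(1))

  pairwiseP <- if (anovaOk)
    stats::pairwise.t.test(emd$delta, emd$subgroup,
      p.adjust.method = "bonferroni")$p.value
  else NULL

  levelP <- vapply(names(cols), function(cl) {
    d <- emd[cols[[cl]], ]
    if (length(unique(d$level)) < 2) return(NA_real_)
    summary(stats::aov(delta ~ factor(level), data = d))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  chamberP <- vapply(names(cols), function(cl) {
    d <- emd[cols[[cl]], ]
    if (length(unique(d$chamber)) < 2) return(NA_real_)
    stats::t.test(delta ~ chamber, data = d)$p.value
  }, numeric(1))

  list(cells = cells, anovaP = anovaP, pairwiseP = pairwiseP,
    levelP = levelP, chamberP = chamberP)
}
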