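# FPKM conversion, reference-median normalization, absence calling, and
# expression percentiles.

#' FPKM of a protein panel from its recruited read count
#'
#' The nucleotide reference length of a panel is three times its mean
#' amino-acid length; FPKM is then
#' `n_reads / (L / 1000) / (total_reads / 1e6)`.
#' For the raw-read screening stage `totalReads` is the number of read
#' records in the library (the screen has no "mapped" universe); for
#' assembled-feature expression use the mapped-read total instead (see
#' [expressionPercentile()]).
#'
#' @param nReads reads recruited to the panel (best hits).
#' @param meanAALength panel mean amino-acid length, residues.
#' @param totalReads denominator reads (> 0).
#' @return FPKM (vectorized over `nReads`).
#' @examples
#' computeFPKM(10, 500, 1e6)  # 6.6667
#' @export
computeFPKM <- function(nReads, meanAALength, totalReads) {
  if (any(totalReads <= 0)) stop("empty library: totalReads must be > 0")
  if (any(meanAALength <= 0)) stop("meanAALength must be > 0")
  refKb <- 3 * meanAALength / 1000
  nReads / refKb / (totalReads / 1e6)
}

#' Per-panel read counts and FPKM from best-filtered hits
#'
#' Counts, for every panel of the set, the number of distinct reads whose
#' best hit lies in that panel, and converts the counts to FPKM using each
#' panel's own mean amino-acid length. Calls are left unset; see
#' [relativeCoverage()] and [callAbsence()] for the downstream steps.
#'
#' @param bestHits best-filtered hits ([filterBestHits()]).
#' @param ps the [PanelSet-class] that was screened.
#' @param lib the screened [ReadLibrary-class], or a positive count of total
#'   reads to use as the FPKM denominator.
#' @return data.frame with one row per panel: `library_id`, `panel_id`,
#'   `role`, `pathway_label`, `mean_aa_length`, `n_reads`, `fpkm`.
#' @export
screenPanels <- function(bestHits, ps, lib) {
  if (is(lib, "ReadLibrary")) {
    libId <- libraryId(lib); total <- totalReads(lib)
  } else {
    libId <- "library1"; total <- as.numeric(lib)
  }
  if (anyDuplicated(bestHits$read_id))
    stop("hits are not best-filtered: multiple hits per read")
  pls <- panels(ps)
  counts <- table(factor(bestHits$panel_id, levels = names(pls)))
  lens <- vapply(pls, meanAALength, numeric(1))
  data.frame(
    library_id = libId,
    panel_id = names(pls),
    role = vapply(pls, panelRole, character(1)),
    pathway_label = vapply(pls, pathwayLabel, character(1)),
    mean_aa_length = lens,
    n_reads = as.integer(counts),
    fpkm = computeFPKM(as.integer(counts), lens, total),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Coverage of a target panel relative to the reference median
#'
#' @param targetFpkm FPKM of the target panel (vectorized).
#' @param referenceFpkm numeric vector of reference-panel FPKM values; their
#'   median (mean of the middle two for an even count) is the baseline.
#' @return `targetFpkm / median(referenceFpkm)`.
#' @examples
#' relativeCoverage(1, c(1, 2, 3, 4))  # 0.4
#' @export
relativeCoverage <- function(targetFpkm, referenceFpkm) {
  if (length(referenceFpkm) == 0L) stop("no reference panels")
  m <- stats::median(referenceFpkm)
  if (m == 0)
    stop("reference set not detected (median reference FPKM is 0); ",
         "the library is unusable for relative coverage")
  targetFpkm / m
}

#' Add relative coverage to a panel screening report
#'
#' @param reports data.frame from [screenPanels()] covering one library.
#' @return `reports` with a `relative_coverage` column (FPKM over the median
#'   FPKM of the `role == "reference"` panels).
#' @export
addRelativeCoverage <- function(reports) {
  refs <- reports$fpkm[reports$role == "reference"]
  reports$relative_coverage <- relativeCoverage(reports$fpkm, refs)
  reports
}

#' Call absence or presence of target panels
#'
#' Encodes the two-step absence argument: a target whose coverage is at
#' least `foldThreshold`-fold below the reference median is called absent
#' outright; otherwise, if its candidate reads were re-mapped onto the
#' binned assembly ([attributeCandidateReads()]) and the majority land
#' outside the focal bin, it is still called absent *from the focal
#' genome*; with attribution evidence mostly inside the focal bin it is
#' called present; without attribution evidence it stays ambiguous.
#' Reference panels are given the call `"reference"`.
#'
#' @param reports data.frame from [addRelativeCoverage()].
#' @param foldThreshold fold difference below the reference median taken as
#'   outright absence (default 50).
#' @param attribution optional data.frame from [attributeCandidateReads()]
#'   (one row per panel) supplying `attributed_outside_fraction`.
#' @return `reports` with columns `attributed_outside_fraction` and `call`.
#' @export
callAbsence <- function(reports, foldThreshold = 50, attribution = NULL) {
  frac <- rep(NA_real_, nrow(reports))
  if (!is.null(attribution) && nrow(attribution)) {
    i <- match(reports$panel_id, attribution$panel_id)
    frac <- attribution$attributed_outside_fraction[i]
  }
  hasAttr <- if (!is.null(attribution))
    reports$panel_id %in% attribution$panel_id else rep(FALSE, nrow(reports))
  call <- ifelse(reports$relative_coverage <= 1 / foldThreshold, "absent",
          ifelse(hasAttr & !is.na(frac) & frac > 0.5, "absent",
          ifelse(hasAttr, "present", "ambiguous")))
  call[reports$role == "reference"] <- "reference"
  reports$attributed_outside_fraction <- frac
  reports$call <- call
  reports
}

#' Expression FPKM and percentile ranks of assembled features
#'
#' Computes feature FPKM from fragments mapped per feature (reference length
#' = the feature's own length in bp; denominator = reads mapped, per
#' million) and ranks features within the library by mid-rank percent rank:
#' `100 * (n_lower + ties_excluding_self / 2) / (n - 1)`. The single highest
#' expressed feature sits at percentile 100, the lowest at 0, and fully tied
#' features all at 50.
#'
#' @param features data.frame with columns `feature_id`, `mapped_fragments`,
#'   `feature_length_bp`; at least two features.
#' @param totalMapped total mapped fragments of the library; defaults to the
#'   sum over features.
#' @return `features` with `fpkm` and `percentile` columns added.
#' @export
expressionPercentile <- function(features,
                                 totalMapped = sum(features$mapped_fragments)) {
  n <- nrow(features)
  if (n < 2L) stop("need at least two features to rank")
  if (totalMapped <= 0) stop("empty library: totalMapped must be > 0")
  features$fpkm <- features$mapped_fragments /
    (features$feature_length_bp / 1000) / (totalMapped / 1e6)
  f <- features$fpkm
  nLower <- vapply(f, function(x) sum(f < x), numeric(1))
  nTies <- vapply(f, function(x) sum(f == x) - 1, numeric(1))
  features$percentile <- 100 * (nLower + nTies / 2) / (n - 1)
  features
}
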