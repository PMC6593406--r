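# End-to-end screening of one read library against a panel set.

#' Screen a read library for gene absence
#'
#' Runs the full read-level verification for one library: translated
#' recruitment of raw reads to the panels ([searchReads()]), best-hit
#' filtering at the printed thresholds ([filterBestHits()]), per-panel
#' FPKM ([screenPanels()]), normalization against the reference-panel
#' median ([addRelativeCoverage()]), and the absence call
#' ([callAbsence()]). When a binned assembly is supplied, the candidate
#' reads of every target panel that is not at least `foldThreshold`-fold
#' below the reference median are re-mapped onto it
#' ([mapReadsToContigs()]) and attributed to bins
#' ([attributeCandidateReads()]), so that coverage explained by
#' contaminant bins still yields an absence call for the focal genome.
#'
#' @param lib a [ReadLibrary-class].
#' @param ps a [PanelSet-class].
#' @param assembly optional [BinnedAssembly-class] for read attribution.
#' @param minScore engine reporting floor ([searchReads()]).
#' @param evalueMax,minIdentity,minSubjectCov best-hit thresholds
#'   ([filterBestHits()]).
#' @param foldThreshold outright-absence fold threshold ([callAbsence()]).
#' @param mapMinIdentity,mapMinReadCov re-mapping thresholds
#'   ([mapReadsToContigs()]).
#' @param hits optional precomputed hit table (e.g. from
#'   [parseTabularHits()]) used instead of running the built-in engine.
#' @return list with `reports` (per-panel data.frame with `n_reads`,
#'   `fpkm`, `relative_coverage`, `attributed_outside_fraction`, `call`),
#'   `bestHits`, and `attribution` (per-panel rows, possibly empty).
#' @examples
#' \donttest{
#' sc <- simulateScreenScenario("contaminant", seed = 7, nReads = 2e4)
#' res <- screenLibrary(sc$library, sc$panels, assembly = sc$assembly)
#' subset(res$reports, role == "target", c(panel_id, n_reads, fpkm,
#'                                         relative_coverage, call))
#' }
#' @export
screenLibrary <- function(lib, ps, assembly = NULL, minScore = 110,
                          evalueMax = 1e-5, minIdentity = 30,
                          minSubjectCov = 0, foldThreshold = 50,
                          mapMinIdentity = 0.97, mapMinReadCov = 0.9,
                          hits = NULL) {
  if (is.null(hits)) hits <- searchReads(lib, ps, minScore = minScore)
  best <- filterBestHits(hits, evalueMax = evalueMax,
                         minIdentity = minIdentity,
                         minSubjectCov = minSubjectCov)
  reports <- addRelativeCoverage(screenPanels(best, ps, lib))
  attribution <- data.frame()
  if (!is.null(assembly)) {
    roles <- reports$role
    needs <- reports$panel_id[roles == "target" &
                                reports$relative_coverage > 1 / foldThreshold]
    att <- lapply(needs, function(pid) {
      cand <- best$read_id[best$panel_id == pid]
      mapping <- mapReadsToContigs(readSequences(lib)[cand], assembly,
                                   minIdentity = mapMinIdentity,
                                   minReadCov = mapMinReadCov)
      attributeCandidateReads(mapping, assembly, pid)
    })
    if (length(att)) attribution <- do.call(rbind, att)
  }
  reports <- callAbsence(reports, foldThreshold = foldThreshold,
                         attribution = if (nrow(attribution)) attribution)
  list(reports = reports, bestHits = best, attribution = attribution)
}

#' Write a panel screening report to TSV
#'
#' @param reports the `reports` element of [screenLibrary()]'s result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScreenReport <- function(reports, path) {
  utils::write.table(reports, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot relative coverage of target panels
#'
#' Dot plot of per-panel coverage relative to the reference median (log
#' scale) with the outright-absence threshold drawn as a dashed line.
#' Requires ggplot2.
#'
#' @param reports per-panel report(s) from one or more libraries (row-bound).
#' @param foldThreshold threshold to draw (default 50).
#' @return a ggplot object.
#' @export
plotRelativeCoverage <- function(reports, foldThreshold = 50) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotRelativeCoverage needs the ggplot2 package")
  df <- reports[reports$role == "target", , drop = FALSE]
  # zero coverage cannot sit on a log scale; pin it just below the floor
  floorVal <- 1 / (10 * foldThreshold)
  df$rc <- pmax(df$relative_coverage, floorVal)
  ggplot2::ggplot(df, ggplot2::aes(x = panel_id, y = rc, shape = call)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 1 / foldThreshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "coverage / reference median",
                  shape = "call") +
    ggplot2::theme_minimal()
}
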