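# Accessors and show methods for the S4 containers.

#' @describeIn ProteinPanel-class panel id.
#' @param x object.
#' @export
setMethod("panelId", "ProteinPanel", function(x) x@panelId)

#' @describeIn ProteinPanel-class role (`"target"` or `"reference"`).
#' @export
setMethod("panelRole", "ProteinPanel", function(x) x@role)

#' @describeIn ProteinPanel-class pathway annotation.
#' @export
setMethod("pathwayLabel", "ProteinPanel", function(x) x@pathwayLabel)

#' @describeIn ProteinPanel-class per-member EC number lists.
#' @export
setMethod("ecNumbers", "ProteinPanel", function(x) {
  stats::setNames(x@ecNumbers, names(x@sequences))
})

#' @describeIn ProteinPanel-class member sequences as an `AAStringSet`.
#' @export
setMethod("panelSequences", "ProteinPanel", function(x) x@sequences)

#' @describeIn ProteinPanel-class number of members.
#' @export
setMethod("length", "ProteinPanel", function(x) length(x@sequences))

setMethod("meanAALength", "ProteinPanel", function(x) {
  if (length(x@sequences) == 0L) stop("empty panel")
  mean(Biostrings::width(x@sequences))
})

setMethod("show", "ProteinPanel", function(object) {
  cat("ProteinPanel '", object@panelId, "' (", object@role, ")\n", sep = "")
  if (nzchar(object@pathwayLabel))
    cat("  pathway: ", object@pathwayLabel, "\n", sep = "")
  ecs <- unique(unlist(object@ecNumbers))
  cat("  ", length(object@sequences), " member(s), mean length ",
      round(meanAALength(object), 1), " aa",
      if (length(ecs)) paste0("; EC ", paste(ecs, collapse = ", ")) else "",
      "\n", sep = "")
})

#' @describeIn PanelSet-class list of member panels.
#' @param x object.
#' @export
setMethod("panels", "PanelSet", function(x) {
  stats::setNames(x@panels, vapply(x@panels, panelId, character(1)))
})

#' @describeIn PanelSet-class number of panels.
#' @export
setMethod("length", "PanelSet", function(x) length(x@panels))

#' @describeIn PanelSet-class extract one panel by position or id.
#' @param i index or panel id.
#' @param j,... unused.
#' @export
setMethod("[[", "PanelSet", function(x, i, j, ...) panels(x)[[i]])

setMethod("show", "PanelSet", function(object) {
  roles <- vapply(object@panels, panelRole, character(1))
  cat("PanelSet with ", length(object@panels), " panel(s): ",
      sum(roles == "target"), " target, ",
      sum(roles == "reference"), " reference\n", sep = "")
  for (p in object@panels)
    cat("  ", panelId(p), " [", panelRole(p), "] ",
        length(p), " member(s)\n", sep = "")
})

#' @describeIn ReadLibrary-class number of read records.
#' @param x object.
#' @export
setMethod("totalReads", "ReadLibrary", function(x) length(x@reads))

#' @describeIn ReadLibrary-class library id.
#' @export
setMethod("libraryId", "ReadLibrary", function(x) x@libraryId)

#' @describeIn ReadLibrary-class reads as a `DNAStringSet`.
#' @export
setMethod("readSequences", "ReadLibrary", function(x) x@reads)

#' @describeIn ReadLibrary-class per-read truth table (simulated libraries).
#' @export
setMethod("readTruth", "ReadLibrary", function(x) x@truth)

setMethod("show", "ReadLibrary", function(object) {
  cat("ReadLibrary '", object@libraryId, "': ", length(object@reads),
      " ", object@layout, "-layout read record(s)", sep = "")
  if (length(object@reads))
    cat(", widths ", min(Biostrings::width(object@reads)), "-",
        max(Biostrings::width(object@reads)), " nt", sep = "")
  cat(if (nrow(object@truth)) ", with truth table" else "", "\n", sep = "")
})

#' @describeIn BinnedAssembly-class contigs (GC fraction and optional mean
#'   coverage in `mcols`).
#' @param x object.
#' @export
setMethod("contigs", "BinnedAssembly", function(x) x@contigs)

#' @describeIn BinnedAssembly-class contig-to-bin map.
#' @export
setMethod("binOf", "BinnedAssembly", function(x) x@binOf)

#' @describeIn BinnedAssembly-class the focal bin id.
#' @export
setMethod("focalBin", "BinnedAssembly", function(x) x@focalBin)

setMethod("show", "BinnedAssembly", function(object) {
  bins <- table(object@binOf)
  cat("BinnedAssembly: ", length(object@contigs), " contig(s) in ",
      length(bins), " bin(s); focal bin '", object@focalBin, "' (",
      bins[[object@focalBin]], " contig(s))\n", sep = "")
})

#' @describeIn SyntheticCommunity-class genome sequences.
#' @param x object.
#' @export
setMethod("genomes", "SyntheticCommunity", function(x) x@genomes)

#' @describeIn SyntheticCommunity-class relative abundances (sum to 1).
#' @export
setMethod("abundances", "SyntheticCommunity", function(x) x@abundance)

#' @describeIn SyntheticCommunity-class implanted-gene truth table.
#' @export
setMethod("implants", "SyntheticCommunity", function(x) x@implants)

setMethod("show", "SyntheticCommunity", function(object) {
  cat("SyntheticCommunity: ", length(object@genomes), " genome(s), ",
      nrow(object@implants), " implanted gene copy(ies), seed ",
      object@seed, "\n", sep = "")
  for (g in names(object@genomes))
    cat("  ", g, ": ", Biostrings::width(object@genomes)[[
        match(g, names(object@genomes))]], " bp, abundance ",
        signif(object@abundance[[g]], 3), "\n", sep = "")
})

#' @describeIn FamilyCountMatrix-class total counts (families x genomes).
#' @param x object.
#' @export
setMethod("countsTotal", "FamilyCountMatrix", function(x)
  SummarizedExperiment::assay(x, "total"))

#' @describeIn FamilyCountMatrix-class transmembrane-only counts.
#' @export
setMethod("countsTM", "FamilyCountMatrix", function(x)
  SummarizedExperiment::assay(x, "tm"))

#' @describeIn OrdinationResult-class centered site coordinates.
#' @param x object.
#' @export
setMethod("ordinationScores", "OrdinationResult", function(x) x@points)

#' @describeIn OrdinationResult-class Kruskal stress of the solution.
#' @export
setMethod("ordinationStress", "OrdinationResult", function(x) x@stress)

setMethod("show", "OrdinationResult", function(object) {
  cat("OrdinationResult: ", nrow(object@points), " point(s) in ",
      ncol(object@points), "D (", object@distanceMetric, "), stress = ",
      signif(object@stress, 4), ", ", object@nRestarts,
      " random start(s), seed ", object@seed, "\n", sep = "")
})

#' @describeIn OrthologTable-class cluster membership table.
#' @param x object.
#' @export
setMethod("clusterMembership", "OrthologTable", function(x) x@membership)

#' @describeIn OrthologTable-class genome ids.
#' @export
setMethod("genomes", "OrthologTable", function(x) x@genomes)

#' @describeIn OrthologTable-class per-genome singleton genes.
#' @export
setMethod("singletons", "OrthologTable", function(x) x@singletons)

setMethod("show", "OrthologTable", function(object) {
  cat("OrthologTable: ", length(unique(object@membership$cluster_id)),
      " cluster(s) over ", length(object@genomes), " genome(s), ",
      nrow(object@singletons), " singleton gene(s)\n", sep = "")
})
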