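#' @export
setGeneric("panelId", function(x) standardGeneric("panelId"))
#' @export
setGeneric("panelRole", function(x) standardGeneric("panelRole"))
#' @export
setGeneric("pathwayLabel", function(x) standardGeneric("pathwayLabel"))
#' @export
setGeneric("ecNumbers", function(x) standardGeneric("ecNumbers"))
#' @export
setGeneric("panelSequences", function(x) standardGeneric("panelSequences"))
#' @export
setGeneric("panels", function(x) standardGeneric("panels"))

#' Mean amino-acid length of a panel
#'
#' Arithmetic mean length, in residues, of the panel members. Three times
#' this value is the nucleotide reference length used to turn panel read
#' counts into FPKM (see [computeFPKM()]).
#'
#' @param x a [ProteinPanel-class].
#' @return a positive number (residues).
#' @examples
#' p <- ProteinPanel("demo", "target",
#'                   sequences = Biostrings::AAStringSet(c(a = "MKV", b = "MKVLW")))
#' meanAALength(p) # 4
#' @export
setGeneric("meanAALength", function(x) standardGeneric("meanAALength"))

#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))
#' @export
setGeneric("readTruth", function(x) standardGeneric("readTruth"))

#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @export
setGeneric("binOf", function(x) standardGeneric("binOf"))
#' @export
setGeneric("focalBin", function(x) standardGeneric("focalBin"))

#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @export
setGeneric("implants", function(x) standardGeneric("implants"))

#' @export
setGeneric("countsTotal", function(x) standardGeneric("countsTotal"))
#' @export
setGeneric("countsTM", function(x) standardGeneric("countsTM"))

#' @export
setGeneric("ordinationScores", function(x) standardGeneric("ordinationScores"))
#' @export
setGeneric("ordinationStress", function(x) standardGeneric("ordinationStress"))

#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))
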