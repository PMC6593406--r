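#' Protein panel keyed by EC number or explicit sequence list
#'
#' A `ProteinPanel` bundles the protein sequences used to recruit reads for
#' one enzyme (or one curated group of sequences), together with its role in
#' the screen: `"target"` panels are the genes whose absence is under test
#' (e.g. key enzymes of autotrophic CO2-fixation pathways), `"reference"`
#' panels are genes expected present in every genome of the clade (e.g. TCA
#' cycle enzymes) and define the coverage baseline.
#'
#' Members are selected either by EC number or as an explicit list of
#' additional sequences; a member with an empty EC vector is understood to
#' come from the additional-sequence route.
#'
#' @slot panelId single string, unique within a [PanelSet].
#' @slot role `"target"` or `"reference"`.
#' @slot pathwayLabel free-text pathway annotation (e.g. `"CBB"`, `"rTCA"`).
#' @slot sequences [Biostrings::AAStringSet] of panel members, named by
#'   sequence id; residues are the 20 canonical amino acids plus `X`.
#' @slot ecNumbers list of character vectors, one per member (possibly
#'   empty), parallel to `sequences`.
#'
#' @seealso [readProteinPanel()], [PanelSet-class], [meanAALength()]
#' @export
setClass("ProteinPanel",
  slots = c(
    panelId = "character",
    role = "character",
    pathwayLabel = "character",
    sequences = "AAStringSet",
    ecNumbers = "list"
  )
)

setValidity("ProteinPanel", function(object) {
  msg <- character()
  if (length(object@panelId) != 1L || is.na(object@panelId) ||
      !nzchar(object@panelId))
    msg <- c(msg, "panelId must be a single non-empty string")
  if (length(object@role) != 1L || !object@role %in% c("target", "reference"))
    msg <- c(msg, "role must be 'target' or 'reference'")
  if (length(object@sequences) == 0L)
    msg <- c(msg, "panel has no members")
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all members must be named")
  else if (anyDuplicated(ids))
    msg <- c(msg, paste("duplicate seq_id:",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@ecNumbers) != length(object@sequences))
    msg <- c(msg, "ecNumbers must have one entry per member")
  bad <- Biostrings::letterFrequency(object@sequences, "ACDEFGHIKLMNPQRSTVWYX") !=
    Biostrings::width(object@sequences)
  if (any(bad))
    msg <- c(msg, paste("non-canonical residues in:",
                        paste(ids[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Set of protein panels used in one screen
#'
#' A `PanelSet` is a list of [ProteinPanel-class] objects. A usable set
#' contains at least one reference panel (the expected-present baseline) and
#' no sequence id shared between panels; these invariants are reported, not
#' enforced at construction, so that [validatePanels()] can describe a broken
#' set instead of refusing to build it.
#'
#' @slot panels list of [ProteinPanel-class] objects.
#' @seealso [readPanelSet()], [validatePanels()]
#' @export
setClass("PanelSet", slots = c(panels = "list"))

setValidity("PanelSet", function(object) {
  if (!all(vapply(object@panels, is, logical(1), "ProteinPanel")))
    return("all elements of panels must be ProteinPanel objects")
  TRUE
})

#' A library of raw sequencing reads
#'
#' Thin wrapper around a [Biostrings::DNAStringSet] of unassembled reads,
#' with the library id and layout used downstream (FPKM denominators count
#' read records; in a paired library each mate is one record). Libraries
#' produced by [generateReads()] carry a per-read truth table.
#'
#' @slot libraryId single string.
#' @slot reads [Biostrings::DNAStringSet], named by read id.
#' @slot layout `"single"` or `"paired"`.
#' @slot truth data.frame of per-read provenance (empty for real data):
#'   columns `read_id`, `genome_id`, `start`, `strand`.
#' @seealso [readReadLibrary()], [generateReads()], [totalReads()]
#' @export
setClass("ReadLibrary",
  slots = c(
    libraryId = "character",
    reads = "DNAStringSet",
    layout = "character",
    truth = "data.frame"
  ),
  prototype = list(layout = "single", truth = data.frame())
)

setValidity("ReadLibrary", function(object) {
  msg <- character()
  if (length(object@libraryId) != 1L || !nzchar(object@libraryId))
    msg <- c(msg, "libraryId must be a single non-empty string")
  if (!object@layout %in% c("single", "paired"))
    msg <- c(msg, "layout must be 'single' or 'paired'")
  if (length(object@reads) &&
      (is.null(names(object@reads)) || anyDuplicated(names(object@reads))))
    msg <- c(msg, "reads must have unique names")
  if (length(msg)) msg else TRUE
})

#' Binned metagenome assembly
#'
#' Contigs of a metagenome assembly together with their genome-bin
#' assignment. Exactly one bin is designated focal (the symbiont of
#' interest); contigs not assigned to any bin carry bin id `"unbinned"`.
#' Per-contig GC fraction is computed at construction and kept in
#' `mcols(contigs(x))` alongside an optional mean coverage, the two axes of
#' the usual coverage-GC bin plot.
#'
#' @slot contigs [Biostrings::DNAStringSet], named by contig id.
#' @slot binOf named character vector mapping contig id to bin id.
#' @slot focalBin single string, a bin id present in `binOf`.
#' @seealso [readBinnedAssembly()], [mapReadsToContigs()],
#'   [attributeCandidateReads()]
#' @export
setClass("BinnedAssembly",
  slots = c(
    contigs = "DNAStringSet",
    binOf = "character",
    focalBin = "character"
  )
)

setValidity("BinnedAssembly", function(object) {
  msg <- character()
  ids <- names(object@contigs)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "contigs must have unique names")
  if (!setequal(names(object@binOf), ids))
    msg <- c(msg, "binOf must be named by exactly the contig ids")
  if (length(object@focalBin) != 1L ||
      !object@focalBin %in% object@binOf)
    msg <- c(msg, "focalBin must name exactly one bin present in binOf")
  if (length(msg)) msg else TRUE
})

#' Synthetic metagenome community with ground truth
#'
#' Genomes of a simulated community (one focal symbiont plus low-abundance
#' contaminants), their relative abundances, and the record of protein-coding
#' genes implanted into them. The implant table is the machine-readable
#' ground truth against which the screening pipeline is validated.
#'
#' @slot genomes [Biostrings::DNAStringSet], named by genome id.
#' @slot abundance named numeric, summing to 1, parallel to `genomes`.
#' @slot circular named logical, parallel to `genomes`.
#' @slot implants data.frame with columns `seq_id`, `genome_id`, `start`,
#'   `end`, `strand`, `length_nt` (one row per implanted copy).
#' @slot seed integer seed the community was generated from.
#' @seealso [simulateCommunity()], [implantGenes()], [generateReads()]
#' @export
setClass("SyntheticCommunity",
  slots = c(
    genomes = "DNAStringSet",
    abundance = "numeric",
    circular = "logical",
    implants = "data.frame",
    seed = "integer"
  )
)

setValidity("SyntheticCommunity", function(object) {
  msg <- character()
  n <- length(object@genomes)
  if (n == 0L) msg <- c(msg, "community has no genomes")
  if (length(object@abundance) != n || length(object@circular) != n)
    msg <- c(msg, "abundance and circular must be parallel to genomes")
  else if (abs(sum(object@abundance) - 1) > 1e-9)
    msg <- c(msg, "abundances must sum to 1")
  if (nrow(object@implants)) {
    len <- Biostrings::width(object@genomes)[
      match(object@implants$genome_id, names(object@genomes))]
    if (anyNA(len) || any(object@implants$start < 1) ||
        any(object@implants$end > len))
      msg <- c(msg, "implant loci must lie within genome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Genome-by-transporter-family count matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with transporter families
#' as rows and genomes as columns, carrying two assays: `total` (all ORFs
#' whose best kept hit falls in the family) and `tm` (the subset of those
#' ORFs with at least one predicted transmembrane segment). Genome size in
#' ORFs, when known, is stored in `colData(x)$n_orfs`.
#'
#' @seealso [buildFamilyMatrix()], [brayCurtisMatrix()], [nmdsOrdinate()]
#' @export
setClass("FamilyCountMatrix", contains = "SummarizedExperiment")

setValidity("FamilyCountMatrix", function(object) {
  msg <- character()
  if (!all(c("total", "tm") %in% SummarizedExperiment::assayNames(object)))
    return("assays 'total' and 'tm' are required")
  tot <- SummarizedExperiment::assay(object, "total")
  tm <- SummarizedExperiment::assay(object, "tm")
  if (any(tot < 0) || any(tm < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(tm > tot)) msg <- c(msg, "tm counts cannot exceed total counts")
  if (length(msg)) msg else TRUE
})

#' Result of a nonmetric multidimensional scaling ordination
#'
#' Centered two(-or-more)-dimensional NMDS coordinates for a set of genomes,
#' with the Kruskal stress of the best configuration and the provenance
#' (distance metric, number of random starts, seed) needed to reproduce it.
#'
#' @slot points numeric matrix, genomes x dimensions, columns centered.
#' @slot stress non-negative Kruskal stress-1 of the retained solution.
#' @slot distanceMetric label of the dissimilarity used (e.g. `"bray"`).
#' @slot nRestarts number of random starts explored.
#' @slot seed integer seed.
#' @seealso [nmdsOrdinate()]
#' @export
setClass("OrdinationResult",
  slots = c(
    points = "matrix",
    stress = "numeric",
    distanceMetric = "character",
    nRestarts = "integer",
    seed = "integer"
  )
)

setValidity("OrdinationResult", function(object) {
  msg <- character()
  if (length(object@stress) != 1L || object@stress < 0)
    msg <- c(msg, "stress must be a single non-negative number")
  if (nrow(object@points) &&
      any(abs(colMeans(object@points)) > 1e-6 * (1 + max(abs(object@points)))))
    msg <- c(msg, "coordinates must be centered")
  if (length(msg)) msg else TRUE
})

#' Ortholog cluster membership across genomes
#'
#' Membership of protein-coding genes in ortholog clusters, plus per-genome
#' singleton genes (genes not included in any cluster). Pan/core statistics
#' and accumulation curves are computed over clusters only.
#'
#' @slot membership data.frame with columns `cluster_id`, `genome_id`,
#'   `gene_id`; a (genome, gene) pair occurs in at most one cluster.
#' @slot genomes character vector of all genome ids.
#' @slot singletons data.frame with columns `genome_id`, `gene_id`.
#' @seealso [readOrthologTable()], [corePanSets()], [accumulationCurves()]
#' @export
setClass("OrthologTable",
  slots = c(
    membership = "data.frame",
    genomes = "character",
    singletons = "data.frame"
  )
)

setValidity("OrthologTable", function(object) {
  msg <- character()
  m <- object@membership
  if (!all(c("cluster_id", "genome_id", "gene_id") %in% names(m)))
    return("membership needs columns cluster_id, genome_id, gene_id")
  key <- paste(m$genome_id, m$gene_id, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "a (genome, gene) pair occurs in more than one cluster")
  if (!all(m$genome_id %in% object@genomes))
    msg <- c(msg, "membership references genomes missing from the genome list")
  if (length(msg)) msg else TRUE
})
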