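# Synthetic communities, gene implantation, and read simulation with
# machine-readable ground truth.

#' Simulate a community of random genomes
#'
#' Genomes are i.i.d. nucleotide sequences at the requested GC content —
#' deliberately free of genes, so that every protein-coding signal present
#' later is one that [implantGenes()] put there and recorded in the truth
#' table.
#'
#' @param genomeLengths named integer vector of genome lengths (bp); names
#'   become genome ids (defaults `genome01`, ... if unnamed). Lengths of at
#'   least 10 kb are recommended so implants and read edges stay small
#'   relative to the genome.
#' @param gcContents per-genome GC fraction targets (recycled).
#' @param abundances positive relative abundances (normalized to sum to 1).
#' @param seed integer seed; the community is reproducible from it.
#' @param circular logical, recycled (kept as metadata; reads are drawn
#'   linearly either way).
#' @return a [SyntheticCommunity-class].
#' @export
simulateCommunity <- function(genomeLengths, gcContents = 0.5,
                              abundances = 1, seed = 1, circular = FALSE) {
  n <- length(genomeLengths)
  if (n == 0L) stop("at least one genome is required")
  ids <- names(genomeLengths)
  if (is.null(ids)) ids <- sprintf("genome%02d", seq_len(n))
  gc <- rep_len(gcContents, n)
  ab <- rep_len(abundances, n)
  if (any(ab <= 0) || sum(ab) <= 0)
    stop("abundances must be positive and normalizable")
  ab <- ab / sum(ab)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    p <- c(A = (1 - gc[i]) / 2, C = gc[i] / 2, G = gc[i] / 2,
           T = (1 - gc[i]) / 2)
    paste(sample(names(p), genomeLengths[i], replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  new("SyntheticCommunity",
      genomes = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
      abundance = stats::setNames(ab, ids),
      circular = stats::setNames(rep_len(circular, n), ids),
      implants = data.frame(seq_id = character(), genome_id = character(),
                            start = integer(), end = integer(),
                            strand = character(), length_nt = integer(),
                            stringsAsFactors = FALSE),
      seed = as.integer(seed))
}

#' Random peptides with a bacterial-like composition
#'
#' Convenience generator for panel stand-ins: residues drawn i.i.d. from
#' the 20 canonical amino acids at roughly average proteome frequencies.
#'
#' @param n number of peptides.
#' @param length peptide length(s), recycled.
#' @param seed integer seed.
#' @param ids sequence names.
#' @return a named [Biostrings::AAStringSet].
#' @export
randomPeptides <- function(n, length = 300, seed = 1,
                           ids = sprintf("pep%02d", seq_len(n))) {
  freq <- c(A = 8.9, R = 5.5, N = 3.9, D = 5.4, C = 1.2, Q = 3.8, E = 6.1,
            G = 7.3, H = 2.2, I = 5.9, L = 10.2, K = 4.9, M = 2.4, F = 3.9,
            P = 4.4, S = 6.1, T = 5.4, W = 1.3, Y = 2.9, V = 7.2)
  len <- rep_len(length, n)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(names(freq), len[i], replace = TRUE, prob = freq),
          collapse = ""), character(1))
  Biostrings::AAStringSet(stats::setNames(seqs, ids))
}

# Internal: codons per amino acid under the standard code.
.codonsByAA <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- split(names(Biostrings::GENETIC_CODE),
                                    unname(Biostrings::GENETIC_CODE))
    tab
  }
})

# Internal: back-translate one peptide with uniform-random synonymous
# codons (uses the current RNG stream).
.backTranslate <- function(peptide) {
  cb <- .codonsByAA()
  aa <- strsplit(as.character(peptide), "")[[1]]
  paste(vapply(aa, function(a) {
    cs <- cb[[a]]
    if (is.null(cs)) stop("cannot back-translate residue '", a, "'")
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

#' Implant protein-coding genes into community genomes
#'
#' Each placement writes one copy of a peptide into a genome: the peptide
#' is back-translated with uniform-random synonymous codons (so distinct
#' copies share the peptide but not the exact nucleotide sequence) and the
#' resulting CDS replaces the genome sequence at the stated locus, on the
#' stated strand. The implant table — the ground truth — is extended
#' accordingly.
#'
#' @param comm a [SyntheticCommunity-class].
#' @param peptides named [Biostrings::AAStringSet] of peptides referenced by
#'   `placements$seq_id`.
#' @param placements data.frame with columns `seq_id`, `genome_id`, `start`,
#'   `strand` (`"+"`/`"-"`), one row per copy. Loci must lie within the
#'   genome and must not overlap any other implant.
#' @param seed integer seed for the codon choices.
#' @return the community with modified genomes and updated `implants(x)`.
#' @export
implantGenes <- function(comm, peptides, placements, seed = 1) {
  if (nrow(placements) == 0L) return(comm)
  stopifnot(all(c("seq_id", "genome_id", "start", "strand") %in%
                  names(placements)))
  bad <- setdiff(placements$genome_id, names(genomes(comm)))
  if (length(bad)) stop("unknown genome(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(placements$seq_id, names(peptides))
  if (length(bad)) stop("unknown peptide(s): ", paste(bad, collapse = ", "))
  lenNt <- 3L * Biostrings::width(peptides)[match(placements$seq_id,
                                                  names(peptides))]
  newRows <- data.frame(
    seq_id = placements$seq_id, genome_id = placements$genome_id,
    start = as.integer(placements$start),
    end = as.integer(placements$start) + lenNt - 1L,
    strand = placements$strand, length_nt = lenNt,
    stringsAsFactors = FALSE)
  glen <- Biostrings::width(genomes(comm))[match(newRows$genome_id,
                                                 names(genomes(comm)))]
  if (any(newRows$start < 1L) || any(newRows$end > glen))
    stop("implant locus outside genome bounds")
  all_ <- rbind(comm@implants, newRows)
  for (g in unique(all_$genome_id)) {
    iv <- all_[all_$genome_id == g, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1] <= iv$end[-nrow(iv)]))
      stop("overlapping implant loci in genome '", g, "'")
  }
  set.seed(seed)
  gs <- genomes(comm)
  for (i in seq_len(nrow(newRows))) {
    cds <- .backTranslate(peptides[[newRows$seq_id[i]]])
    if (newRows$strand[i] == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    Biostrings::subseq(gs[[newRows$genome_id[i]]],
                       newRows$start[i], newRows$end[i]) <-
      Biostrings::DNAString(cds)
  }
  comm@genomes <- gs
  comm@implants <- all_
  validObject(comm)
  comm
}

#' Simulate shotgun reads from a community
#'
#' Source genomes are drawn with probability proportional to abundance
#' times genome length; start positions are uniform within the genome;
#' strands are equiprobable; substitution errors are i.i.d. per base at
#' `errorRate` (no indels, so reading frames survive sequencing error). In
#' paired mode, records are generated as mate pairs from fragments of
#' `insertSize` (R1 forward, R2 reverse-complement); each mate is one read
#' record.
#'
#' @param comm a [SyntheticCommunity-class].
#' @param nReads number of read records (> 0; even in paired mode).
#' @param readLength read length in bp; must not exceed the shortest
#'   genome.
#' @param errorRate per-base substitution probability.
#' @param paired generate mate pairs?
#' @param seed integer seed.
#' @param insertSize fragment length for paired mode.
#' @param libraryId id of the resulting library.
#' @return a [ReadLibrary-class] whose `readTruth()` table records each
#'   record's source genome, 1-based start on the forward strand of that
#'   genome, and strand.
#' @export
generateReads <- function(comm, nReads, readLength = 150, errorRate = 0,
                          paired = FALSE, seed = 1, insertSize = 3 * readLength,
                          libraryId = "simlib") {
  if (nReads <= 0) stop("nReads must be positive")
  glen <- Biostrings::width(genomes(comm))
  span <- if (paired) insertSize else readLength
  if (span > min(glen)) stop("read/fragment span exceeds shortest genome")
  if (paired && nReads %% 2L != 0L) stop("paired mode needs an even nReads")
  set.seed(seed)
  nFrag <- if (paired) nReads %/% 2L else nReads
  gs <- genomes(comm)
  prob <- abundances(comm) * glen
  gidx <- sample.int(length(gs), nFrag, replace = TRUE, prob = prob)
  starts <- 1L + floor(runif(nFrag) * (glen[gidx] - span + 1L))
  fragStrand <- sample(c("+", "-"), nFrag, replace = TRUE)
  # extract fragments genome by genome
  frags <- character(nFrag)
  for (g in seq_along(gs)) {
    sel <- which(gidx == g)
    if (!length(sel)) next
    frags[sel] <- as.character(Biostrings::extractAt(
      gs[[g]], IRanges::IRanges(starts[sel], width = span)))
  }
  if (paired) {
    r1 <- substr(frags, 1L, readLength)
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      substr(frags, span - readLength + 1L, span))))
    minus <- fragStrand == "-"
    # a minus-strand fragment swaps mate roles relative to the genome
    reads <- c(rbind(ifelse(minus, r2, r1), ifelse(minus, r1, r2)))
    r1pos <- starts; r2pos <- starts + span - readLength
    truth <- data.frame(
      read_id = paste0("read", formatC(rep(seq_len(nFrag), each = 2),
                                       width = 7, flag = "0"),
                       c("/1", "/2")),
      genome_id = rep(names(gs)[gidx], each = 2),
      start = as.integer(c(rbind(ifelse(minus, r2pos, r1pos),
                                 ifelse(minus, r1pos, r2pos)))),
      strand = c(rbind(fragStrand, ifelse(minus, "+", "-"))),
      stringsAsFactors = FALSE)
  } else {
    minus <- fragStrand == "-"
    reads <- frags
    if (any(minus))
      reads[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(frags[minus])))
    truth <- data.frame(
      read_id = paste0("read", formatC(seq_len(nFrag), width = 7, flag = "0")),
      genome_id = names(gs)[gidx],
      start = as.integer(starts),
      strand = fragStrand,
      stringsAsFactors = FALSE)
  }
  if (errorRate > 0) reads <- .addSubstitutions(reads, readLength, errorRate)
  lib <- ReadLibrary(stats::setNames(reads, truth$read_id),
                     libraryId = libraryId,
                     layout = if (paired) "paired" else "single",
                     truth = truth)
  lib
}

# Internal: i.i.d. substitution errors over equal-length reads, applied on
# the concatenated byte representation. Drawing K ~ Binomial(total, rate)
# error positions uniformly without replacement is exactly the i.i.d.
# Bernoulli(rate) per-base model.
.addSubstitutions <- function(reads, readLength, errorRate) {
  total <- length(reads) * readLength
  k <- rbinom(1L, total, errorRate)
  if (k == 0L) return(reads)
  pos <- sample.int(total, k)
  raw <- charToRaw(paste(reads, collapse = ""))
  cur <- rawToChar(raw[pos], multiple = TRUE)
  alt <- matrix(c("C", "G", "T",  "A", "G", "T",  "A", "C", "T",
                  "A", "C", "G"), nrow = 3,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pick <- alt[cbind(sample.int(3L, k, replace = TRUE),
                    match(cur, colnames(alt)))]
  raw[pos] <- charToRaw(paste(pick, collapse = ""))
  all_ <- rawToChar(raw)
  substring(all_, (seq_along(reads) - 1L) * readLength + 1L,
            seq_along(reads) * readLength)
}

#' View a synthetic community as a binned assembly
#'
#' Treats each genome of the community as one perfectly assembled, perfectly
#' binned contig — the idealized metagenome assembly against which candidate
#' reads are re-mapped in end-to-end tests of the attribution logic.
#'
#' @param comm a [SyntheticCommunity-class].
#' @param focal genome id of the focal symbiont (default: the most abundant
#'   genome).
#' @return a [BinnedAssembly-class] with one contig per genome, bin ids
#'   equal to genome ids.
#' @export
asBinnedAssembly <- function(comm, focal = names(which.max(abundances(comm)))) {
  gs <- genomes(comm)
  BinnedAssembly(gs, stats::setNames(names(gs), names(gs)), focalBin = focal)
}

#' Ground-truth expectations for a screened panel set
#'
#' Summarizes the implant table per panel: copies per genome, and the
#' expected relative coverage under the stated abundances (read depth over a
#' locus is proportional to its genome's abundance, so a panel's expected
#' coverage is the abundance-weighted copy sum per kb of panel reference
#' length, normalized by the median of the reference panels).
#'
#' @param comm a [SyntheticCommunity-class] after [implantGenes()].
#' @param ps the [PanelSet-class] whose members were (or were not)
#'   implanted.
#' @return data.frame with one row per panel: `panel_id`, `role`,
#'   `copies_focal`, `copies_total`, `expected_relative_coverage`; the
#'   focal genome is taken as the most abundant one.
#' @export
syntheticTruth <- function(comm, ps) {
  ab <- abundances(comm)
  focal <- names(which.max(ab))
  imp <- implants(comm)
  pls <- panels(ps)
  depthFor <- function(p) {
    mem <- names(panelSequences(p))
    rows <- imp[imp$seq_id %in% mem, , drop = FALSE]
    sum(ab[rows$genome_id]) / (3 * meanAALength(p))
  }
  depth <- vapply(pls, depthFor, numeric(1))
  roles <- vapply(pls, panelRole, character(1))
  refMed <- stats::median(depth[roles == "reference"])
  data.frame(
    panel_id = names(pls),
    role = roles,
    copies_focal = vapply(pls, function(p) sum(
      imp$seq_id %in% names(panelSequences(p)) & imp$genome_id == focal),
      numeric(1)),
    copies_total = vapply(pls, function(p) sum(
      imp$seq_id %in% names(panelSequences(p))), numeric(1)),
    expected_relative_coverage = if (!is.na(refMed) && refMed > 0)
      depth / refMed else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a complete absence-screening scenario
#'
#' Builds the standard study conditions used throughout the package's
#' end-to-end validation: a three-genome community (a focal symbiont at 80%
#' relative abundance and two contaminants at 15% and 5%, 50 kb each at GC
#' 0.45/0.50/0.55), a reference panel set of four single-copy TCA-cycle
#' stand-ins implanted in the focal genome, three autotrophy-marker target
#' panels (RuBisCO, ATP-citrate lyase and acetyl-CoA synthase proxies)
#' implanted nowhere, in the focal genome, or solely in the 5% contaminant,
#' and a single-end read library simulated from the community. All panel
#' stand-ins are 300-residue random peptides, so coverage ratios between
#' panels reflect sampling alone.
#'
#' @param targetLocation where the target genes reside: `"absent"` (in no
#'   genome), `"focal"` (single copy each in the focal genome), or
#'   `"contaminant"` (single copy each in the rarest contaminant — the
#'   classic contamination false-positive the attribution step exists to
#'   catch).
#' @param seed integer seed driving peptides, community, implants and
#'   reads.
#' @param nReads,readLength,errorRate read simulation settings.
#' @param genomeLengths,abundances,gcContents community settings.
#' @param peptideLength length of every panel stand-in peptide.
#' @return list with elements `community`, `panels`, `library`, `assembly`
#'   (one contig per genome, focal genome focal), and `truth`
#'   ([syntheticTruth()] table).
#' @export
simulateScreenScenario <- function(targetLocation = c("absent", "focal",
                                                      "contaminant"),
                                   seed = 1, nReads = 2e5, readLength = 150,
                                   errorRate = 0,
                                   genomeLengths = c(focal = 50000,
                                                     contam_A = 50000,
                                                     contam_B = 50000),
                                   abundances = c(0.80, 0.15, 0.05),
                                   gcContents = c(0.45, 0.50, 0.55),
                                   peptideLength = 300) {
  targetLocation <- match.arg(targetLocation)
  stopifnot(length(genomeLengths) == 3L)
  gids <- names(genomeLengths)
  targetDefs <- data.frame(
    panel_id = c("RuBisCO", "ACL", "AcsB"),
    ec = c("4.1.1.39", "2.3.3.8", "2.3.1.169"),
    pathway = c("CBB", "rTCA", "Wood-Ljungdahl"),
    stringsAsFactors = FALSE)
  refDefs <- data.frame(
    panel_id = c("GltA", "AcnB", "Mdh", "SucC"),
    ec = c("2.3.3.16", "4.2.1.3", "1.1.1.37", "6.2.1.5"),
    pathway = "TCA reference",
    stringsAsFactors = FALSE)
  allIds <- c(targetDefs$panel_id, refDefs$panel_id)
  peps <- randomPeptides(length(allIds), peptideLength, seed = seed,
                         ids = paste0(allIds, "_1"))
  mkPanel <- function(def, i, role) ProteinPanel(
    def$panel_id[i], role, peps[paste0(def$panel_id[i], "_1")],
    ecNumbers = def$ec[i], pathwayLabel = def$pathway[i])
  ps <- PanelSet(c(
    lapply(seq_len(nrow(targetDefs)), function(i)
      mkPanel(targetDefs, i, "target")),
    lapply(seq_len(nrow(refDefs)), function(i)
      mkPanel(refDefs, i, "reference"))))
  comm <- simulateCommunity(genomeLengths, gcContents, abundances,
                            seed = seed + 1000L)
  geneSpan <- 3L * peptideLength
  slot_ <- function(i) 2000L + (i - 1L) * (geneSpan + 4100L)
  plc <- data.frame(
    seq_id = paste0(refDefs$panel_id, "_1"),
    genome_id = gids[1],
    start = slot_(seq_len(nrow(refDefs))),
    strand = rep_len(c("+", "-"), nrow(refDefs)),
    stringsAsFactors = FALSE)
  if (targetLocation != "absent") {
    tg <- if (targetLocation == "focal") gids[1] else gids[3]
    off <- if (targetLocation == "focal") nrow(refDefs) else 0L
    plc <- rbind(plc, data.frame(
      seq_id = paste0(targetDefs$panel_id, "_1"),
      genome_id = tg,
      start = slot_(off + seq_len(nrow(targetDefs))),
      strand = rep_len(c("-", "+"), nrow(targetDefs)),
      stringsAsFactors = FALSE))
  }
  comm <- implantGenes(comm, peps, plc, seed = seed + 2000L)
  lib <- generateReads(comm, nReads = nReads, readLength = readLength,
                       errorRate = errorRate, seed = seed + 3000L,
                       libraryId = paste0("sim_seed", seed))
  list(community = comm,
       panels = ps,
       library = lib,
       assembly = asBinnedAssembly(comm, focal = gids[1]),
       truth = syntheticTruth(comm, ps))
}
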