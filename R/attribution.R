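# Re-mapping candidate reads onto the binned assembly and attributing them
# to genome bins.

#' Construct a binned assembly
#'
#' @param contigs named [Biostrings::DNAStringSet] (or named character).
#' @param bins named character vector mapping contig id to bin id; contigs
#'   missing from it are assigned `"unbinned"`.
#' @param focalBin bin id of the focal symbiont bin.
#' @param meanCoverage optional named numeric of per-contig mean coverage
#'   (kept in `mcols` for coverage-GC plots).
#' @return a [BinnedAssembly-class]; per-contig GC fraction is computed and
#'   stored in `mcols(contigs(x))$gc`.
#' @export
BinnedAssembly <- function(contigs, bins, focalBin, meanCoverage = NULL) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  ids <- names(contigs)
  binOf <- stats::setNames(rep("unbinned", length(ids)), ids)
  binOf[names(bins)[names(bins) %in% ids]] <- bins[names(bins) %in% ids]
  gc <- as.numeric(Biostrings::letterFrequency(contigs, "GC")) /
    pmax(Biostrings::width(contigs), 1L)
  S4Vectors::mcols(contigs) <- S4Vectors::DataFrame(
    gc = gc,
    mean_coverage = if (is.null(meanCoverage)) NA_real_ else
      as.numeric(meanCoverage[ids]))
  new("BinnedAssembly", contigs = contigs, binOf = binOf, focalBin = focalBin)
}

#' Read a binned assembly from FASTA plus a contig-to-bin table
#'
#' @param fastaPath contig FASTA.
#' @param binsPath TSV with columns `contig_id`, `bin_id`.
#' @param focalBin the focal bin id.
#' @return a [BinnedAssembly-class].
#' @export
readBinnedAssembly <- function(fastaPath, binsPath, focalBin) {
  contigs <- Biostrings::readDNAStringSet(fastaPath)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  tab <- utils::read.delim(binsPath, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "bin_id") %in% names(tab)))
    stop("bin table must have columns contig_id, bin_id")
  BinnedAssembly(contigs, stats::setNames(tab$bin_id, tab$contig_id), focalBin)
}

#' Map candidate reads onto assembly contigs
#'
#' Each read is placed on the contig giving its best nucleotide alignment
#' (exact k-mer seeds, ungapped full-length verification on the seeded
#' diagonal, both strands), accepted when identity is at least `minIdentity`
#' over at least `minReadCov` of the read length. Ties on the number of
#' matching bases go to the lexicographically smallest contig id. The
#' contract is defined by these thresholds, so an external SAM mapping
#' ([readSamMapping()]) can substitute.
#'
#' @param reads named [Biostrings::DNAStringSet] (or a [ReadLibrary-class])
#'   of candidate reads, typically those with best hits to a target panel.
#' @param asm a [BinnedAssembly-class].
#' @param minIdentity minimum nucleotide identity (fraction; default 0.97).
#' @param minReadCov minimum aligned fraction of the read (default 0.9).
#' @param seedLength exact seed length in nt.
#' @return data.frame with columns `read_id`, `contig_id` (`NA` when
#'   unmapped), `identity`, `coverage`, `strand`, `pos`.
#' @export
mapReadsToContigs <- function(reads, asm, minIdentity = 0.97,
                              minReadCov = 0.9, seedLength = 16) {
  if (is(reads, "ReadLibrary")) reads <- readSequences(reads)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  ctg <- contigs(asm)
  ctg <- ctg[order(names(ctg))]
  if (length(reads) == 0L)
    return(data.frame(read_id = character(), contig_id = character(),
                      identity = numeric(), coverage = numeric(),
                      strand = integer(), pos = integer(),
                      stringsAsFactors = FALSE))
  m <- cpp_map_reads(as.character(reads), as.character(ctg),
                     as.integer(seedLength), minIdentity, minReadCov)
  data.frame(
    read_id = names(reads),
    contig_id = ifelse(m$contig > 0, names(ctg)[pmax(m$contig, 1L)],
                       NA_character_),
    identity = m$identity, coverage = m$coverage,
    strand = m$strand, pos = m$pos, stringsAsFactors = FALSE)
}

#' Read a mapping of candidate reads from a SAM file
#'
#' Accepts an external mapper's SAM output in lieu of [mapReadsToContigs()].
#' Identity is recomputed from the CIGAR string and the `NM` tag as
#' `(aligned columns - NM) / aligned columns` (columns = M/=/X/I/D
#' operations); read coverage as query-consuming aligned bases over read
#' length (soft/hard clips excluded). Records failing the thresholds, and
#' unmapped records, yield `contig_id = NA`. Secondary and supplementary
#' alignments are ignored.
#'
#' @param path SAM file.
#' @param minIdentity,minReadCov acceptance thresholds as in
#'   [mapReadsToContigs()].
#' @return data.frame with columns `read_id`, `contig_id`, `identity`,
#'   `coverage`, `strand`, `pos`.
#' @export
readSamMapping <- function(path, minIdentity = 0.97, minReadCov = 0.9) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  out <- data.frame(read_id = character(), contig_id = character(),
                    identity = numeric(), coverage = numeric(),
                    strand = integer(), pos = integer(),
                    stringsAsFactors = FALSE)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("malformed SAM record: ", substr(ln, 1, 60))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) next
    rid <- f[1]
    if (bitwAnd(flag, 4L) > 0L || f[3] == "*") {
      out[nrow(out) + 1L, ] <- list(rid, NA_character_, NA_real_, NA_real_,
                                    NA_integer_, NA_integer_)
      next
    }
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    alnCols <- sum(n[op %in% c("M", "=", "X", "I", "D")])
    qAligned <- sum(n[op %in% c("M", "=", "X", "I")])
    readLen <- sum(n[op %in% c("M", "=", "X", "I", "S", "H")])
    nm <- sub("^NM:i:", "", grep("^NM:i:", f, value = TRUE)[1])
    nm <- if (is.na(nm)) 0L else as.integer(nm)
    ident <- if (alnCols > 0) (alnCols - nm) / alnCols else 0
    cov <- if (readLen > 0) qAligned / readLen else 0
    ok <- ident >= minIdentity && cov >= minReadCov
    out[nrow(out) + 1L, ] <- list(
      rid, if (ok) f[3] else NA_character_, ident, cov,
      if (bitwAnd(flag, 16L) > 0L) -1L else 1L, as.integer(f[4]))
  }
  out
}

#' Attribute candidate reads to genome bins
#'
#' Partitions the candidate reads of one target panel by the bin membership
#' of the contig they map to. Reads on contigs outside the focal bin —
#' including unbinned contigs — count as outside; unmapped reads carry no
#' bin evidence and are excluded from the fraction's denominator.
#'
#' @param mapping data.frame from [mapReadsToContigs()] or
#'   [readSamMapping()].
#' @param asm the [BinnedAssembly-class] mapped against.
#' @param panelId id of the target panel the candidates belong to.
#' @return one-row data.frame: `panel_id`, `n_candidates`, `n_inside_focal`,
#'   `n_outside_focal`, `n_unmapped`, `attributed_outside_fraction`
#'   (`NA` when no candidate mapped).
#' @export
attributeCandidateReads <- function(mapping, asm, panelId) {
  bins <- binOf(asm)
  mapped <- !is.na(mapping$contig_id)
  inFocal <- mapped & bins[mapping$contig_id] == focalBin(asm)
  nIn <- sum(inFocal, na.rm = TRUE)
  nOut <- sum(mapped) - nIn
  nUn <- sum(!mapped)
  data.frame(
    panel_id = panelId,
    n_candidates = nrow(mapping),
    n_inside_focal = nIn,
    n_outside_focal = nOut,
    n_unmapped = nUn,
    attributed_outside_fraction =
      if (nIn + nOut > 0) nOut / (nIn + nOut) else NA_real_,
    stringsAsFactors = FALSE)
}
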