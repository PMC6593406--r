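# Loading, validating and summarizing protein panels.

#' Construct a protein panel
#'
#' Low-level constructor; most users will go through [readProteinPanel()] or
#' [readPanelSet()]. Sequences are uppercased; stop (`*`) and gap (`-`, `.`)
#' characters are stripped with a warning; the ambiguous residues B, Z, J, U
#' and O are mapped to `X` with a warning so that downstream alignment
#' scoring sees a defined alphabet.
#'
#' @param panelId single string.
#' @param role `"target"` or `"reference"`.
#' @param sequences named [Biostrings::AAStringSet] (or named character).
#' @param ecNumbers character vector of EC numbers applying to every member,
#'   or a list with one character vector per member. Members with no EC
#'   number are treated as coming from the additional-sequence route.
#' @param pathwayLabel free-text pathway annotation.
#' @return a [ProteinPanel-class].
#' @examples
#' ProteinPanel("rubisco", "target",
#'              sequences = c(rbcL = "MSPQTETKASVGFKAGV"),
#'              ecNumbers = "4.1.1.39", pathwayLabel = "CBB")
#' @export
ProteinPanel <- function(panelId, role, sequences, ecNumbers = character(),
                         pathwayLabel = "") {
  if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
  if (length(sequences) == 0L) stop("empty panel: '", panelId, "'")
  seqs <- toupper(as.character(sequences))
  n_strip <- sum(lengths(regmatches(seqs, gregexpr("[*.-]", seqs))))
  if (n_strip > 0) {
    warning("panel '", panelId, "': stripped ", n_strip,
            " stop/gap character(s)")
    seqs <- gsub("[*.-]", "", seqs)
  }
  n_amb <- sum(lengths(regmatches(seqs, gregexpr("[BZJUO]", seqs))))
  if (n_amb > 0) {
    warning("panel '", panelId, "': mapped ", n_amb,
            " ambiguous residue(s) (B/Z/J/U/O) to X")
    seqs <- chartr("BZJUO", "XXXXX", seqs)
  }
  if (any(!nchar(seqs))) stop("panel '", panelId, "': empty sequence after cleanup")
  if (is.character(ecNumbers))
    ecNumbers <- rep(list(ecNumbers[nzchar(ecNumbers)]), length(seqs))
  new("ProteinPanel", panelId = panelId, role = role,
      pathwayLabel = pathwayLabel,
      sequences = Biostrings::AAStringSet(seqs), ecNumbers = ecNumbers)
}

#' Load one protein panel from a FASTA file
#'
#' Reads the member sequences of one panel (all sequences in the file) and
#' attaches the manifest metadata: panel id, role in the screen, pathway
#' label and EC numbers. Residues are uppercased and `*`/gap characters
#' stripped with a warning (see [ProteinPanel()]).
#'
#' @param fastaPath path to a protein FASTA file.
#' @param panelId,role,ecNumbers,pathwayLabel see [ProteinPanel()].
#' @return a [ProteinPanel-class].
#' @export
readProteinPanel <- function(fastaPath, panelId, role,
                             ecNumbers = character(), pathwayLabel = "") {
  seqs <- Biostrings::readAAStringSet(fastaPath)
  if (length(seqs) == 0L) stop("empty panel: no sequences in ", fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate seq_id in ", fastaPath, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  ProteinPanel(panelId, role, seqs, ecNumbers, pathwayLabel)
}

#' Build a panel set
#'
#' @param ... [ProteinPanel-class] objects, or a single list of them.
#' @return a [PanelSet-class]. Structural invariants (at least one reference
#'   panel, no shared sequence ids) are checked by [validatePanels()], not at
#'   construction.
#' @export
PanelSet <- function(...) {
  p <- list(...)
  if (length(p) == 1L && is.list(p[[1]]) && !is(p[[1]], "ProteinPanel"))
    p <- p[[1]]
  new("PanelSet", panels = p)
}

#' Read a panel set from a manifest
#'
#' The manifest is a TSV with columns `panel_id`, `role`, `pathway_label`,
#' `ec_numbers` (semicolon-joined, possibly empty) and `fasta_path`
#' (relative paths resolved against the manifest's directory).
#'
#' @param manifestPath path to the manifest TSV.
#' @param baseDir directory against which relative `fasta_path` entries are
#'   resolved; defaults to the manifest's directory.
#' @return a [PanelSet-class].
#' @seealso [writePanelSet()] for the inverse operation.
#' @export
readPanelSet <- function(manifestPath, baseDir = dirname(manifestPath)) {
  man <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  need <- c("panel_id", "role", "pathway_label", "ec_numbers", "fasta_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  ps <- lapply(seq_len(nrow(man)), function(i) {
    fp <- man$fasta_path[i]
    if (!file.exists(fp)) fp <- file.path(baseDir, fp)
    ec <- strsplit(man$ec_numbers[i], ";", fixed = TRUE)[[1]]
    readProteinPanel(fp, man$panel_id[i], man$role[i],
                     ecNumbers = trimws(ec[nzchar(trimws(ec))]),
                     pathwayLabel = man$pathway_label[i])
  })
  PanelSet(ps)
}

#' Write a panel set to FASTA files plus a manifest
#'
#' @param ps a [PanelSet-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writePanelSet <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(panels(ps), function(p) {
    fa <- paste0(panelId(p), ".faa")
    Biostrings::writeXStringSet(panelSequences(p), file.path(dir, fa))
    data.frame(panel_id = panelId(p), role = panelRole(p),
               pathway_label = pathwayLabel(p),
               ec_numbers = paste(unique(unlist(ecNumbers(p))), collapse = ";"),
               fasta_path = fa, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifestPath)
}

#' Validate a panel set
#'
#' Checks the structural invariants of a screen's panel set: at least one
#' reference panel, unique panel ids, no sequence id shared between panels,
#' no empty panels. An empty report means the set is valid.
#'
#' @param ps a [PanelSet-class].
#' @return data.frame with columns `panel_id` and `issue` (zero rows iff
#'   the set is valid).
#' @export
validatePanels <- function(ps) {
  issues <- data.frame(panel_id = character(), issue = character(),
                       stringsAsFactors = FALSE)
  flag <- function(panel_id, issue)
    rbind(issues, data.frame(panel_id = panel_id, issue = issue,
                             stringsAsFactors = FALSE))
  if (length(ps) == 0L)
    return(flag("", "panel set is empty"))
  ids <- vapply(ps@panels, panelId, character(1))
  roles <- vapply(ps@panels, panelRole, character(1))
  if (!any(roles == "reference"))
    issues <- flag("", "no reference panel in set")
  for (d in unique(ids[duplicated(ids)]))
    issues <- flag(d, "duplicate panel_id")
  seqids <- data.frame(
    panel_id = rep(ids, vapply(ps@panels, length, integer(1))),
    seq_id = unlist(lapply(ps@panels, function(p) names(panelSequences(p)))),
    stringsAsFactors = FALSE)
  dup <- unique(seqids$seq_id[duplicated(seqids$seq_id)])
  for (d in dup)
    issues <- flag(paste(seqids$panel_id[seqids$seq_id == d], collapse = ","),
                   paste0("seq_id '", d, "' appears in more than one panel"))
  for (p in ps@panels)
    if (length(p) == 0L) issues <- flag(panelId(p), "panel has no members")
  issues
}

# Internal: flattened panel member table used by the search and the screen.
.panelMemberTable <- function(ps) {
  pls <- panels(ps)
  data.frame(
    panel_id = rep(names(pls), vapply(pls, length, integer(1))),
    seq_id = unlist(lapply(pls, function(p) names(panelSequences(p))),
                    use.names = FALSE),
    length_aa = unlist(lapply(pls, function(p)
      Biostrings::width(panelSequences(p))), use.names = FALSE),
    stringsAsFactors = FALSE)
}

# Internal: all member sequences of a set as one named AAStringSet.
.panelMemberSeqs <- function(ps) {
  out <- do.call(c, unname(lapply(panels(ps), panelSequences)))
  out
}
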