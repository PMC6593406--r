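makeAsm <- function(seed = 5) {
  set.seed(seed)
  mkseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
  BinnedAssembly(
    c(C1 = mkseq(3000), C2 = mkseq(3000), C3 = mkseq(2000)),
    bins = c(C1 = "focal", C2 = "contam", C3 = "unbinned"),
    focalBin = "focal")
}

test_that("reads map to their source contig on either strand", {
  asm <- makeAsm()
  c1 <- as.character(contigs(asm)[["C1"]])
  c2 <- as.character(contigs(asm)[["C2"]])
  reads <- c(
    exact = substr(c1, 101, 250),
    rc = revcompChr(substr(c2, 501, 650)),
    random = paste(rep("ACGT", 40), collapse = ""))
  m <- mapReadsToContigs(Biostrings::DNAStringSet(reads), asm)
  expect_equal(m$contig_id[m$read_id == "exact"], "C1")
  expect_equal(m$identity[m$read_id == "exact"], 1)
  expect_equal(m$contig_id[m$read_id == "rc"], "C2")
  expect_equal(m$strand[m$read_id == "rc"], -1L)
  expect_true(is.na(m$contig_id[m$read_id == "random"]))
})

test_that("identity threshold separates near-identical from diverged reads", {
  asm <- makeAsm()
  c1 <- as.character(contigs(asm)[["C1"]])
  rd <- substr(c1, 1, 150)
  mut <- function(x, at) {
    for (p in at) substr(x, p, p) <- chartr("ACGT", "CGTA", substr(x, p, p))
    x
  }
  near <- mut(rd, c(30, 70, 110))        # 3/150 = 2% divergence, passes 0.97
  far <- mut(rd, seq(5, 145, by = 10))   # ~10% divergence, fails
  m <- mapReadsToContigs(Biostrings::DNAStringSet(c(near = near, far = far)),
                         asm)
  expect_equal(m$contig_id[m$read_id == "near"], "C1")
  expect_true(is.na(m$contig_id[m$read_id == "far"]))
})

test_that("attribution partitions candidates and excludes unmapped from the fraction", {
  asm <- makeAsm()
  mapping <- data.frame(
    read_id = paste0("r", 1:10),
    contig_id = c(rep("C2", 8), NA, NA),
    stringsAsFactors = FALSE)
  a <- attributeCandidateReads(mapping, asm, "rubisco")
  expect_equal(a$n_candidates, 10L)
  expect_equal(a$n_inside_focal, 0L)
  expect_equal(a$n_outside_focal, 8L)
  expect_equal(a$n_unmapped, 2L)
  expect_equal(a$attributed_outside_fraction, 1)

  allFocal <- data.frame(read_id = paste0("r", 1:10), contig_id = "C1",
                         stringsAsFactors = FALSE)
  expect_equal(attributeCandidateReads(allFocal, asm,
                                       "x")$attributed_outside_fraction, 0)

  none <- mapping[0, ]
  a0 <- attributeCandidateReads(none, asm, "x")
  expect_equal(a0$n_candidates, 0L)
  expect_true(is.na(a0$attributed_outside_fraction))

  unbinned <- data.frame(read_id = "r1", contig_id = "C3",
                         stringsAsFactors = FALSE)
  expect_equal(attributeCandidateReads(unbinned, asm,
                                       "x")$attributed_outside_fraction, 1)
})

test_that("the candidate partition is conserved on randomized mappings", {
  asm <- makeAsm()
  set.seed(21)
  for (i in 1:20) {
    n <- sample(0:30, 1)
    mapping <- data.frame(
      read_id = paste0("r", seq_len(n)),
      contig_id = sample(c("C1", "C2", "C3", NA), n, replace = TRUE),
      stringsAsFactors = FALSE)
    a <- attributeCandidateReads(mapping, asm, "p")
    expect_equal(a$n_inside_focal + a$n_outside_focal + a$n_unmapped,
                 a$n_candidates)
  }
})

test_that("SAM records substitute for the built-in mapper", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:C1\tLN:3000",
    paste("r1", 0, "C1", 101, 60, "150M", "*", 0, 0,
          strrep("A", 150), "*", "NM:i:2", sep = "\t"),
    paste("r2", 16, "C2", 51, 60, "100M50S", "*", 0, 0,
          strrep("A", 150), "*", "NM:i:0", sep = "\t"),   # 67% coverage: fails
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("A", 150), "*", sep = "\t")), sam)
  m <- readSamMapping(sam)
  expect_equal(m$contig_id[m$read_id == "r1"], "C1")
  expect_equal(m$identity[m$read_id == "r1"], 148 / 150)
  expect_true(is.na(m$contig_id[m$read_id == "r2"]))
  expect_true(is.na(m$contig_id[m$read_id == "r3"]))
})
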