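test_that("simulated genomes hit their GC targets and are reproducible", {
  comm <- simulateCommunity(c(g1 = 50000, g2 = 50000),
                            gcContents = c(0.40, 0.60),
                            abundances = c(0.7, 0.3), seed = 5)
  gc <- Biostrings::letterFrequency(genomes(comm), "GC", as.prob = TRUE)
  expect_lt(abs(gc[1] - 0.40), 0.02)
  expect_lt(abs(gc[2] - 0.60), 0.02)
  comm2 <- simulateCommunity(c(g1 = 50000, g2 = 50000),
                             gcContents = c(0.40, 0.60),
                             abundances = c(0.7, 0.3), seed = 5)
  expect_identical(as.character(genomes(comm)), as.character(genomes(comm2)))
  expect_equal(sum(abundances(comm)), 1)
  expect_error(simulateCommunity(integer(0)), "at least one genome")
  expect_error(simulateCommunity(c(g = 1000), abundances = -1), "positive")
})

test_that("implants are placed, recorded, and translate back to the peptide", {
  comm <- simulateCommunity(c(focal = 20000, contam = 20000), seed = 2)
  peps <- randomPeptides(1, 100, seed = 3, ids = "rbcL_1")
  comm2 <- implantGenes(comm, peps,
                        data.frame(seq_id = "rbcL_1", genome_id = "contam",
                                   start = 5001, strand = "-"), seed = 4)
  imp <- implants(comm2)
  expect_equal(nrow(imp), 1L)
  expect_equal(imp$length_nt, 300L)
  expect_equal(sum(imp$genome_id == "focal"), 0L)  # truth: focal copies 0
  # round trip: translating the locus in the placed frame gives the peptide
  locus <- as.character(Biostrings::subseq(genomes(comm2)[["contam"]],
                                           5001, 5300))
  expect_equal(sixFrameTranslate(locus)[["-1"]], as.character(peps[[1]]))

  # two copies in one genome are both recorded
  comm3 <- implantGenes(comm, peps,
                        data.frame(seq_id = c("rbcL_1", "rbcL_1"),
                                   genome_id = "focal",
                                   start = c(1000, 3000), strand = "+"),
                        seed = 4)
  expect_equal(sum(implants(comm3)$seq_id == "rbcL_1"), 2L)

  expect_error(
    implantGenes(comm, peps,
                 data.frame(seq_id = c("rbcL_1", "rbcL_1"),
                            genome_id = "focal", start = c(1000, 1100),
                            strand = "+")),
    "overlap")
  expect_error(
    implantGenes(comm, peps,
                 data.frame(seq_id = "rbcL_1", genome_id = "focal",
                            start = 19901, strand = "+")),
    "bounds")
})

test_that("error-free reads are exact substrings of their source genome", {
  comm <- simulateCommunity(c(a = 15000, b = 15000), seed = 6)
  lib <- generateReads(comm, nReads = 50, readLength = 100, errorRate = 0,
                       seed = 7)
  tr <- readTruth(lib)
  for (i in seq_len(50)) {
    g <- as.character(genomes(comm)[[tr$genome_id[i]]])
    fragment <- substr(g, tr$start[i], tr$start[i] + 99)
    rd <- as.character(readSequences(lib)[[i]])
    expect_equal(rd, if (tr$strand[i] == "+") fragment else revcompChr(fragment))
  }
  expect_error(generateReads(comm, 0), "positive")
})

test_that("read counts split by abundance within binomial error", {
  comm <- simulateCommunity(c(a = 20000, b = 20000),
                            abundances = c(0.9, 0.1), seed = 8)
  lib <- generateReads(comm, nReads = 1e5, readLength = 100, seed = 9)
  nA <- sum(readTruth(lib)$genome_id == "a")
  sigma <- sqrt(1e5 * 0.9 * 0.1)
  expect_lt(abs(nA - 9e4), 3 * sigma)
})

test_that("substitution errors appear at the requested rate", {
  comm <- simulateCommunity(c(a = 20000), seed = 10)
  lib <- generateReads(comm, nReads = 2000, readLength = 100,
                       errorRate = 0.02, seed = 11)
  tr <- readTruth(lib)
  g <- as.character(genomes(comm)[["a"]])
  nDiff <- 0L
  for (i in seq_len(2000)) {
    fragment <- substr(g, tr$start[i], tr$start[i] + 99)
    if (tr$strand[i] == "-") fragment <- revcompChr(fragment)
    rd <- as.character(readSequences(lib)[[i]])
    nDiff <- nDiff + sum(strsplit(rd, "")[[1]] != strsplit(fragment, "")[[1]])
  }
  rate <- nDiff / 2e5
  expect_lt(abs(rate - 0.02), 3 * sqrt(0.02 * 0.98 / 2e5))
})

test_that("paired mode yields mate records with consistent truth", {
  comm <- simulateCommunity(c(a = 20000), seed = 12)
  lib <- generateReads(comm, nReads = 40, readLength = 100, paired = TRUE,
                       seed = 13, insertSize = 300)
  expect_equal(totalReads(lib), 40L)
  tr <- readTruth(lib)
  expect_true(all(grepl("/[12]$", tr$read_id)))
  # mates come from the same fragment: starts differ by insert - readlen
  odd <- seq(1, 39, by = 2)
  expect_true(all(abs(tr$start[odd + 1] - tr$start[odd]) == 200))
  expect_true(all(tr$strand[odd] != tr$strand[odd + 1]))
  # every record is still an exact substring on its stated strand
  g <- as.character(genomes(comm)[["a"]])
  for (i in seq_len(40)) {
    fragment <- substr(g, tr$start[i], tr$start[i] + 99)
    rd <- as.character(readSequences(lib)[[i]])
    expect_equal(rd, if (tr$strand[i] == "+") fragment else revcompChr(fragment))
  }
})

test_that("scenario truth matches its construction", {
  sc <- simulateScreenScenario("contaminant", seed = 3, nReads = 1000)
  tr <- sc$truth
  expect_equal(tr$copies_focal[tr$role == "target"], rep(0, 3))
  expect_equal(tr$copies_total[tr$role == "target"], rep(1, 3))
  expect_equal(tr$expected_relative_coverage[tr$role == "reference"],
               rep(1, 4))
  expect_equal(tr$expected_relative_coverage[tr$role == "target"],
               rep(0.05 / 0.80, 3))
  expect_equal(focalBin(sc$assembly), "focal")
  sc2 <- simulateScreenScenario("contaminant", seed = 3, nReads = 1000)
  expect_identical(as.character(readSequences(sc2$library)),
                   as.character(readSequences(sc$library)))
})
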