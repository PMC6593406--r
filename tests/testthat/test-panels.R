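test_that("FASTA loading normalizes case and strips stops/gaps with warning", {
  fa <- tempfile(fileext = ".faa")
  writeLines(c(">p1 some description", "mkv", ">p2", "MKVLW"), fa)
  p <- readProteinPanel(fa, "demo", "target", ecNumbers = "4.1.1.39")
  expect_s4_class(p, "ProteinPanel")
  expect_equal(length(p), 2L)
  expect_equal(as.character(panelSequences(p))[["p1"]], "MKV")

  writeLines(c(">p1", "MKV*"), fa)
  expect_warning(p <- readProteinPanel(fa, "demo", "target"), "stop/gap")
  expect_equal(as.character(panelSequences(p))[["p1"]], "MKV")
})

test_that("empty panels and duplicate ids are rejected", {
  fa <- tempfile(fileext = ".faa")
  file.create(fa)
  expect_error(readProteinPanel(fa, "x", "target"), "empty panel")
  writeLines(c(">dup", "MKV", ">dup", "MKW"), fa)
  expect_error(readProteinPanel(fa, "x", "target"), "duplicate seq_id")
})

test_that("ambiguous residues map to X with a warning", {
  expect_warning(p <- ProteinPanel("z", "target", c(a = "MBZKU")), "B/Z/J/U/O")
  expect_equal(as.character(panelSequences(p))[["a"]], "MXXKX")
})

test_that("mean amino-acid length is the arithmetic mean and order-invariant", {
  p1 <- ProteinPanel("a", "target", c(x = strrep("M", 300)))
  expect_equal(meanAALength(p1), 300)
  p2 <- ProteinPanel("b", "target",
                     c(x = strrep("M", 400), y = strrep("K", 600)))
  expect_equal(meanAALength(p2), 500)
  p3 <- ProteinPanel("c", "target",
                     c(x = strrep("M", 100), y = strrep("K", 200),
                       z = strrep("V", 301)))
  expect_equal(meanAALength(p3), (100 + 200 + 301) / 3)
  p3r <- ProteinPanel("c", "target",
                      c(z = strrep("V", 301), x = strrep("M", 100),
                        y = strrep("K", 200)))
  expect_equal(meanAALength(p3r), meanAALength(p3))
})

test_that("panel set validation reports exactly the broken invariants", {
  expect_equal(nrow(validatePanels(tinyPanelSet())), 0L)

  noRef <- PanelSet(ProteinPanel("t", "target", c(a = "MKV")))
  rep1 <- validatePanels(noRef)
  expect_true(any(grepl("no reference", rep1$issue)))

  shared <- PanelSet(
    ProteinPanel("t", "target", c(dup = "MKV")),
    ProteinPanel("r", "reference", c(dup = "MKW")))
  rep2 <- validatePanels(shared)
  expect_true(any(grepl("'dup'", rep2$issue)))
})

test_that("write/read round-trip preserves sequences and metadata", {
  ps <- tinyPanelSet()
  d <- tempfile()
  readBack <- readPanelSet(writePanelSet(ps, d))
  expect_equal(length(readBack), length(ps))
  for (id in names(panels(ps))) {
    a <- panels(ps)[[id]]; b <- panels(readBack)[[id]]
    expect_equal(as.character(panelSequences(b)), as.character(panelSequences(a)))
    expect_equal(panelRole(b), panelRole(a))
    expect_equal(pathwayLabel(b), pathwayLabel(a))
    expect_equal(sort(unique(unlist(ecNumbers(b)))),
                 sort(unique(unlist(ecNumbers(a)))))
  }
})
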