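cfg <- siteConfig()

test_that("entry-level quality predicates report each failure by name", {
  good <- parsePDB(generateBound(fixtureSpec(seed = 51),
                                 file.path(tempdir(), "db-good.pdb"))$path)
  expect_true(rulesOfFive(good, cfg)$pass)

  nmr <- parsePDB(generateBound(fixtureSpec(seed = 52, defects = "nmr"),
                                file.path(tempdir(), "db-nmr.pdb"))$path)
  r <- rulesOfFive(nmr, cfg)
  expect_false(r$pass)
  expect_true("method" %in% r$reasons)
  expect_true("resolution" %in% r$reasons)  # NMR carries no resolution

  hires <- parsePDB(generateBound(
    fixtureSpec(seed = 53, defects = "high_resolution"),
    file.path(tempdir(), "db-hires.pdb"))$path)
  expect_equal(rulesOfFive(hires, cfg)$reasons, "resolution")

  masked <- parsePDB(generateBound(
    fixtureSpec(seed = 54, defects = "modres_mask"),
    file.path(tempdir(), "db-mask.pdb"))$path)
  expect_equal(rulesOfFive(masked, cfg)$reasons, "free ligand")
})

test_that("entries with nucleic-acid chains fail the polymer predicate", {
  s <- parsePDB(generateBound(fixtureSpec(seed = 55),
                              file.path(tempdir(), "db-dna.pdb"))$path)
  dna <- atoms(s)[atoms(s)$record == "ATOM", ][1:8, ]
  dna$resName <- "DA"; dna$chainId <- "C"; dna$resSeq <- 1:8
  s2 <- new("PDBStructure", entryId = s@entryId, method = s@method,
            resolution = s@resolution,
            polymerTypes = c("protein", "DNA"),
            atoms = rbind(atoms(s), dna), seqres = list(),
            het = s@het, modres = s@modres)
  expect_true("polymer type" %in% rulesOfFive(s2, cfg)$reasons)
})

test_that("complex stability accepts pocket ligands and rejects grazers", {
  fx <- generateBound(fixtureSpec(seed = 56),
                      file.path(tempdir(), "db-stab.pdb"))
  s <- parsePDB(fx$path)
  ch <- splitChains(s)[["A"]]
  lig <- extractLigands(s)[[1]]
  expect_true(stabilityOfComplex(ch, lig, cfg))

  bad <- generateBound(fixtureSpec(seed = 57, defects = "unstable_ligand"),
                       file.path(tempdir(), "db-unstab.pdb"))
  sb <- parsePDB(bad$path)
  expect_false(stabilityOfComplex(splitChains(sb)[["A"]],
                                  extractLigands(sb)[[1]], cfg))

  # ligand far from every residue: empty site, unstable
  far <- makeLigand(sweep(matrix(rnorm(18), 6, 3), 2, c(500, 500, 500), "+"))
  expect_false(stabilityOfComplex(ch, far, cfg))
})

test_that("database build reproduces the generator's stage truth table", {
  defs <- c("", "", "nmr", "small_ligand", "", "unstable_ligand",
            "modres_mask", "short_chain")
  corpus <- generateCorpus(file.path(tempdir(), "db-corpus"), nFamilies = 2,
                           perFamily = 4, seed = 61, defects = defs)
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  expect_equal(db@manifest$stage_counts, corpus$expectedStageCounts)
  counts <- unlist(db@manifest$stage_counts)
  expect_true(all(diff(counts[-1]) <= 0))  # chain-level cascade is monotone
  # every admitted ligand re-checks against both gates
  for (e in dbEntries(db)) {
    for (l in e@ligands) {
      expect_gte(atomCount(l), cfg$minLigandAtoms)
      expect_true(stabilityOfComplex(e@chain, l, cfg))
    }
  }
})

test_that("empty input and unreadable files are handled gracefully", {
  db0 <- buildDatabase(character(), NULL, cfg)
  expect_length(dbEntries(db0), 0)
  expect_equal(unname(unlist(db0@manifest$stage_counts)), rep(0L, 4))
  junk <- file.path(tempdir(), "junk.pdb")
  writeLines("this is not a pdb", junk)
  fx <- generateBound(fixtureSpec(seed = 62),
                      file.path(tempdir(), "db-ok.pdb"))
  db1 <- buildDatabase(c(junk, fx$path), NULL, cfg)
  expect_length(dbEntries(db1), 1)
  expect_length(db1@manifest$skipped, 1)
})

test_that("homology mapping lookup is exact, case-insensitive, first-wins", {
  p <- file.path(tempdir(), "map.tsv")
  writeLines(c("# comment", "1abc\tA\ta.1.1.1", "1abc\tB\tb.2.1.1",
               "2xyz\tA\ta.1.1.1", "1abc\tA\tc.9.9.9"), p)
  m <- readHomologyMapping(p)
  expect_equal(lookupHomologyClass("1ABC", "A", m) |> suppressWarnings(),
               "a.1.1.1")
  expect_warning(lookupHomologyClass("1abc", "A", m), "multiple classes")
  expect_true(is.na(lookupHomologyClass("9zzz", "A", m)))
  bad <- file.path(tempdir(), "map-bad.tsv")
  writeLines(c("1abc\tA\ta.1.1.1", "oops"), bad)
  expect_error(readHomologyMapping(bad), "line 2")
})

test_that("homology index retrieval matches the mapping file", {
  corpus <- generateCorpus(file.path(tempdir(), "db-hom"), nFamilies = 3,
                           perFamily = 3, seed = 63)
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  fam2 <- queryHomologyIndex("a.2.1.1", db)
  expect_length(fam2, 3)
  expect_true(all(grepl("^2f", vapply(fam2, entryId, ""))))
  expect_length(queryHomologyIndex("z.9.9.9", db), 0)
  expect_length(queryHomologyIndex(NA_character_, db), 0)
})

test_that("length-index retrieval equals a brute-force linear scan", {
  corpus <- generateCorpus(file.path(tempdir(), "db-len"), nFamilies = 3,
                           perFamily = 4, seed = 64,
                           nResidues = c(40, 55, 70, 90, 120, 60, 45, 80,
                                         100, 65, 50, 75))
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  lens <- vapply(dbEntries(db), function(e) length(e@chain), 0L)
  set.seed(65)
  for (q in sample(20:200, 50)) {
    got <- sort(unname(vapply(queryLengthIndex(q, db, cfg), entryId, "")))
    want <- sort(unname(vapply(dbEntries(db)[abs(q - lens) / q <
                                               cfg$lengthTolerance],
                               entryId, "")))
    expect_equal(got, want)
  }
  expect_error(queryLengthIndex(0, db, cfg), "positive")
})

test_that("the 30 percent length boundary is strict", {
  mkEntry <- function(id, n) {
    new("TemplateEntry", entryId = id, chainId = "A",
        chain = makeChain(randomTrace(n, seed = 1)),
        ligands = list(makeLigand(matrix(rnorm(18), 6, 3))),
        homologyClass = NA_character_)
  }
  entries <- list(t141_A = mkEntry("t141", 141), t260_A = mkEntry("t260", 260))
  li <- data.frame(key = c("t141_A", "t260_A"), length = c(141L, 260L))
  db <- new("TemplateDB", entries = entries, homologyIndex = list(),
            lengthIndex = li[order(li$length), ], manifest = list())
  got <- vapply(queryLengthIndex(200, db, cfg), entryId, "")
  expect_equal(got, "t141")  # 29.5 % in, exactly 30 % out
})

test_that("save/load round-trips the database and builds are deterministic", {
  corpus <- generateCorpus(file.path(tempdir(), "db-rt"), nFamilies = 2,
                           perFamily = 2, seed = 66)
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  d1 <- file.path(tempdir(), "dbdir1"); d2 <- file.path(tempdir(), "dbdir2")
  saveDatabase(db, d1)
  db2 <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  saveDatabase(db2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- loadDatabase(d1)
  expect_equal(names(dbEntries(back)), names(dbEntries(db)))
  expect_equal(back@lengthIndex, db@lengthIndex)
  expect_equal(back@homologyIndex, db@homologyIndex)
  e1 <- dbEntries(db)[[1]]; e2 <- dbEntries(back)[[1]]
  expect_equal(caCoords(e2@chain), caCoords(e1@chain), tolerance = 1e-3)
  expect_equal(length(e2@ligands), length(e1@ligands))
})
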