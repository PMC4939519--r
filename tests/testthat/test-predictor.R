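cfg <- siteConfig()

mkMapped <- function(centers, tRank = seq_len(nrow(centers))) {
  lapply(seq_len(nrow(centers)), function(i)
    list(atoms = data.frame(record = "HETATM", name = "C1", resName = "LIG",
                            chainId = "A", resSeq = 201L, iCode = "",
                            x = centers[i, 1], y = centers[i, 2],
                            z = centers[i, 3], occupancy = 1, element = "C",
                            isHydrogen = FALSE),
         center = centers[i, ], source = sprintf("t%d", i),
         templateRank = tRank[i]))
}

test_that("consensus clustering reproduces the worked micro-example", {
  centers <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(10, 10, 10))
  cl <- clusterLigandCenters(mkMapped(centers), cfg)
  expect_length(cl, 2)
  # three mutually-close centers tie at count 2; lowest template rank wins
  expect_equal(cl[[1]]$center, c(0, 0, 0))
  expect_equal(cl[[1]]$support, 3L)
  expect_equal(cl[[2]]$center, c(10, 10, 10))
  expect_equal(cl[[2]]$support, 1L)
})

test_that("clustering matches the brute-force count-and-remove oracle", {
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(1:50, 1)
    centers <- matrix(runif(3 * n, 0, 20), ncol = 3)
    tRank <- sample(1:20, n, replace = TRUE)
    got <- clusterLigandCenters(mkMapped(centers, tRank),
                                siteConfig(maxSites = 3))
    want <- oracleCluster(centers, tRank, 3.0, 3)
    expect_equal(length(got), length(want))
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$center, want[[i]]$center)
      expect_equal(got[[i]]$support, want[[i]]$support)
      expect_equal(got[[i]]$electedIndex, want[[i]]$elected)
    }
  }
})

test_that("elected centers are mutually separated and support is bounded", {
  set.seed(72)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    centers <- matrix(runif(3 * n, 0, 15), ncol = 3)
    mapped <- mkMapped(centers, sample(1:5, n, replace = TRUE))
    cl <- clusterLigandCenters(mapped, cfg)
    if (length(cl) > 1) {
      cc <- do.call(rbind, lapply(cl, `[[`, "center"))
      d <- as.matrix(dist(cc))
      expect_true(all(d[upper.tri(d)] >= cfg$clusterRadius))
    }
    expect_lte(sum(vapply(cl, `[[`, 0L, "support")), n)
  }
})

test_that("bound-site detection respects the closed 8 A boundary", {
  # six-atom point ligand at the origin; residues at 8.00 and 8.05 A
  lig <- makeLigand(matrix(0, 6, 3))
  ca <- rbind(c(8, 0, 0), c(0, 8.05, 0), c(0, 0, 5))
  chain <- makeChain(ca)
  sites <- predictBound(chain, list(lig), cfg)
  expect_length(sites, 1)
  expect_setequal(siteResidues(sites[[1]]), c("A:1", "A:3"))
  # center = mean of site atoms, and the ligand lies within 4 A of it
  expect_equal(siteCenter(sites[[1]]), colMeans(ca[c(1, 3), ]))
})

test_that("multiple stable ligands rank by heavy-atom count", {
  fx <- generateBound(fixtureSpec(seed = 73),
                      file.path(tempdir(), "pr-two.pdb"))
  s <- parsePDB(fx$path)
  ch <- splitChains(s)[["A"]]
  big <- extractLigands(s)[[1]]                      # 8 atoms, in pocket
  small <- makeLigand(coordsOf(big)[1:6, ] + 0.1, compId = "LG2",
                      resSeq = 202L)                 # 6 atoms, same pocket
  sites <- predictBound(ch, list(small, big), cfg)
  expect_length(sites, 2)
  expect_equal(sites[[1]]@rank, 1L)
  # rank 1 must come from the 8-atom ligand
  expect_equal(siteCenter(sites[[1]]),
               siteCenter(predictBound(ch, list(big), cfg)[[1]]))
})

test_that("ligand mapping transforms template ligands into the query frame", {
  entry <- new("TemplateEntry", entryId = "tmpl", chainId = "A",
               chain = makeChain(randomTrace(20, seed = 74)),
               ligands = list(makeLigand(matrix(rnorm(18), 6, 3)),
                              makeLigand(matrix(rnorm(18), 6, 3),
                                         resSeq = 202L)),
               homologyClass = NA_character_)
  tr <- rigidTransform(randomRotationMatrix(), c(1, 2, 3))
  aln <- new("AlignmentResult", pairs = cbind(1:8, 1:8), transform = tr,
             rmsd = 0, score = 1)
  selected <- list(list(entry = entry, alignment = aln),
                   list(entry = entry, alignment = aln),
                   list(entry = entry, alignment = aln))
  mapped <- mapLigands(selected, cfg)
  expect_length(mapped, 6)                     # 3 templates x 2 ligands
  handRotated <- applyTransform(tr, rbind(geometricCenter(
    entry@ligands[[1]])))[1, ]
  expect_equal(mapped[[1]]$center, unname(handRotated), tolerance = 1e-9)
  expect_equal(mapped[[1]]$center,
               unname(geometricCenter(mapped[[1]]$atoms)), tolerance = 1e-9)
  # identity alignment leaves coordinates unchanged
  selId <- list(list(entry = entry, alignment = new(
    "AlignmentResult", pairs = cbind(1:8, 1:8),
    transform = rigidTransform(), rmsd = 0, score = 1)))
  expect_equal(mapLigands(selId, cfg)[[1]]$atoms$x,
               atoms(entry@ligands[[1]])$x)
})

test_that("routing separates stable-bound, homology and length-index queries", {
  corpus <- generateCorpus(file.path(tempdir(), "pr-route"), nFamilies = 2,
                           perFamily = 3, seed = 75)
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  mapping <- readHomologyMapping(corpus$mappingPath)

  s <- parsePDB(corpus$paths[1])
  ch <- splitChains(s)[["A"]]
  ligs <- extractLigands(s, cfg$minLigandAtoms)
  expect_equal(routeChain(ch, ligs, db, s@entryId, mapping, cfg)$route,
               "part1")

  # unstable bound chain with a mapped class: ligand stripped, homology route
  bad <- generateBound(fixtureSpec(seed = 999, foldFamily = 1,
                                   defects = "unstable_ligand"),
                       file.path(tempdir(), "pr-unstable.pdb"),
                       entryId = "q901")
  sb <- parsePDB(bad$path)
  chb <- splitChains(sb)[["A"]]
  ligb <- extractLigands(sb, cfg$minLigandAtoms)
  mapping2 <- rbind(mapping, data.frame(entryId = "q901", chainId = "A",
                                        class = "a.1.1.1"))
  rt <- routeChain(chb, ligb, db, "q901", mapping2, cfg)
  expect_equal(rt$route, "part2")
  expect_length(rt$candidates, 3)

  # unmapped chain falls to the length index
  rt3 <- routeChain(chb, ligb, db, "q901", mapping, cfg)
  expect_equal(rt3$route, "part3")
  expect_gt(length(rt3$candidates), 0)
})

test_that("end-to-end prediction recovers the pocket of an unbound query", {
  corpus <- generateCorpus(file.path(tempdir(), "pr-e2e"), nFamilies = 2,
                           perFamily = 3, seed = 76)
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  mapping <- readHomologyMapping(corpus$mappingPath)
  ub <- deriveUnbound(corpus$paths[4], file.path(tempdir(), "pr-q.pdb"),
                      seed = 77, noiseSigma = 0.2, newEntryId = "q902",
                      truth = corpus$truths[["2f01"]])
  mapping <- rbind(mapping, data.frame(entryId = "q902", chainId = "A",
                                       class = "a.2.1.1"))
  pred <- predictSites(parsePDB(ub$path), db, mapping, cfg)[["A"]]
  expect_equal(pred$status, "ok")
  expect_equal(pred$route, "part2")
  expect_gte(length(pred$sites), 1)
  expect_lte(minDistance(siteCenter(pred$sites[[1]]),
                         coordsOf(ub$truth$trueLigand)), 4)
  expect_equal(pred$sites[[1]]@mode, "unbound")
  # site residues all lie within 10 A of the elected mapped ligand
  expect_gt(length(siteResidues(pred$sites[[1]])), 0)
})

test_that("prediction is equivariant under rigid motion of the query", {
  corpus <- generateCorpus(file.path(tempdir(), "pr-eq"), nFamilies = 1,
                           perFamily = 3, seed = 78)
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  ub1 <- deriveUnbound(corpus$paths[2], file.path(tempdir(), "pr-eq1.pdb"),
                       seed = 79, noiseSigma = 0, newEntryId = "q903")
  p1 <- predictSites(parsePDB(ub1$path), db, NULL, cfg)[["A"]]
  # move the already-written query once more
  ub2 <- deriveUnbound(ub1$path, file.path(tempdir(), "pr-eq2.pdb"),
                       seed = 80, noiseSigma = 0, newEntryId = "q904")
  p2 <- predictSites(parsePDB(ub2$path), db, NULL, cfg)[["A"]]
  expect_equal(length(p1$sites), length(p2$sites))
  for (i in seq_along(p1$sites)) {
    moved <- applyTransform(ub2$transform,
                            rbind(siteCenter(p1$sites[[i]])))[1, ]
    expect_equal(unname(siteCenter(p2$sites[[i]])), unname(moved),
                 tolerance = 2e-3)  # PDB coordinate precision
  }
})

test_that("a tiny ligand-free chain yields a no_template status, no crash", {
  fx <- generateBound(fixtureSpec(seed = 81, nResidues = 10),
                      file.path(tempdir(), "pr-tiny-b.pdb"))
  ub <- deriveUnbound(fx$path, file.path(tempdir(), "pr-tiny.pdb"),
                      seed = 82, newEntryId = "q905")
  corpus <- generateCorpus(file.path(tempdir(), "pr-tinydb"), 1, 2,
                           seed = 83)
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  pred <- predictSites(parsePDB(ub$path), db, NULL, cfg)[["A"]]
  expect_equal(pred$status, "no_template")
  expect_length(pred$sites, 0)
})
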