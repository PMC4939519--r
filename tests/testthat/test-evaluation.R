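cfg <- siteConfig()

test_that("center-hit criterion is a closed 4 A bound on the nearest atom", {
  lig <- makeLigand(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                          c(1, 1, 0), c(0, 1, 1)))
  expect_true(siteHit(c(0, 0, 0), lig))
  expect_true(siteHit(c(6, 0, 0), lig))     # 4.0 from (2,0,0): closed bound
  expect_false(siteHit(c(6.2, 0, 0), lig))  # 4.2 away: miss
  set.seed(91)
  for (rep in 1:20) {
    ctr <- rnorm(3, sd = 4)
    brute <- min(apply(coordsOf(lig), 1,
                       function(a) sqrt(sum((a - ctr)^2)))) <= 4
    expect_equal(siteHit(ctr, lig), brute)
  }
})

test_that("center-hit is invariant under joint rigid motion", {
  lig <- makeLigand(matrix(rnorm(18), 6, 3))
  ctr <- c(1, 2, 2.5)
  tr <- rigidTransform(randomRotationMatrix(), c(10, -4, 3))
  expect_equal(siteHit(ctr, lig),
               siteHit(applyTransform(tr, rbind(ctr))[1, ],
                       applyTransform(tr, lig)))
})

test_that("top-k success is monotone in k and fails on empty predictions", {
  lig <- makeLigand(matrix(0, 6, 3))
  mkSite <- function(rank, center)
    new("BindingSite", rank = as.integer(rank), center = center,
        support = 1L, residues = character(), mode = "unbound")
  sites <- list(mkSite(1, c(50, 0, 0)), mkSite(2, c(60, 0, 0)),
                mkSite(3, c(1, 0, 0)))
  expect_false(topkSuccess(sites, list(lig), 1))
  expect_true(topkSuccess(sites, list(lig), 3))
  for (k in 1:3)
    expect_true(topkSuccess(sites, list(lig), k) <=
                  topkSuccess(sites, list(lig), k + 1))
  expect_false(topkSuccess(list(), list(lig), 3))
  top1hit <- list(mkSite(1, c(0, 0, 0)))
  expect_true(topkSuccess(top1hit, list(lig), 1))
  expect_true(topkSuccess(top1hit, list(lig), 3))
})

test_that("residue partition equals brute-force set arithmetic", {
  fx <- generateBound(fixtureSpec(seed = 92),
                      file.path(tempdir(), "ev-part.pdb"))
  s <- parsePDB(fx$path)
  ch <- splitChains(s)[["A"]]
  lig <- extractLigands(s)[[1]]
  expSite <- oracleExpSite(ch, coordsOf(lig), cfg$boundSiteRadius)
  universe <- paste0("A:", ch@residueIds)
  set.seed(93)
  for (rep in 1:10) {
    pred <- sample(universe, sample(0:40, 1))
    got <- residuePartition(ch, pred, list(lig), cfg)
    expect_equal(got[["tp"]], length(intersect(pred, expSite)))
    expect_equal(got[["fp"]], length(setdiff(pred, expSite)))
    expect_equal(got[["fn"]], length(setdiff(expSite, pred)))
    expect_equal(sum(got), length(ch))
  }
  perfect <- residuePartition(ch, expSite, list(lig), cfg)
  expect_equal(perfect[["fp"]], 0L)
  expect_equal(perfect[["fn"]], 0L)
  empty <- residuePartition(ch, character(), list(lig), cfg)
  expect_equal(empty[["tp"]], 0L)
  expect_equal(empty[["fn"]], length(expSite))
})

test_that("MCC matches direct arithmetic, its range and its symmetry", {
  expect_equal(computeMCC(c(tp = 10, tn = 90, fp = 0, fn = 0)), 1)
  expect_equal(computeMCC(c(tp = 0, tn = 0, fp = 10, fn = 90)), -1)
  expect_equal(computeMCC(c(tp = 8, tn = 80, fp = 2, fn = 10)),
               620 / sqrt(10 * 18 * 82 * 90), tolerance = 1e-12)
  expect_equal(computeMCC(c(tp = 0, tn = 50, fp = 0, fn = 0)), 0)
  expect_error(computeMCC(c(tp = -1, tn = 1, fp = 1, fn = 1)), "negative")
  set.seed(94)
  for (rep in 1:200) {
    cts <- setNames(as.list(sample(0:30, 4, replace = TRUE)),
                    c("tp", "tn", "fp", "fn"))
    v <- computeMCC(cts)
    expect_gte(v, -1); expect_lte(v, 1)
    swapped <- list(tp = cts$tn, tn = cts$tp, fp = cts$fn, fn = cts$fp)
    expect_equal(computeMCC(swapped), v, tolerance = 1e-12)
  }
})

test_that("stable bound queries score a hit with MCC 1 by convention", {
  corpus <- generateCorpus(file.path(tempdir(), "ev-bound"), nFamilies = 1,
                           perFamily = 3, seed = 95)
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  queries <- lapply(corpus$paths, function(p) {
    s <- parsePDB(p)
    list(structure = s, truthLigands = extractLigands(s), mode = "bound")
  })
  res <- evaluateDataset(queries, db, NULL, cfg)
  expect_equal(res$top1Rate, 1.0)
  expect_equal(res$top3Rate, 1.0)
  expect_equal(res$meanMCC, 1.0)
  expect_true(all(res$perQuery$route == "part1"))
})

test_that("mixed suites aggregate hits, misses and exclusions correctly", {
  corpus <- generateCorpus(file.path(tempdir(), "ev-mix"), nFamilies = 2,
                           perFamily = 3, seed = 96)
  db <- buildDatabase(corpus$paths, corpus$mappingPath, cfg)
  mapping <- readHomologyMapping(corpus$mappingPath)
  sBound <- parsePDB(corpus$paths[1])
  ub <- deriveUnbound(corpus$paths[4], file.path(tempdir(), "ev-ub.pdb"),
                      seed = 97, noiseSigma = 0.2, newEntryId = "q801",
                      truth = corpus$truths[["2f01"]])
  mapping <- rbind(mapping, data.frame(entryId = "q801", chainId = "A",
                                       class = "a.2.1.1"))
  # an engineered miss: a tiny foreign chain no template can serve
  lone <- generateBound(fixtureSpec(seed = 98, nResidues = 12,
                                    foldFamily = 9),
                        file.path(tempdir(), "ev-lone-b.pdb"))
  ubLone <- deriveUnbound(lone$path, file.path(tempdir(), "ev-lone.pdb"),
                          seed = 99, newEntryId = "q802",
                          truth = lone$truth)
  queries <- list(
    list(structure = sBound, truthLigands = extractLigands(sBound),
         mode = "bound"),
    list(structure = parsePDB(ub$path),
         truthLigands = list(ub$truth$trueLigand), mode = "unbound"),
    list(structure = parsePDB(ubLone$path),
         truthLigands = list(ubLone$truth$trueLigand), mode = "unbound"),
    list(structure = sBound, truthLigands = list(), mode = "bound"))
  res <- evaluateDataset(queries, db, mapping, cfg)
  expect_equal(nrow(res$perQuery), 3)      # the truthless query is excluded
  expect_length(res$excluded, 1)
  expect_equal(res$perQuery$top1, c(TRUE, TRUE, FALSE))
  expect_equal(res$top1Rate, 2 / 3, tolerance = 1e-12)
  expect_equal(res$perQuery$mcc[1], 1)
  expect_gt(res$perQuery$mcc[2], 0)        # recovered pocket overlaps truth
  expect_equal(res$perQuery$mcc[3], 0)     # no prediction at all
})
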