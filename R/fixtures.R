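# Deterministic synthetic-structure generator.  Backbones are parametric
# CA (+ pseudo side-chain centroid) traces with 3.8 Angstrom CA spacing: a
# spherical-spiral "cage" of residues around a pocket center, plus a
# family-specific smooth random tail.  A ligand of known geometry sits at the
# pocket center, so the complex-stability gate holds by construction unless a
# defect deliberately violates it.  No physical force field: the method under
# test needs geometry, not chemistry.

FIXTURE_DEFECTS <- c("nmr", "high_resolution", "small_ligand",
                     "unstable_ligand", "modres_mask", "short_chain")

# evaluate expr with a private RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.unit <- function(v) v / sqrt(sum(v^2))

# 12 icosahedron vertex directions for ligand atom placement
.ICOS <- local({
  p <- (1 + sqrt(5)) / 2
  m <- rbind(c(0, 1, p), c(0, -1, p), c(0, 1, -p), c(0, -1, -p),
             c(1, p, 0), c(-1, p, 0), c(1, -p, 0), c(-1, -p, 0),
             c(p, 0, 1), c(-p, 0, 1), c(p, 0, -1), c(-p, 0, -1))
  m / sqrt(rowSums(m^2))
})

#' Specification of one synthetic bound structure
#'
#' @param seed integer seed; every coordinate of the output is a
#'   deterministic function of the spec.
#' @param nResidues residue count of the main chain (>= 10; the pocket cage
#'   uses min(28, nResidues - 2) residues, the rest form the tail).
#' @param foldFamily integer family label; family members share backbone
#'   shape parameters and are structurally alignable, different families are
#'   not.
#' @param pocketRadius radius (Angstrom) of the residue cage around the
#'   ligand.
#' @param ligandAtoms heavy-atom count of the ligand (default 8; the
#'   "small_ligand" defect overrides this to 5).
#' @param familyVariant non-negative integer reshaping the family; used by
#'   [generateCorpus()] to respace families whose backbones come out too
#'   similar.
#' @param defects character vector of deliberate failures:
#'   "nmr" (EXPDTA SOLUTION NMR, no resolution), "high_resolution" (3.5
#'   Angstrom), "small_ligand" (5 heavy atoms), "unstable_ligand" (ligand
#'   grazing the tail, violating the stability gate), "modres_mask" (the HET
#'   component also listed in MODRES, so it is not a free ligand),
#'   "short_chain" (an extra 12-residue chain B, removed by the length
#'   filter).
#' @return a list of class \code{"FixtureSpec"}.
#' @export
fixtureSpec <- function(seed, nResidues = 60, foldFamily = 1L,
                        pocketRadius = 8, ligandAtoms = 8,
                        familyVariant = 0L, defects = character()) {
  if (nResidues < 10) stop("fixtureSpec: nResidues must be >= 10")
  if (ligandAtoms < 1) stop("fixtureSpec: ligandAtoms must be >= 1")
  unknown <- setdiff(defects, FIXTURE_DEFECTS)
  if (length(unknown))
    stop("fixtureSpec: unknown defect(s): ", paste(unknown, collapse = ", "))
  if (all(c("nmr", "high_resolution") %in% defects))
    stop("fixtureSpec: contradictory defects 'nmr' and 'high_resolution'",
         " (an NMR entry has no diffraction resolution)")
  structure(list(seed = as.integer(seed), nResidues = as.integer(nResidues),
                 foldFamily = as.integer(foldFamily),
                 pocketRadius = pocketRadius,
                 ligandAtoms = as.integer(ligandAtoms),
                 familyVariant = as.integer(familyVariant),
                 defects = defects),
            class = "FixtureSpec")
}

# family-level shape parameters and perturbation table (deterministic per
# family label)
.familyParams <- function(foldFamily, variant = 0L, maxResidues = 400) {
  .withSeed(7919L + 137L * as.integer(foldFamily) +
              104729L * as.integer(variant), {
    list(sphereRadius = runif(1, 7.6, 9.4),
         phi0 = runif(1, 0.28, 0.42),
         handedness = sample(c(-1, 1), 1),
         bend = runif(1, 0.35, 0.55),
         tailKicks = matrix(runif(3 * maxResidues, -1, 1),
                            ncol = 3),
         aaNames = sample(names(AA3), maxResidues, replace = TRUE))
  })
}

# canonical-frame CA trace: cage around the origin + outward tail
.backboneCA <- function(fam, nResidues, pocketRadius) {
  m <- min(28L, nResidues - 2L)
  R <- pocketRadius
  phi <- seq(fam$phi0, pi - fam$phi0, length.out = m)
  dphi <- phi[2] - phi[1]
  psi <- numeric(m)
  for (i in 2:m) {
    step <- sqrt(max((3.8 / R)^2 - dphi^2, 0.02)) /
      sin((phi[i] + phi[i - 1]) / 2)
    psi[i] <- psi[i - 1] + fam$handedness * step
  }
  cage <- R * cbind(sin(phi) * cos(psi), sin(phi) * sin(psi), cos(phi))
  nTail <- nResidues - m
  if (nTail > 0) {
    pos <- cage[m, ]
    dir <- .unit(pos)
    tail <- matrix(0, nTail, 3)
    for (k in seq_len(nTail)) {
      dir <- .unit(dir + fam$bend * fam$tailKicks[k, ] + 0.15 * .unit(pos))
      pos <- pos + 3.8 * dir
      tail[k, ] <- pos
    }
    rbind(cage, tail)
  } else cage
}

# pseudo side-chain centroid: 1.5 Angstrom along the local convexity
# direction (points away from the pocket for cage residues)
.cbFromCA <- function(ca) {
  n <- nrow(ca)
  cb <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- ca[c(max(1, i - 1), min(n, i + 1)), , drop = FALSE]
    v <- ca[i, ] - colMeans(nb)
    if (sum(v^2) < 1e-8) v <- ca[i, ]
    cb[i, ] <- ca[i, ] + 1.5 * .unit(v)
  }
  cb
}

.ligandAtoms <- function(center, k) {
  dirs <- rbind(.ICOS, 1.6 * .ICOS)  # second shell for k > 12
  sweep(1.4 * dirs[seq_len(k), , drop = FALSE], 2, center, "+")
}

.polymerAtomTable <- function(ca, cb, resNames, chainId, startRes = 1L) {
  n <- nrow(ca)
  data.frame(
    record = "ATOM",
    name = rep(c("CA", "CB"), n),
    resName = rep(resNames, each = 2),
    chainId = chainId,
    resSeq = rep(startRes - 1L + seq_len(n), each = 2),
    iCode = "",
    x = as.numeric(t(cbind(ca[, 1], cb[, 1]))),
    y = as.numeric(t(cbind(ca[, 2], cb[, 2]))),
    z = as.numeric(t(cbind(ca[, 3], cb[, 3]))),
    occupancy = 1, element = "C", isHydrogen = FALSE,
    stringsAsFactors = FALSE)
}

.hetAtomTable <- function(coords, compId, chainId, resSeq, elements, names) {
  data.frame(record = "HETATM", name = names, resName = compId,
             chainId = chainId, resSeq = resSeq, iCode = "",
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occupancy = 1, element = elements,
             isHydrogen = elements %in% c("H", "D"),
             stringsAsFactors = FALSE)
}

#' Generate one synthetic bound structure
#'
#' Builds the canonical-frame model (cage + tail backbone, ligand, two waters,
#' one ligand hydrogen to exercise heavy-atom counting), applies member-level
#' coordinate noise (sigma 0.15 Angstrom) and a seeded rigid motion, writes a
#' valid PDB file (HEADER, EXPDTA, REMARK 2, SEQRES, HET, MODRES, ATOM,
#' HETATM) and returns the ground truth.  Output is byte-identical for
#' identical specs.
#'
#' @param spec a [fixtureSpec()].
#' @param path output PDB path.
#' @param entryId four-character entry identifier (default derived from the
#'   seed).
#' @return list with \code{path}, \code{entryId} and \code{truth}: the true
#'   [Ligand-class], \code{center}, \code{siteResidues} (residues within the
#'   8-Angstrom bound-site radius of the ligand, re-derived from the written
#'   coordinates) and \code{expectedStagePass} flags for the four database
#'   filters.
#' @export
generateBound <- function(spec, path,
                          entryId = sprintf("s%03d", spec$seed %% 1000)) {
  stopifnot(inherits(spec, "FixtureSpec"))
  fam <- .familyParams(spec$foldFamily, spec$familyVariant)
  defects <- spec$defects
  nLig <- if ("small_ligand" %in% defects) 5L else spec$ligandAtoms

  .withSeed(spec$seed, {
    ca <- .backboneCA(fam, spec$nResidues, spec$pocketRadius)
    ca <- ca + matrix(rnorm(length(ca), sd = 0.15), ncol = 3)
    cb <- .cbFromCA(ca)
    resNames <- fam$aaNames[seq_len(spec$nResidues)]
    poly <- .polymerAtomTable(ca, cb, resNames, "A")

    ligCenter <- c(0, 0, 0)
    if ("unstable_ligand" %in% defects) {
      # graze the tail: site residues all on one side, site center far away
      tailEnd <- ca[nrow(ca), ]
      v <- .unit(tailEnd)
      for (d in seq(7, 14, by = 1)) {
        ligCenter <- tailEnd + d * v
        lig <- .ligandAtoms(ligCenter, nLig)
        chain <- new("ChainRecord", chainId = "A", atoms = poly,
                     residueIds = as.character(seq_len(spec$nResidues)),
                     sequence = paste(AA3[resNames], collapse = ""))
        if (!stabilityOfComplex(chain, lig, siteConfig())) break
      }
    }
    lig <- .ligandAtoms(ligCenter, nLig)
    ligTab <- .hetAtomTable(lig, "LIG", "A", 201L,
                            rep(c("C", "O", "N"), length.out = nLig),
                            paste0(rep(c("C", "O", "N"),
                                       length.out = nLig), seq_len(nLig)))
    ligH <- .hetAtomTable(matrix(ligCenter + c(0.5, 0.5, 0.5), 1), "LIG",
                          "A", 201L, "H", "H1")
    waters <- .hetAtomTable(rbind(c(25, 25, 25), c(27, 25, 25)), "HOH", "A",
                            c(301L, 302L), c("O", "O"), c("O", "O"))

    atomsAll <- rbind(poly, ligTab, ligH, waters)
    if ("short_chain" %in% defects) {
      nB <- 12L
      caB <- cbind(40 + 3.8 * (seq_len(nB) - 1), 40, 40)
      cbB <- .cbFromCA(caB)
      atomsAll <- rbind(atomsAll,
                        .polymerAtomTable(caB, cbB,
                                          fam$aaNames[30 + seq_len(nB)], "B"))
    }

    # seeded member rigid motion of the whole model
    tr <- rigidTransform(.randomRotation(), runif(3, -15, 15))
    atomsAll <- applyTransform(tr, atomsAll)

    het <- data.frame(compId = c("LIG", "HOH", "HOH"), chainId = "A",
                      resSeq = c(201L, 301L, 302L), iCode = "",
                      stringsAsFactors = FALSE)
    modres <- if ("modres_mask" %in% defects)
      data.frame(compId = "LIG", chainId = "A", resSeq = 201L, iCode = "",
                 stringsAsFactors = FALSE) else NULL
    method <- if ("nmr" %in% defects) "SOLUTION NMR" else "X-RAY DIFFRACTION"
    resolution <- if ("nmr" %in% defects) NA_real_ else
      if ("high_resolution" %in% defects) 3.5 else 2.0

    writePDBFile(path, atomsAll, entryId = entryId, method = method,
                 resolution = resolution, het = het, modres = modres)

    # ground truth, re-derived from the written (PDB-precision) coordinates
    s <- parsePDB(path)
    chainA <- splitChains(s)[["A"]]
    ligRows <- s@atoms[s@atoms$record == "HETATM" &
                         s@atoms$resName == "LIG" & !s@atoms$isHydrogen, ]
    trueLigand <- new("Ligand", compId = "LIG", chainId = "A",
                      resSeq = 201L, iCode = "", atoms = ligRows)
    expected <- list(
      rules_of_five = !any(c("nmr", "high_resolution", "modres_mask")
                           %in% defects),
      chain_length = TRUE,
      ligand_atoms = !any(c("small_ligand", "modres_mask") %in% defects),
      stability = !any(c("small_ligand", "modres_mask", "unstable_ligand")
                       %in% defects))
    list(path = path, entryId = entryId,
         truth = list(trueLigand = trueLigand,
                      center = as.numeric(geometricCenter(trueLigand)),
                      siteResidues = .residuesNear(chainA,
                                                   coordsOf(trueLigand),
                                                   8),
                      expectedStagePass = expected))
  })
}

#' Derive an unbound query from a bound fixture
#'
#' Removes every HET group (and the HET/MODRES bookkeeping), applies a seeded
#' random rigid motion and optional Gaussian coordinate noise to the polymer
#' atoms, and writes the result.  The supplied ground truth is transported
#' through the same rigid motion (noise is never applied to the truth).
#'
#' @param boundPath path of the bound fixture.
#' @param path output PDB path.
#' @param seed integer seed for the rigid motion and the noise.
#' @param noiseSigma per-coordinate Gaussian noise (Angstrom, default 0).
#' @param newEntryId entry identifier for the unbound copy.
#' @param truth the \code{truth} element returned by [generateBound()], or
#'   NULL.
#' @return list with \code{path}, \code{entryId}, \code{transform} and the
#'   transported \code{truth} (NULL if none given).
#' @export
deriveUnbound <- function(boundPath, path, seed, noiseSigma = 0,
                          newEntryId = "QRY1", truth = NULL) {
  s <- parsePDB(boundPath)
  .withSeed(seed, {
    tr <- rigidTransform(.randomRotation(), runif(3, -20, 20))
    poly <- s@atoms[s@atoms$record == "ATOM", , drop = FALSE]
    poly <- applyTransform(tr, poly)
    if (noiseSigma > 0) {
      poly$x <- poly$x + rnorm(nrow(poly), sd = noiseSigma)
      poly$y <- poly$y + rnorm(nrow(poly), sd = noiseSigma)
      poly$z <- poly$z + rnorm(nrow(poly), sd = noiseSigma)
    }
    writePDBFile(path, poly, entryId = newEntryId, method = s@method,
                 resolution = s@resolution)
    newTruth <- NULL
    if (!is.null(truth)) {
      newTruth <- truth
      newTruth$trueLigand <- applyTransform(tr, truth$trueLigand)
      newTruth$center <- as.numeric(
        applyTransform(tr, matrix(truth$center, 1)))
    }
    list(path = path, entryId = newEntryId, transform = tr,
         truth = newTruth)
  })
}

#' Generate a template corpus with a homology mapping and a truth table
#'
#' Writes \code{nFamilies * perFamily} bound fixtures (one file per entry)
#' into \code{dir}, a mapping file assigning one classification string per
#' family, and returns the per-entry truth table with expected filter-stage
#' outcomes and the expected database stage counts.  Members of a family
#' share fold parameters (and are therefore alignable); families differ.
#'
#' @param dir output directory (created).
#' @param nFamilies,perFamily corpus shape (>= 1 each).
#' @param seed integer seed.
#' @param defects character vector of defect labels (one per member, recycled;
#'   "" for none), assigned in member order.
#' @param nResidues main-chain length, one value per member (recycled).
#' @return list with \code{paths}, \code{mappingPath}, \code{truth} (one row
#'   per entry: entryId, family, class, defect, per-stage pass flags),
#'   \code{truths} (per-entry ground-truth lists, named by entry id),
#'   \code{expectedStageCounts} and \code{dir}.
#' @export
generateCorpus <- function(dir, nFamilies = 3, perFamily = 4, seed = 1,
                           defects = "", nResidues = 60) {
  stopifnot(nFamilies >= 1, perFamily >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nFamilies * perFamily
  defects <- rep_len(defects, n)
  nResidues <- rep_len(nResidues, n)

  # space the families: bump a family's variant until its clean backbone
  # scores below 0.29 against every already-accepted family
  variants <- integer(nFamilies)
  reps <- list()
  for (f in seq_len(nFamilies)) {
    nRes <- nResidues[(f - 1) * perFamily + 1]
    for (v in 0:19) {
      ca <- .backboneCA(.familyParams(f, v), nRes, 8)
      rep <- new("ChainRecord", chainId = "A",
                 atoms = data.frame(record = "ATOM", name = "CA",
                                    resName = "ALA", chainId = "A",
                                    resSeq = seq_len(nRes), iCode = "",
                                    x = ca[, 1], y = ca[, 2], z = ca[, 3],
                                    occupancy = 1, element = "C",
                                    isHydrogen = FALSE,
                                    stringsAsFactors = FALSE),
                 residueIds = as.character(seq_len(nRes)),
                 sequence = paste(rep("A", nRes), collapse = ""))
      sep <- all(vapply(reps, function(r)
        alignChains(rep, r)@score < 0.29, logical(1)))
      if (sep) { variants[f] <- v; reps[[f]] <- rep; break }
      if (v == 19)
        stop("generateCorpus: could not space family ", f,
             " from the previous families")
    }
  }

  rows <- list(); paths <- character(); truths <- list()
  mapLines <- c("# entry chain class")
  i <- 0
  for (f in seq_len(nFamilies)) {
    cls <- sprintf("a.%d.1.1", f)
    for (m in seq_len(perFamily)) {
      i <- i + 1
      id <- sprintf("%df%02d", f, m)
      def <- if (nzchar(defects[i])) strsplit(defects[i], ",")[[1]] else
        character()
      spec <- fixtureSpec(seed = seed * 1000L + i, nResidues = nResidues[i],
                          foldFamily = f, familyVariant = variants[f],
                          defects = def)
      fx <- generateBound(spec, file.path(dir, paste0(id, ".pdb")),
                          entryId = id)
      paths <- c(paths, fx$path)
      truths[[id]] <- fx$truth
      mapLines <- c(mapLines, paste(id, "A", cls, sep = "\t"))
      ep <- fx$truth$expectedStagePass
      rows[[i]] <- data.frame(
        entryId = id, family = f, class = cls,
        defect = defects[i],
        rules_of_five = ep$rules_of_five,
        chain_length = ep$chain_length,
        ligand_atoms = ep$ligand_atoms,
        stability = ep$stability,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  mappingPath <- file.path(dir, "mapping.tsv")
  writeLines(mapLines, mappingPath)
  expected <- list(
    entries_rules_of_five = sum(truth$rules_of_five),
    chains_length = sum(truth$rules_of_five & truth$chain_length),
    chains_with_ligand = sum(truth$rules_of_five & truth$chain_length &
                               truth$ligand_atoms),
    chains_stable = sum(truth$rules_of_five & truth$chain_length &
                          truth$ligand_atoms & truth$stability))
  list(paths = paths, mappingPath = mappingPath, truth = truth,
       truths = truths, expectedStageCounts = expected, dir = dir)
}
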