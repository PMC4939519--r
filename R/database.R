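# Bound-template database: the four-stage entry/chain filter cascade, the
# complex-stability gate, the homology and chain-length indexes, and an
# inspectable on-disk representation (JSON manifest + per-entry PDB + TSV
# indexes; no binary formats).

#' Entry-level quality filter
#'
#' The five predicates an entry must satisfy to seed templates: protein-only
#' polymers (no DNA/RNA), X-ray experiment, resolution in (0, maxResolution],
#' at least one free ligand (a HET group outside MODRES that is not water —
#' the atom-count rule is applied later, at the chain stage), and at least one
#' chain longer than \code{minChainLen} residues.
#'
#' @param s a [PDBStructure-class].
#' @param cfg a [siteConfig()] list.
#' @return list with \code{pass} (flag) and \code{reasons} (character vector
#'   naming each failed predicate: "polymer type", "method", "resolution",
#'   "free ligand", "chain length").
#' @export
rulesOfFive <- function(s, cfg = siteConfig()) {
  stopifnot(is(s, "PDBStructure"))
  reasons <- character()
  if (!("protein" %in% s@polymerTypes) ||
      any(c("DNA", "RNA") %in% s@polymerTypes))
    reasons <- c(reasons, "polymer type")
  if (!grepl("X-RAY", s@method, fixed = TRUE))
    reasons <- c(reasons, "method")
  if (is.na(s@resolution) || s@resolution <= 0 ||
      s@resolution > cfg$maxResolution)
    reasons <- c(reasons, "resolution")
  free <- FALSE
  if (nrow(s@het)) {
    hk <- paste(s@het$compId, s@het$chainId, s@het$resSeq, s@het$iCode,
                sep = "|")
    mk <- paste(s@modres$compId, s@modres$chainId, s@modres$resSeq,
                s@modres$iCode, sep = "|")
    free <- any(!(s@het$compId %in% WATER_IDS) & !(hk %in% mk))
  }
  if (!free) reasons <- c(reasons, "free ligand")
  if (!any(vapply(splitChains(s), length, integer(1)) > cfg$minChainLen))
    reasons <- c(reasons, "chain length")
  list(pass = length(reasons) == 0, reasons = reasons)
}

# residue identifiers ("chain:resSeq<iCode>") of chain residues having any
# heavy atom within `radius` (closed) of any row of ligCoords
.residuesNear <- function(chain, ligCoords, radius) {
  a <- chain@atoms[!chain@atoms$isHydrogen, , drop = FALSE]
  if (nrow(a) == 0 || nrow(ligCoords) == 0) return(character())
  d <- .crossDist(cbind(a$x, a$y, a$z), ligCoords)
  near <- apply(d, 1, min) <= radius
  ids <- unique(paste0(a$resSeq, a$iCode)[near])
  # preserve chain order
  ids <- chain@residueIds[chain@residueIds %in% ids]
  if (length(ids) == 0) return(character())
  paste0(chain@chainId, ":", ids)
}

# all heavy atoms of the named residues of a chain
.residueAtoms <- function(chain, residueKeys) {
  a <- chain@atoms[!chain@atoms$isHydrogen, , drop = FALSE]
  keys <- .resKey(chain@chainId, a$resSeq, a$iCode)
  a[keys %in% residueKeys, , drop = FALSE]
}

#' Complex-stability gate
#'
#' A chain-ligand complex is stable iff the binding site computed from the
#' ligand is self-consistent: the site is all chain residues with any heavy
#' atom within \code{cfg$boundSiteRadius} (8 Angstrom) of any ligand heavy
#' atom, and some ligand atom must lie within \code{cfg$stabilityDist}
#' (4 Angstrom) of the geometric center of the site's heavy atoms.  An empty
#' site is unstable.  A ligand grazing a flat surface fails: its site lies on
#' one side so the site center falls inside the protein, far from the ligand.
#'
#' @param chain a [ChainRecord-class].
#' @param ligand a [Ligand-class] (or an atom table / coordinate matrix).
#' @param cfg a [siteConfig()] list.
#' @return TRUE iff the complex is stable.
#' @export
stabilityOfComplex <- function(chain, ligand, cfg = siteConfig()) {
  lig <- coordsOf(ligand)
  site <- .residuesNear(chain, lig, cfg$boundSiteRadius)
  if (length(site) == 0) return(FALSE)
  ctr <- geometricCenter(.residueAtoms(chain, site))
  minDistance(ctr, lig) <= cfg$stabilityDist
}

#' Read a homology-class mapping file
#'
#' Whitespace/TSV lines \code{pdb_id chain_id class_string} (a reduced
#' fold-classification dialect); \code{#} comments and blank lines ignored.
#' Malformed lines raise an error naming the line number.
#'
#' @param path path to the mapping file.
#' @return data.frame with columns \code{entryId} (lower-cased),
#'   \code{chainId}, \code{class}.
#' @export
readHomologyMapping <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("malformed mapping line ", keep[bad[1]], ": '",
         lines[keep[bad[1]]], "'")
  data.frame(entryId = tolower(vapply(fields, `[`, "", 1)),
             chainId = vapply(fields, `[`, "", 2),
             class = vapply(fields, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Look up a chain's homology class
#'
#' Exact match on (entry id, chain id), case-insensitive on the entry id.
#' When a chain is mapped more than once the first occurrence wins and a
#' warning is issued.
#'
#' @param entryId,chainId identity of the chain.
#' @param mapping data.frame from [readHomologyMapping()] (or NULL).
#' @return the classification string, or NA when unmapped.
#' @export
lookupHomologyClass <- function(entryId, chainId, mapping) {
  if (is.null(mapping)) return(NA_character_)
  hit <- which(mapping$entryId == tolower(entryId) &
                 mapping$chainId == chainId)
  if (length(hit) == 0) return(NA_character_)
  if (length(unique(mapping$class[hit])) > 1)
    warning("chain ", entryId, ":", chainId,
            " mapped to multiple classes; using the first")
  mapping$class[hit[1]]
}

#' Build the bound-template database
#'
#' Runs the four-stage filter cascade over a set of PDB files:
#' \enumerate{
#'   \item entries are filtered by [rulesOfFive()];
#'   \item surviving entries are split into chains and chains of
#'     \code{minChainLen} residues or fewer are removed;
#'   \item chains must own at least one ligand with at least
#'     \code{minLigandAtoms} heavy atoms ([extractLigands()] rules);
#'   \item each (chain, ligand) pair must pass [stabilityOfComplex()];
#'     unstable ligands are dropped, and a chain survives iff at least one of
#'     its ligands is stable.
#' }
#' Stage survivor counts are recorded in the manifest (they are non-increasing
#' at chain level by construction).  Unreadable files are logged in the
#' manifest and skipped.
#'
#' @param paths character vector of PDB file paths.
#' @param mapping homology mapping data.frame from [readHomologyMapping()],
#'   a path to such a file, or NULL (no homology index).
#' @param cfg a [siteConfig()] list.
#' @return a [TemplateDB-class].
#' @examples
#' dir <- tempfile(); corpus <- generateCorpus(dir, 2, 2, seed = 11)
#' db <- buildDatabase(corpus$paths, corpus$mappingPath)
#' db
#' @export
buildDatabase <- function(paths, mapping = NULL, cfg = siteConfig()) {
  if (is.character(mapping) && length(mapping) == 1)
    mapping <- readHomologyMapping(mapping)
  skipped <- character()
  structures <- list()
  for (p in paths) {
    s <- tryCatch(parsePDB(p), error = function(e) {
      conditionMessage(e)
    })
    if (is.character(s)) skipped <- c(skipped, paste0(p, ": ", s))
    else structures[[length(structures) + 1]] <- s
  }

  stage1 <- Filter(function(s) rulesOfFive(s, cfg)$pass, structures)

  entries <- list()
  nChainsLen <- 0L; nChainsLig <- 0L; nChainsStable <- 0L
  for (s in stage1) {
    chains <- splitChains(s)
    chains <- Filter(function(ch) length(ch) > cfg$minChainLen, chains)
    nChainsLen <- nChainsLen + length(chains)
    ligands <- extractLigands(s, cfg$minLigandAtoms)
    for (ch in chains) {
      mine <- Filter(function(l) l@chainId == ch@chainId, ligands)
      if (length(mine) == 0) next
      nChainsLig <- nChainsLig + 1L
      stable <- Filter(function(l) stabilityOfComplex(ch, l, cfg), mine)
      if (length(stable) == 0) next
      nChainsStable <- nChainsStable + 1L
      cls <- lookupHomologyClass(s@entryId, ch@chainId, mapping)
      key <- paste0(tolower(s@entryId), "_", ch@chainId)
      entries[[key]] <- new("TemplateEntry", entryId = tolower(s@entryId),
                            chainId = ch@chainId, chain = ch,
                            ligands = stable, homologyClass = cls)
    }
  }
  if (length(entries)) entries <- entries[order(names(entries))]
  .assembleDb(entries, cfg,
              stageCounts = list(entries_rules_of_five = length(stage1),
                                 chains_length = nChainsLen,
                                 chains_with_ligand = nChainsLig,
                                 chains_stable = nChainsStable),
              skipped = skipped, nInput = length(paths))
}

.assembleDb <- function(entries, cfg, stageCounts, skipped, nInput) {
  keys <- as.character(names(entries) %||% character())
  lens <- vapply(entries, function(e) length(e@chain), integer(1))
  cls <- vapply(entries, function(e) e@homologyClass, character(1))
  lengthIndex <- data.frame(key = keys, length = unname(lens),
                            stringsAsFactors = FALSE)
  lengthIndex <- lengthIndex[order(lengthIndex$length, lengthIndex$key), ,
                             drop = FALSE]
  rownames(lengthIndex) <- NULL
  homologyIndex <- split(keys[!is.na(cls)], cls[!is.na(cls)])
  new("TemplateDB", entries = entries, homologyIndex = homologyIndex,
      lengthIndex = lengthIndex,
      manifest = list(n_input = nInput, stage_counts = stageCounts,
                      config = unclass(cfg), skipped = skipped))
}

#' Query the homology index
#'
#' @param classId classification string.
#' @param db a [TemplateDB-class].
#' @return list of [TemplateEntry-class] with exactly that class (possibly
#'   empty, in which case callers fall through to the length index).
#' @export
queryHomologyIndex <- function(classId, db) {
  stopifnot(is(db, "TemplateDB"))
  if (is.na(classId)) return(list())
  keys <- db@homologyIndex[[classId]]
  if (is.null(keys)) return(list())
  unname(db@entries[keys])
}

#' Query the chain-length index
#'
#' Templates whose length differs from the query length by strictly less than
#' \code{cfg$lengthTolerance} (fraction of the query length), located by
#' binary search on the sorted length index.
#'
#' @param queryLen query chain length in residues (> 0).
#' @param db a [TemplateDB-class].
#' @param cfg a [siteConfig()] list.
#' @return list of [TemplateEntry-class].
#' @export
queryLengthIndex <- function(queryLen, db, cfg = siteConfig()) {
  stopifnot(is(db, "TemplateDB"))
  if (queryLen <= 0) stop("queryLengthIndex: query length must be positive")
  lens <- db@lengthIndex$length
  if (length(lens) == 0) return(list())
  lo <- queryLen * (1 - cfg$lengthTolerance)
  hi <- queryLen * (1 + cfg$lengthTolerance)
  # findInterval on the sorted column, then resolve the open bounds exactly
  from <- findInterval(lo, lens) + 1L   # first index with length >= lo
  to <- findInterval(hi, lens)          # last index with length <= hi
  if (from > to) return(list())
  idx <- from:to
  keep <- abs(queryLen - lens[idx]) / queryLen < cfg$lengthTolerance
  unname(db@entries[db@lengthIndex$key[idx[keep]]])
}

## persistence --------------------------------------------------------------

#' Save a template database to a directory
#'
#' Writes an inspectable, diffable store: \code{manifest.json} (stage counts,
#' configuration snapshot, per-entry metadata), \code{entries/<key>.pdb}
#' (chain plus its stable ligands), \code{homology_index.tsv} and
#' \code{length_index.tsv}.  Byte-identical for identical inputs.
#'
#' @param db a [TemplateDB-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
saveDatabase <- function(db, dir) {
  stopifnot(is(db, "TemplateDB"))
  dir.create(file.path(dir, "entries"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- lapply(db@entries, function(e) {
    list(entryId = e@entryId, chainId = e@chainId,
         length = length(e@chain),
         homologyClass = if (is.na(e@homologyClass)) NULL else
           e@homologyClass,
         nLigands = length(e@ligands))
  })
  jsonlite::write_json(c(db@manifest, list(entries = meta)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  for (key in names(db@entries)) {
    e <- db@entries[[key]]
    ligAtoms <- do.call(rbind, lapply(e@ligands, function(l) {
      a <- l@atoms
      a$record <- "HETATM"; a$resName <- l@compId
      a$chainId <- l@chainId; a$resSeq <- l@resSeq; a$iCode <- l@iCode
      a
    }))
    het <- data.frame(
      compId = vapply(e@ligands, function(l) l@compId, character(1)),
      chainId = vapply(e@ligands, function(l) l@chainId, character(1)),
      resSeq = vapply(e@ligands, function(l) l@resSeq, integer(1)),
      iCode = vapply(e@ligands, function(l) l@iCode, character(1)),
      stringsAsFactors = FALSE)
    writePDBFile(file.path(dir, "entries", paste0(key, ".pdb")),
                 rbind(e@chain@atoms, ligAtoms), entryId = e@entryId,
                 het = het)
  }
  hom <- data.frame(
    class = rep(names(db@homologyIndex), lengths(db@homologyIndex)),
    key = unlist(db@homologyIndex, use.names = FALSE))
  write.table(hom, file.path(dir, "homology_index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(db@lengthIndex, file.path(dir, "length_index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a template database from a directory
#'
#' @param dir a directory written by [saveDatabase()].
#' @return a [TemplateDB-class].
#' @export
loadDatabase <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  cfg <- do.call(siteConfig, man$config)
  entries <- list()
  for (key in names(man$entries)) {
    m <- man$entries[[key]]
    s <- parsePDB(file.path(dir, "entries", paste0(key, ".pdb")))
    ch <- splitChains(s)[[m$chainId]]
    ligs <- Filter(function(l) l@chainId == m$chainId,
                   extractLigands(s, cfg$minLigandAtoms))
    entries[[key]] <- new("TemplateEntry", entryId = m$entryId,
                          chainId = m$chainId, chain = ch, ligands = ligs,
                          homologyClass = if (is.null(m$homologyClass))
                            NA_character_ else m$homologyClass)
  }
  .assembleDb(entries, cfg,
              stageCounts = man$stage_counts,
              skipped = unlist(man$skipped) %||% character(),
              nInput = man$n_input)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
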