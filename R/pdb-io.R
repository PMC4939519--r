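# PDB-format I/O.  Coordinate and SEQRES records are read through
# bio3d::read.pdb; the header records this package needs for ligand
# identification and entry filtering (EXPDTA, REMARK 2 resolution, HET,
# MODRES) are parsed here, as is writing (bio3d cannot emit header records).

.emptyAtomTable <- function() {
  data.frame(record = character(), name = character(), resName = character(),
             chainId = character(), resSeq = integer(), iCode = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), element = character(),
             isHydrogen = logical(), stringsAsFactors = FALSE)
}

.elementFromName <- function(name) {
  e <- sub("^[0-9]*", "", name)
  substr(e, 1, 1)
}

# residue identity within a chain: author number + insertion code
.resKey <- function(chainId, resSeq, iCode) paste0(chainId, ":", resSeq, iCode)

#' Parse a PDB-format file
#'
#' Reads one PDB entry: header metadata (EXPDTA experiment method, REMARK 2
#' resolution, HET, MODRES, SEQRES) and all coordinate records.  Alternate
#' locations are resolved to the highest-occupancy conformer (ties to the
#' lowest altLoc letter); hydrogens are retained but flagged; for multi-model
#' files only the first model is kept.
#'
#' @param path path to a PDB-format text file.
#' @return a [PDBStructure-class] object.
#' @examples
#' fx <- generateBound(fixtureSpec(seed = 1), tempfile(fileext = ".pdb"))
#' s <- parsePDB(fx$path)
#' s
#' @export
parsePDB <- function(path) {
  if (!file.exists(path)) stop("parsePDB: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  if (!any(rec %in% c("ATOM  ", "HETATM")))
    stop("parsePDB: no coordinate records in '", path, "' (empty chains)")

  entryId <- basename(path)
  hdr <- lines[rec == "HEADER"]
  if (length(hdr) && nchar(hdr[1]) >= 66) {
    id <- trimws(substr(hdr[1], 63, 66))
    if (nzchar(id)) entryId <- id
  }
  method <- "UNKNOWN"
  exp <- lines[rec == "EXPDTA"]
  if (length(exp)) method <- trimws(substr(exp[1], 11, nchar(exp[1])))
  resolution <- NA_real_
  rem2 <- lines[grepl("^REMARK   2 RESOLUTION\\.", lines)]
  if (length(rem2)) {
    m <- regmatches(rem2[1],
                    regexpr("[0-9]+\\.[0-9]+(?=[[:space:]]+ANGSTROM)",
                            rem2[1], perl = TRUE))
    if (length(m)) resolution <- as.numeric(m)
  }

  hetLines <- lines[rec == "HET   "]
  het <- if (length(hetLines)) {
    data.frame(compId = trimws(substr(hetLines, 8, 10)),
               chainId = trimws(substr(hetLines, 13, 13)),
               resSeq = as.integer(trimws(substr(hetLines, 14, 17))),
               iCode = trimws(substr(hetLines, 18, 18)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(compId = character(), chainId = character(),
               resSeq = integer(), iCode = character(),
               stringsAsFactors = FALSE)
  }
  modLines <- lines[rec == "MODRES"]
  modres <- if (length(modLines)) {
    data.frame(compId = trimws(substr(modLines, 13, 15)),
               chainId = trimws(substr(modLines, 17, 17)),
               resSeq = as.integer(trimws(substr(modLines, 19, 22))),
               iCode = trimws(substr(modLines, 23, 23)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(compId = character(), chainId = character(),
               resSeq = integer(), iCode = character(),
               stringsAsFactors = FALSE)
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e)
      stop("parsePDB: cannot parse coordinate records of '", path, "': ",
           conditionMessage(e)))
  a <- pdb$atom
  df <- data.frame(
    record = a$type,
    name = a$elety,
    resName = a$resid,
    chainId = ifelse(is.na(a$chain), "", a$chain),
    resSeq = a$resno,
    iCode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    element = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                     .elementFromName(a$elety), a$elesy),
    stringsAsFactors = FALSE)
  df$isHydrogen <- df$element %in% c("H", "D")

  # altloc resolution: highest occupancy, ties to the lowest altLoc letter
  alt <- ifelse(is.na(a$alt), "", a$alt)
  key <- paste(df$record, df$chainId, df$resSeq, df$iCode, df$resName,
               df$name, sep = "|")
  ord <- order(key, -df$occupancy, alt)
  keep <- ord[!duplicated(key[ord])]
  df <- df[sort(keep), , drop = FALSE]
  rownames(df) <- NULL

  seqres <- list()
  if (!is.null(pdb$seqres) && length(pdb$seqres))
    seqres <- split(unname(pdb$seqres), names(pdb$seqres))

  polyRes <- unique(c(unlist(seqres, use.names = FALSE),
                      df$resName[df$record == "ATOM"]))
  polymerTypes <- unique(c(
    if (any(polyRes %in% names(AA3))) "protein",
    if (any(polyRes %in% DNA_RES)) "DNA",
    if (any(polyRes %in% RNA_RES)) "RNA"))
  if (is.null(polymerTypes)) polymerTypes <- character()

  if (!any(df$record == "ATOM"))
    stop("parsePDB: no polymer (ATOM) records in '", path, "' (empty chains)")

  new("PDBStructure", entryId = entryId, method = method,
      resolution = resolution, polymerTypes = polymerTypes, atoms = df,
      seqres = seqres, het = het, modres = modres)
}

#' Split a structure into polymer chains
#'
#' One [ChainRecord-class] per polymer chain identifier, residues in file
#' order, author numbering preserved.  HET groups are never chains.
#'
#' @param s a [PDBStructure-class].
#' @return named list of [ChainRecord-class] objects.
#' @export
splitChains <- function(s) {
  stopifnot(is(s, "PDBStructure"))
  poly <- s@atoms[s@atoms$record == "ATOM", , drop = FALSE]
  out <- list()
  for (ch in unique(poly$chainId)) {
    ca <- poly[poly$chainId == ch, , drop = FALSE]
    rid <- paste0(ca$resSeq, ca$iCode)
    ids <- unique(rid)
    resNames <- ca$resName[match(ids, rid)]
    seq1 <- paste(ifelse(resNames %in% names(AA3), AA3[resNames], "X"),
                  collapse = "")
    out[[ch]] <- new("ChainRecord", chainId = ch, atoms = ca,
                     residueIds = ids, sequence = seq1)
  }
  out
}

#' Extract true ligands from a structure
#'
#' Applies the ligand-identification rules: a HETATM group is a ligand iff it
#' appears in the HET records, does not appear in the MODRES records (modified
#' residues of the polymer are not ligands), is not water (HOH/DOD/WAT), and
#' has at least \code{minAtoms} heavy atoms.  Hydrogens never count toward the
#' atom threshold.  Each ligand is assigned to the chain named on its HETATM
#' records; if that chain has no polymer residues the nearest polymer chain
#' (by minimum atom distance to the ligand center) is used.
#'
#' @param s a [PDBStructure-class].
#' @param minAtoms minimum heavy-atom count (default 6).
#' @return list of [Ligand-class], ordered by chain, residue number, compId;
#'   may be empty.
#' @export
extractLigands <- function(s, minAtoms = 6) {
  stopifnot(is(s, "PDBStructure"))
  hetatm <- s@atoms[s@atoms$record == "HETATM", , drop = FALSE]
  if (nrow(hetatm) == 0) return(list())
  polyChains <- unique(s@atoms$chainId[s@atoms$record == "ATOM"])

  grpKey <- paste(hetatm$resName, hetatm$chainId, hetatm$resSeq, hetatm$iCode,
                  sep = "|")
  hetKey <- paste(s@het$compId, s@het$chainId, s@het$resSeq, s@het$iCode,
                  sep = "|")
  modKey <- paste(s@modres$compId, s@modres$chainId, s@modres$resSeq,
                  s@modres$iCode, sep = "|")

  out <- list()
  for (k in unique(grpKey)) {
    g <- hetatm[grpKey == k, , drop = FALSE]
    compId <- g$resName[1]
    if (compId %in% WATER_IDS) next
    if (!(k %in% hetKey)) next
    if (k %in% modKey) next
    heavy <- g[!g$isHydrogen, , drop = FALSE]
    if (nrow(heavy) < minAtoms) next
    ch <- g$chainId[1]
    if (!(ch %in% polyChains)) {
      ctr <- colMeans(cbind(heavy$x, heavy$y, heavy$z))
      d <- vapply(polyChains, function(pc) {
        pa <- s@atoms[s@atoms$record == "ATOM" & s@atoms$chainId == pc, ]
        minDistance(ctr, coordsOf(pa))
      }, numeric(1))
      ch <- polyChains[which.min(d)]
    }
    out[[length(out) + 1]] <- new("Ligand", compId = compId, chainId = ch,
                                  resSeq = as.integer(g$resSeq[1]),
                                  iCode = g$iCode[1], atoms = heavy)
  }
  if (length(out)) {
    ord <- order(vapply(out, function(l) l@chainId, character(1)),
                 vapply(out, function(l) l@resSeq, integer(1)),
                 vapply(out, function(l) l@iCode, character(1)),
                 vapply(out, function(l) l@compId, character(1)))
    out <- out[ord]
  }
  out
}

## writing ------------------------------------------------------------------

.fmtAtomName <- function(name) {
  ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
}

.coordLine <- function(record, serial, name, resName, chainId, resSeq, iCode,
                       x, y, z, occupancy, element) {
  sprintf("%-6s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, .fmtAtomName(name), resName, chainId, resSeq,
          ifelse(nzchar(iCode), iCode, " "), x, y, z, occupancy, 0,
          element)
}

#' Write a PDB-format file
#'
#' Writes header records (HEADER, EXPDTA, REMARK 2, SEQRES, HET, MODRES) and
#' coordinate records with TER separators between polymer chains.  Used by the
#' fixture generator, the database store and the prediction writer; output is
#' parseable by [parsePDB()] with coordinates at standard PDB precision
#' (3 decimals).
#'
#' @param path output path.
#' @param atoms atom table (ATOM records are written first, grouped by chain,
#'   then HETATM records).
#' @param entryId four-character entry identifier.
#' @param method EXPDTA string (default "X-RAY DIFFRACTION").
#' @param resolution REMARK 2 resolution in Angstrom; NA writes
#'   "NOT APPLICABLE".
#' @param seqres named list chain -> residue names, or NULL to derive from the
#'   ATOM records.
#' @param het,modres data.frames as in [PDBStructure-class] (may be NULL).
#' @return the path, invisibly.
#' @export
writePDBFile <- function(path, atoms, entryId = "XXXX",
                         method = "X-RAY DIFFRACTION", resolution = 2.0,
                         seqres = NULL, het = NULL, modres = NULL) {
  lines <- character()
  lines <- c(lines, sprintf("%-62s%4s", "HEADER    SYNTHETIC PROTEIN",
                            toupper(entryId)))
  lines <- c(lines, sprintf("EXPDTA    %s", method))
  lines <- c(lines, if (is.na(resolution))
    "REMARK   2 RESOLUTION. NOT APPLICABLE." else
    sprintf("REMARK   2 RESOLUTION.%9.2f ANGSTROMS.", resolution))

  poly <- atoms[atoms$record == "ATOM", , drop = FALSE]
  if (is.null(seqres)) {
    seqres <- lapply(split(poly, poly$chainId), function(p) {
      p$resName[!duplicated(paste0(p$resSeq, p$iCode))]
    })
  }
  for (ch in names(seqres)) {
    rn <- seqres[[ch]]
    rows <- split(rn, ceiling(seq_along(rn) / 13))
    for (i in seq_along(rows)) {
      lines <- c(lines, sprintf("SEQRES %3d %1s %4d  %s", i, ch,
                                length(rn), paste(rows[[i]], collapse = " ")))
    }
  }
  if (!is.null(modres) && nrow(modres)) {
    for (i in seq_len(nrow(modres))) {
      lines <- c(lines, sprintf("MODRES %4s %-3s %1s %4d%1s %-3s",
                                toupper(entryId), modres$compId[i],
                                modres$chainId[i], modres$resSeq[i],
                                ifelse(nzchar(modres$iCode[i]),
                                       modres$iCode[i], " "),
                                "ALA"))
    }
  }
  if (!is.null(het) && nrow(het)) {
    hetatm <- atoms[atoms$record == "HETATM", , drop = FALSE]
    for (i in seq_len(nrow(het))) {
      n <- sum(hetatm$resName == het$compId[i] &
                 hetatm$chainId == het$chainId[i] &
                 hetatm$resSeq == het$resSeq[i] &
                 hetatm$iCode == het$iCode[i])
      lines <- c(lines, sprintf("HET    %3s  %1s%4d%1s  %5d", het$compId[i],
                                het$chainId[i], het$resSeq[i],
                                ifelse(nzchar(het$iCode[i]),
                                       het$iCode[i], " "), n))
    }
  }

  serial <- 0L
  for (ch in unique(poly$chainId)) {
    p <- poly[poly$chainId == ch, , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      serial <- serial + 1L
      lines <- c(lines, .coordLine("ATOM", serial, p$name[i], p$resName[i],
                                   p$chainId[i], p$resSeq[i], p$iCode[i],
                                   p$x[i], p$y[i], p$z[i], p$occupancy[i],
                                   p$element[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d", serial))
  }
  hetatm <- atoms[atoms$record == "HETATM", , drop = FALSE]
  for (i in seq_len(nrow(hetatm))) {
    serial <- serial + 1L
    lines <- c(lines, .coordLine("HETATM", serial, hetatm$name[i],
                                 hetatm$resName[i], hetatm$chainId[i],
                                 hetatm$resSeq[i], hetatm$iCode[i],
                                 hetatm$x[i], hetatm$y[i], hetatm$z[i],
                                 hetatm$occupancy[i], hetatm$element[i]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write binding-site predictions
#'
#' Emits three files sharing a prefix: \code{<prefix>.tsv} and
#' \code{<prefix>.json} (rank, center coordinates, support count, site
#' residues as a \code{chain:resnum} semicolon list, plus the configuration
#' snapshot in the JSON), and \code{<prefix>.pdb} — the query chain with one
#' pseudo-ligand HETATM (component \code{PSE}) per predicted center for
#' visualisation.
#'
#' @param sites list of [BindingSite-class] (may be empty).
#' @param chain the query [ChainRecord-class].
#' @param prefix output path prefix.
#' @param cfg configuration snapshot to embed (a [siteConfig()] list), or
#'   NULL.
#' @param status machine-readable status string ("ok", "no_template", ...).
#' @return named character vector of the written paths, invisibly.
#' @export
writePrediction <- function(sites, chain, prefix, cfg = NULL, status = "ok") {
  stopifnot(is(chain, "ChainRecord"))
  df <- data.frame(
    rank = vapply(sites, function(s) s@rank, integer(1)),
    center_x = vapply(sites, function(s) s@center[1], numeric(1)),
    center_y = vapply(sites, function(s) s@center[2], numeric(1)),
    center_z = vapply(sites, function(s) s@center[3], numeric(1)),
    n_support = vapply(sites, function(s) s@support, integer(1)),
    residues = vapply(sites, function(s)
      paste(s@residues, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  tsv <- paste0(prefix, ".tsv"); jsn <- paste0(prefix, ".json")
  pdb <- paste0(prefix, ".pdb")
  ok <- tryCatch({
    write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("writePrediction: cannot write '", tsv, "': ",
                              conditionMessage(e)))
  jsonlite::write_json(
    list(chain = chain@chainId, status = status, sites = df,
         config = if (is.null(cfg)) NULL else unclass(cfg)),
    jsn, auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")

  pseudo <- .emptyAtomTable()
  if (length(sites)) {
    pseudo <- do.call(rbind, lapply(sites, function(s) {
      data.frame(record = "HETATM", name = "C1", resName = "PSE",
                 chainId = chain@chainId, resSeq = 900L + s@rank,
                 iCode = "", x = s@center[1], y = s@center[2],
                 z = s@center[3], occupancy = 1, element = "C",
                 isHydrogen = FALSE, stringsAsFactors = FALSE)
    }))
  }
  het <- if (nrow(pseudo))
    pseudo[, c("resName", "chainId", "resSeq", "iCode")] else NULL
  if (!is.null(het)) names(het)[1] <- "compId"
  writePDBFile(pdb, rbind(chain@atoms, pseudo), entryId = "PRED", het = het)
  invisible(c(tsv = tsv, json = jsn, pdb = pdb))
}
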