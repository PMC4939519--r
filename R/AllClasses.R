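# S4 classes for structures, chains, ligands, transforms, alignments,
# template databases and predictions.  Atom tables are plain data.frames
# with columns record, name, resName, chainId, resSeq, iCode, x, y, z,
# occupancy, element, isHydrogen; helpers in pdb-io.R build them.

ATOM_COLS <- c("record", "name", "resName", "chainId", "resSeq", "iCode",
               "x", "y", "z", "occupancy", "element", "isHydrogen")

.validAtomTable <- function(df, allowEmpty = FALSE) {
  if (!is.data.frame(df)) return("atom table must be a data.frame")
  missing <- setdiff(ATOM_COLS, names(df))
  if (length(missing))
    return(paste0("atom table lacks columns: ", paste(missing, collapse = ", ")))
  if (!allowEmpty && nrow(df) == 0) return("atom table is empty")
  if (nrow(df) && !all(is.finite(c(df$x, df$y, df$z))))
    return("atom coordinates must be finite")
  if (nrow(df) && any(!nzchar(df$element)))
    return("atom element symbols must be non-empty")
  TRUE
}

#' ChainRecord: one polymer chain
#'
#' A single polymer chain of a parsed structure: its ordered residues (as an
#' atom table), the residue identifiers (author numbering, insertion codes
#' preserved) and the one-letter sequence.
#'
#' @slot chainId one-character chain identifier.
#' @slot atoms data.frame of polymer atoms (hydrogens retained, flagged).
#' @slot residueIds character vector of unique residue identifiers
#'   (\code{"<resSeq><iCode>"}) in chain order.
#' @slot sequence one-letter amino-acid sequence (\code{X} for non-standard).
#' @exportClass ChainRecord
setClass("ChainRecord",
  representation(chainId = "character", atoms = "data.frame",
                 residueIds = "character", sequence = "character"))

setValidity("ChainRecord", function(object) {
  msg <- .validAtomTable(object@atoms)
  if (!isTRUE(msg)) return(msg)
  if (anyDuplicated(object@residueIds))
    return("residue identifiers must be unique within a chain")
  if (length(object@residueIds) != nchar(object@sequence))
    return("sequence length must equal residue count")
  TRUE
})

#' Ligand: one heteroatom group
#'
#' A HET group accepted as a candidate ligand: heavy atoms only (hydrogens are
#' never counted toward the ligand-size rule), with the chain it is assigned
#' to.
#'
#' @slot compId three-letter component identifier.
#' @slot chainId assigned polymer chain.
#' @slot resSeq author residue number of the group.
#' @slot iCode insertion code ("" if none).
#' @slot atoms data.frame of heavy atoms.
#' @exportClass Ligand
setClass("Ligand",
  representation(compId = "character", chainId = "character",
                 resSeq = "integer", iCode = "character", atoms = "data.frame"))

setValidity("Ligand", function(object) {
  msg <- .validAtomTable(object@atoms)
  if (!isTRUE(msg)) return(msg)
  if (any(object@atoms$isHydrogen))
    return("ligand atom table must contain heavy atoms only")
  if (object@compId %in% WATER_IDS)
    return("water is not a ligand")
  TRUE
})

#' PDBStructure: a parsed PDB entry
#'
#' One parsed PDB-format entry: header metadata (experiment method, resolution,
#' HET and MODRES bookkeeping, SEQRES) plus the full atom table.  Chains and
#' ligands are derived views obtained with [splitChains()] and
#' [extractLigands()].
#'
#' @slot entryId four-character entry identifier.
#' @slot method experiment method string from EXPDTA.
#' @slot resolution resolution in Angstrom (NA for non-diffraction methods).
#' @slot polymerTypes kinds of polymer present ("protein", "DNA", "RNA").
#' @slot atoms full atom table (ATOM and HETATM records).
#' @slot seqres named list, chain id -> SEQRES residue names.
#' @slot het data.frame of HET records (compId, chainId, resSeq, iCode).
#' @slot modres data.frame of MODRES records (compId, chainId, resSeq, iCode).
#' @exportClass PDBStructure
setClass("PDBStructure",
  representation(entryId = "character", method = "character",
                 resolution = "numeric", polymerTypes = "character",
                 atoms = "data.frame", seqres = "list",
                 het = "data.frame", modres = "data.frame"))

setValidity("PDBStructure", function(object) {
  msg <- .validAtomTable(object@atoms)
  if (!isTRUE(msg)) return(msg)
  if (length(object@resolution) != 1)
    return("resolution must be a single value (possibly NA)")
  TRUE
})

#' RigidTransform: a proper rigid-body transform
#'
#' Rotation (proper, det +1) followed by translation; the transform applied to
#' coordinates x is \code{R x + t}.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector (Angstrom).
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal (tolerance 1e-6)")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation must be proper (determinant +1)")
  if (length(object@translation) != 3 || !all(is.finite(object@translation)))
    return("translation must be a finite 3-vector")
  TRUE
})

#' AlignmentResult: a pairwise structural alignment
#'
#' Result of aligning a query chain against a template chain: the aligned
#' residue pairs (1-based indices into each chain's residue order, strictly
#' increasing in both), the rigid transform taking template coordinates into
#' the query frame, the CA RMSD over the aligned pairs and a length-normalised
#' similarity score in [0, 1].
#'
#' @slot pairs two-column integer matrix (query index, template index).
#' @slot transform RigidTransform (template -> query frame), or NULL-rotation
#'   identity when no alignment was found.
#' @slot rmsd CA RMSD (Angstrom) over the aligned pairs.
#' @slot score similarity score in [0, 1].
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(pairs = "matrix", transform = "RigidTransform",
                 rmsd = "numeric", score = "numeric"))

setValidity("AlignmentResult", function(object) {
  p <- object@pairs
  if (ncol(p) != 2) return("pairs must have two columns")
  if (nrow(p) > 1) {
    if (any(diff(p[, 1]) <= 0) || any(diff(p[, 2]) <= 0))
      return("aligned pairs must be strictly increasing in both chains")
  }
  if (object@rmsd < 0) return("rmsd must be non-negative")
  if (object@score < 0 || object@score > 1 + 1e-9)
    return("score must lie in [0, 1]")
  TRUE
})

#' TemplateEntry: one database chain with its stable ligands
#'
#' A chain admitted to the bound-template database: it owns at least one
#' ligand that passed both the ligand-size and the complex-stability gates.
#'
#' @slot entryId four-character entry identifier.
#' @slot chainId chain identifier.
#' @slot chain the ChainRecord.
#' @slot ligands list of stable [Ligand] objects (non-empty).
#' @slot homologyClass fold classification string, or NA when unmapped.
#' @exportClass TemplateEntry
setClass("TemplateEntry",
  representation(entryId = "character", chainId = "character",
                 chain = "ChainRecord", ligands = "list",
                 homologyClass = "character"))

setValidity("TemplateEntry", function(object) {
  if (length(object@ligands) == 0)
    return("a template entry must own at least one stable ligand")
  if (!all(vapply(object@ligands, is, logical(1), class2 = "Ligand")))
    return("ligands must be Ligand objects")
  TRUE
})

#' TemplateDB: the bound-template database
#'
#' The filtered template set with its two retrieval indexes and the build
#' manifest (per-stage survivor counts and the configuration snapshot).
#'
#' @slot entries named list of [TemplateEntry] (name \code{"<entry>_<chain>"}).
#' @slot homologyIndex named list: classification string -> entry keys.
#' @slot lengthIndex data.frame (key, length) sorted by length.
#' @slot manifest list: stage counts, config snapshot, skipped files.
#' @exportClass TemplateDB
setClass("TemplateDB",
  representation(entries = "list", homologyIndex = "list",
                 lengthIndex = "data.frame", manifest = "list"))

setValidity("TemplateDB", function(object) {
  if (!all(vapply(object@entries, is, logical(1), class2 = "TemplateEntry")))
    return("entries must be TemplateEntry objects")
  if (nrow(object@lengthIndex) != length(object@entries))
    return("every entry must appear in the length index")
  sc <- object@manifest$stage_counts
  if (!is.null(sc) && length(sc) >= 2 && is.unsorted(rev(unlist(sc)[-1])))
    return("chain-level stage counts must be non-increasing")
  TRUE
})

#' BindingSite: one ranked predicted binding site
#'
#' @slot rank 1-based rank (1 = Top1).
#' @slot center predicted site center, length-3 numeric (Angstrom).
#' @slot support number of mapped-ligand centers in the elected cluster
#'   (1 for sites read off a bound query's own ligand).
#' @slot residues character vector of site residues (\code{"chain:resSeq"}).
#' @slot mode "bound" or "unbound".
#' @exportClass BindingSite
setClass("BindingSite",
  representation(rank = "integer", center = "numeric", support = "integer",
                 residues = "character", mode = "character"))

setValidity("BindingSite", function(object) {
  if (length(object@center) != 3 || !all(is.finite(object@center)))
    return("center must be a finite 3-vector")
  if (object@rank < 1) return("rank must be >= 1")
  if (object@support < 1) return("support must be >= 1")
  if (!object@mode %in% c("bound", "unbound"))
    return("mode must be 'bound' or 'unbound'")
  TRUE
})

## show methods ------------------------------------------------------------

setMethod("show", "PDBStructure", function(object) {
  cat("PDBStructure", object@entryId, "\n")
  cat("  method:     ", object@method, "\n")
  cat("  resolution: ",
      if (is.na(object@resolution)) "NA" else
        sprintf("%.2f A", object@resolution), "\n")
  ch <- unique(object@atoms$chainId[object@atoms$record == "ATOM"])
  cat("  chains:     ", paste(ch, collapse = ", "), "\n")
  cat("  HET groups: ", nrow(object@het), " (MODRES: ",
      nrow(object@modres), ")\n", sep = "")
})

setMethod("show", "ChainRecord", function(object) {
  cat("ChainRecord", object@chainId, "-", length(object@residueIds),
      "residues\n")
})

setMethod("show", "Ligand", function(object) {
  cat(sprintf("Ligand %s %s:%d%s (%d heavy atoms)\n", object@compId,
              object@chainId, object@resSeq, object@iCode,
              nrow(object@atoms)))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: %d pairs, rmsd %.3f A, score %.3f\n",
              nrow(object@pairs), object@rmsd, object@score))
})

setMethod("show", "TemplateDB", function(object) {
  cat("TemplateDB with", length(object@entries), "template chains\n")
  cat("  homology classes:", length(object@homologyIndex), "\n")
  sc <- object@manifest$stage_counts
  if (!is.null(sc))
    cat("  stage counts:", paste(unlist(sc), collapse = " -> "), "\n")
})

setMethod("show", "BindingSite", function(object) {
  cat(sprintf("BindingSite Top%d (%s): center (%.2f, %.2f, %.2f), support %d, %d residues\n",
              object@rank, object@mode, object@center[1], object@center[2],
              object@center[3], object@support, length(object@residues)))
})

## accessors ---------------------------------------------------------------

#' @describeIn ChainRecord-class number of residues
#' @param x a ChainRecord
#' @export
setMethod("length", "ChainRecord", function(x) length(x@residueIds))

#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: \code{atoms()}
#' returns an object's atom table, \code{chainId()} its chain identifier,
#' \code{entryId()} a structure's or template's entry identifier,
#' \code{atomCount()} a ligand's heavy-atom count, \code{alignedLength()} and
#' \code{alignScore()} an alignment's pair count and similarity score,
#' \code{dbEntries()} a database's template list and \code{siteCenter()} /
#' \code{siteResidues()} / \code{siteSupport()} the fields of a predicted
#' site.
#'
#' @param x an object of the documented classes.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "ChainRecord", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "Ligand", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname accessors
#' @export
setMethod("chainId", "ChainRecord", function(x) x@chainId)
#' @rdname accessors
#' @export
setMethod("chainId", "Ligand", function(x) x@chainId)

#' @rdname accessors
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))
#' @rdname accessors
#' @export
setMethod("entryId", "PDBStructure", function(x) x@entryId)
#' @rdname accessors
#' @export
setMethod("entryId", "TemplateEntry", function(x) x@entryId)

#' @rdname accessors
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))
#' @rdname accessors
#' @export
setMethod("atomCount", "Ligand", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setGeneric("alignedLength", function(x) standardGeneric("alignedLength"))
#' @rdname accessors
#' @export
setMethod("alignedLength", "AlignmentResult", function(x) nrow(x@pairs))

#' @rdname accessors
#' @export
setGeneric("alignScore", function(x) standardGeneric("alignScore"))
#' @rdname accessors
#' @export
setMethod("alignScore", "AlignmentResult", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("dbEntries", function(x) standardGeneric("dbEntries"))
#' @rdname accessors
#' @export
setMethod("dbEntries", "TemplateDB", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("siteCenter", function(x) standardGeneric("siteCenter"))
#' @rdname accessors
#' @export
setMethod("siteCenter", "BindingSite", function(x) x@center)

#' @rdname accessors
#' @export
setGeneric("siteResidues", function(x) standardGeneric("siteResidues"))
#' @rdname accessors
#' @export
setMethod("siteResidues", "BindingSite", function(x) x@residues)

#' @rdname accessors
#' @export
setGeneric("siteSupport", function(x) standardGeneric("siteSupport"))
#' @rdname accessors
#' @export
setMethod("siteSupport", "BindingSite", function(x) x@support)
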