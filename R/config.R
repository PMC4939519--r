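# Configuration: one flat list of validated thresholds shared by the
# database builder, the aligner and the predictor.

WATER_IDS <- c("HOH", "DOD", "WAT")

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
DNA_RES <- c("DA", "DC", "DG", "DT", "DI", "DU")
RNA_RES <- c("A", "C", "G", "U", "I")

.CONFIG_RANGES <- list(
  maxResolution     = c(0, Inf),
  minChainLen       = c(1, Inf),
  minLigandAtoms    = c(1, Inf),
  stabilityDist     = c(0, Inf),
  boundSiteRadius   = c(0, Inf),
  unboundSiteRadius = c(0, Inf),
  lengthTolerance   = c(0, 1),     # open interval, checked separately
  clusterRadius     = c(1, 8),
  topTemplates      = c(1, Inf),
  maxSites          = c(1, Inf),
  hitThreshold      = c(0, Inf),
  afpLen            = c(3, Inf),
  dIntra            = c(0, Inf),
  dJoin             = c(0, Inf),
  gapMax            = c(0, Inf),
  maxAfps           = c(100, Inf)
)

#' Configuration for database building and site prediction
#'
#' Returns the full set of thresholds used across the pipeline, with the
#' method's defaults, overridden by any named arguments.  All values are
#' validated against their allowed ranges.
#'
#' @param ... named overrides of the defaults.
#'
#' @details Defaults (distances in Angstrom):
#' \describe{
#'   \item{maxResolution (3.0)}{X-ray resolution cut-off for template entries.}
#'   \item{minChainLen (20)}{chains must be strictly longer than this.}
#'   \item{minLigandAtoms (6)}{minimum heavy-atom count of a true ligand.}
#'   \item{stabilityDist (4)}{complex-stability gate: some ligand atom must lie
#'     within this distance of the site's geometric center (closed).}
#'   \item{boundSiteRadius (8)}{site residues of a bound chain: any heavy atom
#'     within this distance of any ligand heavy atom (closed).}
#'   \item{unboundSiteRadius (10)}{site residues around a mapped ligand
#'     (closed).}
#'   \item{lengthTolerance (0.30)}{chain-length index: relative length
#'     difference strictly below this fraction of the query length.}
#'   \item{clusterRadius (3.0)}{consensus clustering radius; neighbour counts
#'     use strict "less than"; valid range 1-8.}
#'   \item{topTemplates (20)}{at most this many templates contribute ligands.}
#'   \item{maxSites (3)}{number of ranked sites reported (Top1..Top3).}
#'   \item{hitThreshold (4)}{center-hit evaluation distance (closed).}
#'   \item{afpLen (8), dIntra (3.0), dJoin (4.0), gapMax (30), maxAfps (5000)}{
#'     aligner settings: fragment window length, intra-fragment and
#'     cross-fragment mean distance-matrix difference cut-offs, maximum
#'     residue gap between chained fragments, and a cap on the number of
#'     candidate fragment pairs kept (smallest differences first).}
#' }
#'
#' @return a named list of class \code{"SiteConfig"}.
#' @examples
#' cfg <- siteConfig(clusterRadius = 2.0)
#' cfg$clusterRadius
#' @export
siteConfig <- function(...) {
  cfg <- list(
    maxResolution = 3.0, minChainLen = 20, minLigandAtoms = 6,
    stabilityDist = 4.0, boundSiteRadius = 8.0, unboundSiteRadius = 10.0,
    lengthTolerance = 0.30, clusterRadius = 3.0, topTemplates = 20,
    maxSites = 3, hitThreshold = 4.0,
    afpLen = 8, dIntra = 3.0, dJoin = 4.0, gapMax = 30, maxAfps = 5000)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  validateConfig(cfg)
}

#' Validate a configuration list
#'
#' Checks every threshold against its allowed range and returns the
#' configuration with class \code{"SiteConfig"}.  Called by [siteConfig()];
#' exposed so configurations read from files can be validated the same way.
#'
#' @param cfg a named list with the fields of [siteConfig()].
#' @return the validated configuration.
#' @export
validateConfig <- function(cfg) {
  for (field in names(.CONFIG_RANGES)) {
    v <- cfg[[field]]
    rng <- .CONFIG_RANGES[[field]]
    if (is.null(v) || length(v) != 1 || !is.numeric(v) || !is.finite(v))
      stop("configuration field '", field, "' must be a single finite number")
    if (v < rng[1] || v > rng[2])
      stop("configuration field '", field, "' = ", v,
           " outside allowed range [", rng[1], ", ", rng[2], "]")
  }
  if (cfg$lengthTolerance <= 0 || cfg$lengthTolerance >= 1)
    stop("configuration field 'lengthTolerance' = ", cfg$lengthTolerance,
         " outside allowed open range (0, 1)")
  class(cfg) <- "SiteConfig"
  cfg
}

#' Load a configuration from a key/value file
#'
#' Reads a flat \code{key: value} (YAML-style) file whose keys mirror the
#' fields of [siteConfig()]; values given in \code{overrides} take precedence
#' over the file, which takes precedence over the defaults.
#'
#' @param path path to the file, or NULL for defaults only.
#' @param overrides named list of final overrides (e.g. command-line flags).
#' @return a validated \code{"SiteConfig"} list.
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        stop("malformed configuration line: '", ln, "'")
      key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
      if (is.na(val)) stop("non-numeric value for '", key, "'")
      vals[[key]] <- val
    }
  }
  vals[names(overrides)] <- overrides
  do.call(siteConfig, vals)
}
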