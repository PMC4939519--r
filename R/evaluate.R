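# Benchmark metrics: the 4-Angstrom center-hit accuracy and the residue-level
# Matthews correlation coefficient.

#' Center-hit test for one predicted site
#'
#' A predicted site center counts as a hit iff its minimum distance to any
#' heavy atom of the true ligand is within the threshold (closed, default
#' 4 Angstrom).
#'
#' @param center predicted site center (length-3 numeric).
#' @param trueLigand the experimentally observed [Ligand-class].
#' @param threshold hit distance in Angstrom.
#' @return TRUE/FALSE.
#' @export
siteHit <- function(center, trueLigand, threshold = 4) {
  m <- coordsOf(trueLigand)
  if (nrow(m) == 0) stop("siteHit: true ligand has no atoms")
  minDistance(center, m) <= threshold
}

#' Top-k success of a ranked prediction list
#'
#' Success iff any of the first \code{k} predicted sites hits any true
#' ligand.  Monotone in \code{k}; an empty prediction list always fails.
#'
#' @param sites list of [BindingSite-class], ordered by rank.
#' @param trueLigands list of [Ligand-class].
#' @param k number of top sites considered.
#' @param threshold hit distance in Angstrom.
#' @return TRUE/FALSE.
#' @export
topkSuccess <- function(sites, trueLigands, k = 1, threshold = 4) {
  sites <- head(sites, k)
  for (s in sites)
    for (l in trueLigands)
      if (siteHit(s@center, l, threshold)) return(TRUE)
  FALSE
}

#' Residue-level confusion counts
#'
#' Partitions the chain's residues into the four confusion classes.  The
#' experimental site is every residue with any heavy atom within
#' \code{cfg$boundSiteRadius} (8 Angstrom) of any heavy atom of an
#' experimental ligand; the predicted site is the given residue set.
#'
#' @param chain the query [ChainRecord-class].
#' @param predictedResidues character vector of predicted site residue
#'   identifiers (\code{"chain:resSeq"}).
#' @param experimentalLigands list of [Ligand-class] (the bound form's
#'   original ligands).
#' @param cfg a [siteConfig()] list.
#' @return named integer vector \code{c(tp, tn, fp, fn)} summing to the chain
#'   residue count.
#' @export
residuePartition <- function(chain, predictedResidues, experimentalLigands,
                             cfg = siteConfig()) {
  lig <- do.call(rbind, lapply(experimentalLigands, coordsOf))
  expSite <- .residuesNear(chain, lig, cfg$boundSiteRadius)
  universe <- paste0(chain@chainId, ":", chain@residueIds)
  pred <- intersect(predictedResidues, universe)
  inPred <- universe %in% pred
  inExp <- universe %in% expSite
  c(tp = sum(inPred & inExp), tn = sum(!inPred & !inExp),
    fp = sum(inPred & !inExp), fn = sum(!inPred & inExp))
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with the standard convention that a zero factor in the denominator gives
#' MCC 0.
#'
#' @param counts named vector or list with \code{tp}, \code{tn}, \code{fp},
#'   \code{fn} (all non-negative).
#' @return scalar in [-1, 1].
#' @examples
#' computeMCC(c(tp = 10, tn = 90, fp = 0, fn = 0))  # 1
#' @export
computeMCC <- function(counts) {
  counts <- as.list(counts)
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0)) stop("computeMCC: negative counts")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Evaluate the pipeline over a query set
#'
#' Scores each query chain with the center-hit accuracy (Top1/Top3) and the
#' residue-level MCC.  A bound query whose ligand passes the stability gate
#' needs no prediction: by convention it scores a hit with MCC 1.  All other
#' queries (unbound, or bound-but-unstable with their original ligands
#' removed) are run through [predictSites()] and scored against the supplied
#' ground-truth ligands; the MCC uses the Top1 site's residues.
#'
#' @param queries list of records \code{list(structure, truthLigands, mode)}
#'   with \code{mode} "bound" or "unbound"; \code{truthLigands} is a list of
#'   [Ligand-class] (the experimentally observed ligands, held out for
#'   unbound queries).  Queries without ground truth are excluded (with a
#'   logged reason in the returned \code{excluded}).
#' @param db a [TemplateDB-class].
#' @param mapping homology mapping data.frame, or NULL.
#' @param cfg a [siteConfig()] list.
#' @return list with \code{perQuery} (data.frame: query, chain, mode, route,
#'   top1, top3, mcc), \code{top1Rate}, \code{top3Rate}, \code{meanMCC},
#'   \code{excluded}.
#' @export
evaluateDataset <- function(queries, db, mapping = NULL, cfg = siteConfig()) {
  rows <- list(); excluded <- character()
  for (q in queries) {
    s <- q$structure
    if (is.null(q$truthLigands) || length(q$truthLigands) == 0) {
      excluded <- c(excluded, paste0(s@entryId, ": no ground-truth ligand"))
      next
    }
    chain <- splitChains(s)[[1]]
    mode <- q$mode %||% "unbound"
    if (mode == "bound") {
      ligs <- Filter(function(l) l@chainId == chain@chainId,
                     extractLigands(s, cfg$minLigandAtoms))
      stable <- Filter(function(l) stabilityOfComplex(chain, l, cfg), ligs)
      if (length(stable)) {
        rows[[length(rows) + 1]] <- data.frame(
          query = s@entryId, chain = chain@chainId, mode = "bound",
          route = "part1", top1 = TRUE, top3 = TRUE, mcc = 1,
          stringsAsFactors = FALSE)
        next
      }
      # unstable bound chain: treated as unbound, original ligands removed
    }
    pred <- predictSites(s, db, mapping, cfg)[[chain@chainId]]
    top1 <- topkSuccess(pred$sites, q$truthLigands, 1, cfg$hitThreshold)
    top3 <- topkSuccess(pred$sites, q$truthLigands, cfg$maxSites,
                        cfg$hitThreshold)
    predRes <- if (length(pred$sites)) pred$sites[[1]]@residues else
      character()
    mcc <- computeMCC(residuePartition(chain, predRes, q$truthLigands, cfg))
    rows[[length(rows) + 1]] <- data.frame(
      query = s@entryId, chain = chain@chainId, mode = mode,
      route = pred$route, top1 = top1, top3 = top3, mcc = mcc,
      stringsAsFactors = FALSE)
  }
  perQuery <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), chain = character(), mode = character(),
               route = character(), top1 = logical(), top3 = logical(),
               mcc = numeric(), stringsAsFactors = FALSE)
  list(perQuery = perQuery,
       top1Rate = mean(perQuery$top1),
       top3Rate = mean(perQuery$top3),
       meanMCC = mean(perQuery$mcc),
       excluded = excluded)
}
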