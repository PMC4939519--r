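# The three-route prediction workflow: direct detection for stable bound
# queries (Part 1), template search via the homology index (Part 2) with
# fallback to the chain-length index (Part 3), ligand mapping into the query
# frame, consensus clustering of mapped ligand centers, and site-residue
# detection.

#' Route a query chain
#'
#' Part 1 iff the chain owns a ligand that passes both the atom-count and the
#' stability gates (a bound chain failing stability is treated as unbound,
#' its original ligands ignored).  Otherwise Part 2 iff the chain has a
#' homology class and the homology index returns at least one template;
#' otherwise Part 3 (chain-length index).
#'
#' @param chain a [ChainRecord-class].
#' @param ligands the chain's candidate ligands (already atom-count filtered,
#'   as returned by [extractLigands()]).
#' @param db a [TemplateDB-class].
#' @param entryId entry identifier of the query structure (for the homology
#'   lookup).
#' @param mapping homology mapping data.frame, or NULL.
#' @param cfg a [siteConfig()] list.
#' @return list with \code{route} ("part1", "part2" or "part3"),
#'   \code{stableLigands} (Part 1) or \code{candidates} (Parts 2/3).
#' @export
routeChain <- function(chain, ligands, db, entryId = "", mapping = NULL,
                       cfg = siteConfig()) {
  mine <- Filter(function(l) l@chainId == chain@chainId, ligands)
  stable <- Filter(function(l) stabilityOfComplex(chain, l, cfg), mine)
  if (length(stable))
    return(list(route = "part1", stableLigands = stable))
  cls <- lookupHomologyClass(entryId, chain@chainId, mapping)
  if (!is.na(cls)) {
    cands <- queryHomologyIndex(cls, db)
    if (length(cands))
      return(list(route = "part2", candidates = cands, class = cls))
  }
  list(route = "part3",
       candidates = queryLengthIndex(length(chain), db, cfg))
}

#' Predict binding sites of a stable bound chain (Part 1)
#'
#' One site per stable ligand, read off directly: site residues are all chain
#' residues with any heavy atom within \code{cfg$boundSiteRadius} (8 Angstrom,
#' closed) of any ligand heavy atom; the site center is the geometric center
#' of the site's heavy atoms.  Sites are ranked by ligand heavy-atom count
#' (descending) and truncated to \code{cfg$maxSites}.
#'
#' @param chain a [ChainRecord-class].
#' @param stableLigands list of stable [Ligand-class] objects.
#' @param cfg a [siteConfig()] list.
#' @return list of [BindingSite-class] (mode "bound").
#' @export
predictBound <- function(chain, stableLigands, cfg = siteConfig()) {
  ord <- order(-vapply(stableLigands, atomCount, integer(1)))
  stableLigands <- stableLigands[ord]
  stableLigands <- head(stableLigands, cfg$maxSites)
  lapply(seq_along(stableLigands), function(r) {
    lig <- stableLigands[[r]]
    site <- .residuesNear(chain, coordsOf(lig), cfg$boundSiteRadius)
    ctr <- geometricCenter(.residueAtoms(
      chain, site))
    new("BindingSite", rank = as.integer(r), center = as.numeric(ctr),
        support = 1L, residues = site, mode = "bound")
  })
}

#' Align and select templates for a query chain
#'
#' Aligns the query against every candidate template, maps each template's
#' ligands into the query frame with the alignment transform, and discards
#' templates none of whose mapped ligands passes [stabilityOfComplex()]
#' against the query (a mapped ligand landing off the query surface cannot
#' define a site).  Survivors are ranked by [rankTemplates()] and truncated
#' to \code{cfg$topTemplates}.
#'
#' @param chain the query [ChainRecord-class].
#' @param candidates list of [TemplateEntry-class].
#' @param cfg a [siteConfig()] list.
#' @return list of records \code{list(entry, alignment, stableIdx)} where
#'   \code{stableIdx} indexes the template ligands that passed the gate; empty
#'   when no candidate qualifies.
#' @export
selectTemplates <- function(chain, candidates, cfg = siteConfig()) {
  kept <- list()
  for (entry in candidates) {
    aln <- alignChains(chain, entry@chain, cfg)
    if (alignedLength(aln) == 0) next
    ok <- which(vapply(entry@ligands, function(l) {
      stabilityOfComplex(chain, applyTransform(aln@transform, l), cfg)
    }, logical(1)))
    if (length(ok) == 0) next
    kept[[length(kept) + 1]] <- list(entry = entry, alignment = aln,
                                     stableIdx = ok)
  }
  rankTemplates(kept, cfg$topTemplates)
}

#' Map template ligands into the query frame
#'
#' Transforms each selected template's gate-passing ligands with that
#' template's alignment transform, producing one mapped-ligand record per
#' ligand.
#'
#' @param selected list from [selectTemplates()] (records may omit
#'   \code{stableIdx}, in which case all ligands are mapped).
#' @param cfg a [siteConfig()] list.
#' @return list of records \code{list(atoms, center, source, templateRank)};
#'   \code{center} is always the geometric center of \code{atoms}.
#' @export
mapLigands <- function(selected, cfg = siteConfig()) {
  out <- list()
  for (r in seq_along(selected)) {
    rec <- selected[[r]]
    idx <- rec$stableIdx %||% seq_along(rec$entry@ligands)
    for (j in idx) {
      lig <- applyTransform(rec$alignment@transform, rec$entry@ligands[[j]])
      out[[length(out) + 1]] <- list(
        atoms = lig@atoms,
        center = as.numeric(geometricCenter(lig)),
        source = paste0(rec$entry@entryId, "_", rec$entry@chainId),
        templateRank = r)
    }
  }
  out
}

#' Consensus clustering of mapped ligand centers
#'
#' Iterative neighbour-count election: for every remaining mapped ligand,
#' count the *other* remaining centers at distance strictly less than
#' \code{cfg$clusterRadius}; the ligand with the largest count becomes the
#' next site center (ties broken by best template rank, then input order);
#' it and every center within the radius are removed, and counting restarts
#' from scratch.  Repeats up to \code{cfg$maxSites} times or exhaustion.  No
#' cluster number is assumed: the radius (default 3 Angstrom) is the only
#' constraint.
#'
#' @param mapped list from [mapLigands()].
#' @param cfg a [siteConfig()] list.
#' @return list of clusters in election order:
#'   \code{list(center, support, electedIndex, members)} where
#'   \code{support} is the cluster size (elected ligand plus its in-radius
#'   neighbours) and indices refer to \code{mapped}.
#' @export
clusterLigandCenters <- function(mapped, cfg = siteConfig()) {
  n <- length(mapped)
  if (n == 0) return(list())
  centers <- do.call(rbind, lapply(mapped, function(m) m$center))
  tRank <- vapply(mapped, function(m) m$templateRank, numeric(1))
  remaining <- seq_len(n)
  out <- list()
  while (length(remaining) && length(out) < cfg$maxSites) {
    d <- .crossDist(centers[remaining, , drop = FALSE],
                    centers[remaining, , drop = FALSE])
    counts <- rowSums(d < cfg$clusterRadius) - 1L  # exclude self
    e <- order(-counts, tRank[remaining], remaining)[1]
    members <- remaining[d[e, ] < cfg$clusterRadius]
    out[[length(out) + 1]] <- list(center = centers[remaining[e], ],
                                   support = length(members),
                                   electedIndex = remaining[e],
                                   members = members)
    remaining <- setdiff(remaining, members)
  }
  out
}

#' Site residues around a mapped ligand
#'
#' All query residues with any heavy atom within \code{cfg$unboundSiteRadius}
#' (10 Angstrom, closed) of any atom of the cluster's elected ligand.
#'
#' @param chain the query [ChainRecord-class].
#' @param mappedLigand one record from [mapLigands()] (the elected ligand).
#' @param cfg a [siteConfig()] list.
#' @return character vector of residue identifiers (may be empty).
#' @export
detectSiteResidues <- function(chain, mappedLigand, cfg = siteConfig()) {
  .residuesNear(chain, coordsOf(mappedLigand$atoms), cfg$unboundSiteRadius)
}

#' Predict binding sites for every chain of a structure
#'
#' Splits the query into chains and routes each: stable bound chains are read
#' off directly ([predictBound()]); all others go through template selection
#' (homology index first; if the homology route yields no usable template the
#' chain falls through to the chain-length index), ligand mapping, consensus
#' clustering and site-residue detection.  Deterministic for a fixed database
#' and configuration.
#'
#' @param s the query [PDBStructure-class].
#' @param db a [TemplateDB-class].
#' @param mapping homology mapping data.frame (or NULL).
#' @param cfg a [siteConfig()] list.
#' @return named list (one element per chain):
#'   \code{list(chainId, route, status, sites)} with \code{status} "ok" or
#'   "no_template" and \code{sites} a list of [BindingSite-class].
#' @examples
#' dir <- tempfile(); corpus <- generateCorpus(dir, 2, 3, seed = 5)
#' db <- buildDatabase(corpus$paths, corpus$mappingPath)
#' ub <- deriveUnbound(corpus$paths[1], tempfile(fileext = ".pdb"),
#'                     seed = 9, newEntryId = "q001")
#' predictSites(parsePDB(ub$path), db)
#' @export
predictSites <- function(s, db, mapping = NULL, cfg = siteConfig()) {
  stopifnot(is(s, "PDBStructure"), is(db, "TemplateDB"))
  chains <- splitChains(s)
  ligands <- extractLigands(s, cfg$minLigandAtoms)
  out <- list()
  for (ch in chains) {
    rt <- routeChain(ch, ligands, db, s@entryId, mapping, cfg)
    if (rt$route == "part1") {
      out[[ch@chainId]] <- list(chainId = ch@chainId, route = "part1",
                                status = "ok",
                                sites = predictBound(ch, rt$stableLigands,
                                                     cfg))
      next
    }
    route <- rt$route
    selected <- selectTemplates(ch, rt$candidates, cfg)
    if (length(selected) == 0 && route == "part2") {
      # homology route exhausted: fall through to the length index
      route <- "part2->part3"
      selected <- selectTemplates(ch, queryLengthIndex(length(ch), db, cfg),
                                  cfg)
    }
    if (length(selected) == 0) {
      out[[ch@chainId]] <- list(chainId = ch@chainId, route = route,
                                status = "no_template", sites = list())
      next
    }
    mapped <- mapLigands(selected, cfg)
    clusters <- clusterLigandCenters(mapped, cfg)
    sites <- lapply(seq_along(clusters), function(r) {
      cl <- clusters[[r]]
      new("BindingSite", rank = as.integer(r),
          center = as.numeric(cl$center),
          support = as.integer(cl$support),
          residues = detectSiteResidues(ch, mapped[[cl$electedIndex]], cfg),
          mode = "unbound")
    })
    out[[ch@chainId]] <- list(chainId = ch@chainId, route = route,
                              status = "ok", sites = sites)
  }
  out
}
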