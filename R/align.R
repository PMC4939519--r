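# CE-style pairwise structural alignment: aligned fragment pairs (AFPs) from
# intra-fragment distance-matrix agreement, dynamic-programming chaining, and
# a final Kabsch superposition over the aligned CA pairs.

#' CA coordinates of a chain
#'
#' One row per residue, in chain order.  Errors (naming the residue) if any
#' residue lacks a CA atom.
#'
#' @param chain a [ChainRecord-class].
#' @return n x 3 matrix.
#' @export
caCoords <- function(chain) {
  stopifnot(is(chain, "ChainRecord"))
  a <- chain@atoms
  ca <- a[a$name == "CA", , drop = FALSE]
  key <- paste0(ca$resSeq, ca$iCode)
  idx <- match(chain@residueIds, key)
  if (anyNA(idx))
    stop("chain ", chain@chainId, ": residue ",
         chain@residueIds[which(is.na(idx))[1]], " has no CA atom")
  cbind(ca$x[idx], ca$y[idx], ca$z[idx])
}

#' Find aligned fragment pairs between two chains
#'
#' Scans all fixed-length residue-window pairs and keeps those whose
#' intra-fragment CA distance matrices agree to a mean absolute difference of
#' at most \code{cfg$dIntra}.  Distance matrices are rigid-motion invariant,
#' so the AFP set is unchanged by rigid motion of either chain.
#'
#' @param query,template [ChainRecord-class] objects with CA atoms.
#' @param cfg a [siteConfig()] list (fields \code{afpLen}, \code{dIntra},
#'   \code{maxAfps}).
#' @return data.frame with 1-based columns \code{qStart}, \code{tStart} and
#'   the mean difference \code{diff}, sorted by (qStart, tStart).  If more
#'   than \code{cfg$maxAfps} windows qualify, the smallest differences are
#'   kept.
#' @export
findAFPs <- function(query, template, cfg = siteConfig()) {
  L <- as.integer(cfg$afpLen)
  caq <- caCoords(query); cat_ <- caCoords(template)
  if (nrow(caq) < L || nrow(cat_) < L)
    return(data.frame(qStart = integer(), tStart = integer(),
                      diff = numeric()))
  dq <- .crossDist(caq, caq); dt <- .crossDist(cat_, cat_)
  res <- .afpScan(dq, dt, L, cfg$dIntra)
  df <- data.frame(qStart = res$qs + 1L, tStart = res$ts + 1L,
                   diff = res$diff)
  if (nrow(df) > cfg$maxAfps)
    df <- df[order(df$diff)[seq_len(cfg$maxAfps)], , drop = FALSE]
  df <- df[order(df$qStart, df$tStart), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Chain fragment pairs into the best sequential alignment path
#'
#' Dynamic program over the AFP graph: admissible successors are either
#' same-diagonal overlapping windows (whose residue pairs are consistent) or
#' disjoint windows with a gap of at most \code{cfg$gapMax} residues in each
#' chain and a cross-fragment mean distance-matrix difference of at most
#' \code{cfg$dJoin}.  The path maximises the number of aligned residue pairs;
#' ties are broken by the smaller sum of fragment differences, then by the
#' earlier fragment (deterministic).
#'
#' @param afps data.frame from [findAFPs()].
#' @param query,template the chains the AFPs refer to.
#' @param cfg a [siteConfig()] list.
#' @return list with \code{path} (row indices into \code{afps}) and
#'   \code{pairs} (two-column 1-based matrix of aligned residue indices,
#'   strictly increasing in both columns).  Empty input yields an empty path.
#' @export
extendAlignment <- function(afps, query, template, cfg = siteConfig()) {
  if (nrow(afps) == 0)
    return(list(path = integer(),
                pairs = matrix(integer(), 0, 2)))
  L <- as.integer(cfg$afpLen)
  caq <- caCoords(query); cat_ <- caCoords(template)
  dq <- .crossDist(caq, caq); dt <- .crossDist(cat_, cat_)
  ord <- order(afps$qStart, afps$tStart)
  afps <- afps[ord, , drop = FALSE]
  res <- .ceDp(afps$qStart - 1L, afps$tStart - 1L, afps$diff, dq, dt, L,
               cfg$dJoin, as.integer(cfg$gapMax))
  list(path = ord[res$path + 1L], pairs = res$pairs + 1L)
}

.emptyAlignment <- function() {
  new("AlignmentResult", pairs = matrix(integer(), 0, 2),
      transform = rigidTransform(), rmsd = 0, score = 0)
}

#' Align a query chain against a template chain
#'
#' Full CE-style alignment: AFP detection, path extension, then a single
#' Kabsch superposition over the aligned CA pairs.  The similarity score is
#' \deqn{score = \frac{aligned}{\min(n_q, n_t)} \cdot \frac{1}{1 + rmsd/r_0}}
#' with \eqn{r_0 = 3} Angstrom — length-normalised and bounded in [0, 1]; a
#' self-alignment scores exactly 1.
#'
#' @param query,template [ChainRecord-class] objects.
#' @param cfg a [siteConfig()] list.
#' @return an [AlignmentResult-class]; when no AFP is found (no usable
#'   template) the result has zero aligned length and score 0.
#' @examples
#' fx <- generateBound(fixtureSpec(seed = 3), tempfile(fileext = ".pdb"))
#' ch <- splitChains(parsePDB(fx$path))[[1]]
#' alignChains(ch, ch)  # full-length, rmsd 0, score 1
#' @export
alignChains <- function(query, template, cfg = siteConfig()) {
  if (length(query) < cfg$afpLen || length(template) < cfg$afpLen)
    return(.emptyAlignment())
  afps <- findAFPs(query, template, cfg)
  if (nrow(afps) == 0) return(.emptyAlignment())
  ext <- extendAlignment(afps, query, template, cfg)
  pairs <- ext$pairs
  if (nrow(pairs) < 3) return(.emptyAlignment())
  caq <- caCoords(query); cat_ <- caCoords(template)
  fit <- kabschSuperpose(cat_[pairs[, 2], , drop = FALSE],
                         caq[pairs[, 1], , drop = FALSE])
  score <- (nrow(pairs) / min(length(query), length(template))) *
    1 / (1 + fit$rmsd / 3)
  new("AlignmentResult", pairs = pairs, transform = fit$transform,
      rmsd = fit$rmsd, score = min(score, 1))
}

#' Rank aligned templates
#'
#' Sorts template/alignment pairs by similarity score (descending), breaking
#' ties by lower RMSD and then lexicographic entry identifier, and truncates
#' to the top \code{k} (at most 20 templates contribute by default).
#'
#' @param results list of \code{list(entry = TemplateEntry,
#'   alignment = AlignmentResult)}.
#' @param k maximum number retained (default 20).
#' @return the sorted, truncated list.
#' @export
rankTemplates <- function(results, k = 20) {
  if (length(results) == 0) return(results)
  scores <- vapply(results, function(r) r$alignment@score, numeric(1))
  rmsds <- vapply(results, function(r) r$alignment@rmsd, numeric(1))
  ids <- vapply(results, function(r)
    paste0(r$entry@entryId, "_", r$entry@chainId), character(1))
  head(results[order(-scores, rmsds, ids)], k)
}
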