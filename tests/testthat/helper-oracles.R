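# Shared test helpers: hand-built chains/ligands and independent brute-force
# oracles.  Oracles deliberately avoid the package's vectorised internals.

# a ChainRecord from a CA coordinate matrix (one atom per residue)
makeChain <- function(ca, chainId = "A") {
  n <- nrow(ca)
  atoms <- data.frame(record = "ATOM", name = "CA", resName = "ALA",
                      chainId = chainId, resSeq = seq_len(n), iCode = "",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      occupancy = 1, element = "C", isHydrogen = FALSE,
                      stringsAsFactors = FALSE)
  new("ChainRecord", chainId = chainId, atoms = atoms,
      residueIds = as.character(seq_len(n)),
      sequence = paste(rep("A", n), collapse = ""))
}

# a Ligand with k heavy atoms at given coordinates
makeLigand <- function(coords, compId = "LIG", chainId = "A",
                       resSeq = 201L) {
  coords <- rbind(coords)
  k <- nrow(coords)
  atoms <- data.frame(record = "HETATM", name = paste0("C", seq_len(k)),
                      resName = compId, chainId = chainId, resSeq = resSeq,
                      iCode = "", x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], occupancy = 1, element = "C",
                      isHydrogen = FALSE, stringsAsFactors = FALSE)
  new("Ligand", compId = compId, chainId = chainId, resSeq = resSeq,
      iCode = "", atoms = atoms)
}

# smooth random CA trace with 3.8 A spacing
randomTrace <- function(n, seed) {
  set.seed(seed)
  pos <- c(0, 0, 0); dir <- c(1, 0, 0)
  out <- matrix(0, n, 3)
  out[1, ] <- pos
  for (i in 2:n) {
    dir <- dir + 0.6 * runif(3, -1, 1)
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + 3.8 * dir
    out[i, ] <- pos
  }
  out
}

# ideal alpha-helix CA trace
helixTrace <- function(n) {
  t <- seq_len(n)
  cbind(2.3 * cos(t * 100 * pi / 180), 2.3 * sin(t * 100 * pi / 180),
        1.5 * t)
}

randomRotationMatrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## clustering oracle: re-counts from scratch each round with explicit loops
oracleCluster <- function(centers, tRank, radius, maxSites) {
  alive <- rep(TRUE, nrow(centers))
  res <- list()
  while (any(alive) && length(res) < maxSites) {
    idx <- which(alive)
    cnt <- integer(length(idx))
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a != b &&
            sqrt(sum((centers[idx[a], ] - centers[idx[b], ])^2)) < radius)
          cnt[a] <- cnt[a] + 1L
      }
    }
    pick <- idx[order(-cnt, tRank[idx], idx)][1]
    mem <- idx[vapply(idx, function(j)
      sqrt(sum((centers[pick, ] - centers[j, ])^2)) < radius, logical(1))]
    res[[length(res) + 1]] <- list(center = centers[pick, ],
                                   support = length(mem), elected = pick)
    alive[mem] <- FALSE
  }
  res
}

## SVD-free superposition oracle: nested Euler-angle grid search (optimal
## translation is centroid matching for any rotation)
oracleRmsd <- function(moving, fixed) {
  Pm <- sweep(moving, 2, colMeans(moving))
  Pf <- sweep(fixed, 2, colMeans(fixed))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  evalR <- function(a, b, c) {
    R <- rot(a, b, c)
    sqrt(mean(rowSums((Pm %*% t(R) - Pf)^2)))
  }
  best <- c(0, 0, 0); bestV <- Inf
  for (a in seq(0, 2 * pi, length.out = 19))
    for (b in seq(0, pi, length.out = 10))
      for (c in seq(0, 2 * pi, length.out = 19)) {
        v <- evalR(a, b, c)
        if (v < bestV) { bestV <- v; best <- c(a, b, c) }
      }
  step <- pi / 9
  for (lvl in 1:3) {
    step <- step / 4
    for (a in best[1] + step * (-3:3))
      for (b in best[2] + step * (-3:3))
        for (c in best[3] + step * (-3:3)) {
          v <- evalR(a, b, c)
          if (v < bestV) { bestV <- v; best <- c(a, b, c) }
        }
  }
  bestV
}

## exhaustive AFP-path enumeration (mirrors the chaining rules; depth-first
## over all monotone chains)
oracleExtend <- function(afps, dq, dt, L, dJoin, gapMax) {
  m <- nrow(afps)
  compat <- function(p, k) {
    s <- afps$qStart[k] - afps$qStart[p]
    st <- afps$tStart[k] - afps$tStart[p]
    if (st <= 0 || s <= 0) return(NULL)
    if (s < L || st < L) {
      if (s != st || s >= L) return(NULL)
      return(s)
    }
    if (s - L > gapMax || st - L > gapMax) return(NULL)
    tot <- 0
    for (a in 0:(L - 1))
      for (b in 0:(L - 1))
        tot <- tot + abs(dq[afps$qStart[p] + a, afps$qStart[k] + b] -
                           dt[afps$tStart[p] + a, afps$tStart[k] + b])
    if (tot / L^2 > dJoin) return(NULL)
    L
  }
  bestLen <- -1; bestCost <- Inf; bestChain <- integer()
  recurse <- function(chain, len, cost) {
    if (len > bestLen || (len == bestLen && cost < bestCost - 1e-12)) {
      bestLen <<- len; bestCost <<- cost; bestChain <<- chain
    }
    last <- chain[length(chain)]
    for (k in seq_len(m)) {
      if (afps$qStart[k] <= afps$qStart[last] ||
          (afps$qStart[k] == afps$qStart[last] &&
             afps$tStart[k] <= afps$tStart[last])) next
      add <- compat(last, k)
      if (is.null(add)) next
      recurse(c(chain, k), len + add, cost + afps$diff[k])
    }
  }
  ord <- order(afps$qStart, afps$tStart)
  for (st in ord) recurse(st, L, afps$diff[st])
  pairs <- NULL; lastQ <- -1
  for (k in bestChain) {
    for (a in 0:(L - 1)) {
      q <- afps$qStart[k] + a
      if (q > lastQ) {
        pairs <- rbind(pairs, c(q, afps$tStart[k] + a))
        lastQ <- q
      }
    }
  }
  list(chain = bestChain, pairs = pairs, len = bestLen)
}

# residue-level distance computation with explicit loops (partition oracle)
oracleExpSite <- function(chain, ligCoords, radius) {
  a <- atoms(chain)
  a <- a[!a$isHydrogen, ]
  hit <- character()
  for (rid in chain@residueIds) {
    ra <- a[paste0(a$resSeq, a$iCode) == rid, , drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(ligCoords))) {
        d <- sqrt(sum((c(ra$x[i], ra$y[i], ra$z[i]) - ligCoords[j, ])^2))
        if (d <= radius) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hit <- c(hit, paste0(chainId(chain), ":", rid))
  }
  hit
}
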