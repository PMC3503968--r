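#' Uncorrected P distance between accession profiles
#'
#' d(i, j) = (number of loci with differing calls) / (number of loci).
#'
#' @param m a [MarkerMatrix-class] with at least one locus.
#' @return symmetric numeric matrix with accession labels, zero diagonal.
#' @export
uncorrectedPDistance <- function(m) {
  stopifnot(is(m, "MarkerMatrix"))
  calls <- markerCalls(m)
  if (nrow(calls) == 0L) stopf("zero loci")
  x <- t(calls)
  ## Hamming distance over binary profiles via cross products
  ones <- x %*% t(x)
  tot <- rowSums(x)
  diffs <- outer(tot, tot, "+") - 2 * ones
  d <- diffs / nrow(calls)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

## --- NeighborNet agglomeration (circular ordering) ------------------------
##
## Bryant-Moulton agglomeration: active nodes start as the taxa, each in its
## own cluster; clusters never exceed two nodes (a linked pair).  At each
## step the pair of clusters minimising the neighbor-joining Q criterion on
## cluster-averaged distances is chosen; within it, the node pair minimising
## Q on the mixed set (other clusters whole, the chosen clusters' nodes as
## singletons) is linked.  Chains of three nodes are reduced to two with the
## standard 2/3-1/3 distance reduction, and the reductions are replayed in
## reverse at the end to expand the final 3-cycle into the full circular
## ordering.  Ties are broken by smallest node creation index.

.nnOrder <- function(D) {
  n <- nrow(D)
  if (n <= 3L) return(seq_len(n))
  maxNodes <- 3L * n
  d <- matrix(0, maxNodes, maxNodes)
  d[1:n, 1:n] <- D
  active <- seq_len(n)
  cluster <- as.list(seq_len(n))      # each element: 1 or 2 node ids (ordered)
  stack <- list()                     # reductions: list(new=c(u,v), old=c(x,y,z))
  nextNode <- n

  clusterDist <- function(A, B)
    mean(d[A, B, drop = FALSE][seq_len(length(A) * length(B))])

  reduce <- function(x, y, z) {
    ## replace chain x-y-z by u-v
    u <- nextNode + 1L; v <- nextNode + 2L
    nextNode <<- nextNode + 2L
    others <- setdiff(active, c(x, y, z))
    d[u, others] <<- 2 / 3 * d[x, others] + 1 / 3 * d[y, others]
    d[others, u] <<- d[u, others]
    d[v, others] <<- 2 / 3 * d[z, others] + 1 / 3 * d[y, others]
    d[others, v] <<- d[v, others]
    d[u, v] <<- d[v, u] <<- (d[x, y] + d[x, z] + d[y, z]) / 3
    active <<- c(others, u, v)
    stack[[length(stack) + 1L]] <<- list(new = c(u, v), old = c(x, y, z))
    c(u, v)
  }

  repeat {
    m <- length(cluster)
    if (length(active) <= 3L || m <= 1L) break
    ## cluster-level Q selection
    cd <- matrix(0, m, m)
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      cd[i, j] <- cd[j, i] <- clusterDist(cluster[[i]], cluster[[j]])
    }
    R <- rowSums(cd)
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      q <- (m - 2) * cd[i, j] - (R[i] - cd[i, j]) - (R[j] - cd[i, j])
      if (q < bestQ - 1e-12) { bestQ <- q; best <- c(i, j) }
    }
    A <- cluster[[best[1]]]; B <- cluster[[best[2]]]
    ## node-level selection: other clusters whole, A and B exploded
    othersIdx <- setdiff(seq_len(m), best)
    mhat <- length(othersIdx) + length(A) + length(B)
    nodes <- c(A, B)
    S <- vapply(nodes, function(p) {
      s <- sum(vapply(othersIdx, function(ci)
        clusterDist(p, cluster[[ci]]), numeric(1)))
      s + sum(d[p, setdiff(nodes, p)])
    }, numeric(1))
    names(S) <- as.character(nodes)
    bestQ <- Inf; bx <- NA_integer_; by <- NA_integer_
    for (x in A) for (y in B) {
      q <- (mhat - 2) * d[x, y] - S[[as.character(x)]] - S[[as.character(y)]]
      if (q < bestQ - 1e-12) { bestQ <- q; bx <- x; by <- y }
    }
    ## agglomerate
    restA <- setdiff(A, bx); restB <- setdiff(B, by)
    if (!length(restA) && !length(restB)) {
      newCluster <- c(bx, by)
    } else if (length(restA) && !length(restB)) {
      newCluster <- reduce(restA, bx, by)
    } else if (!length(restA) && length(restB)) {
      newCluster <- reduce(bx, by, restB)
    } else {
      uv <- reduce(restA, bx, by)
      newCluster <- reduce(uv[1], uv[2], restB)
    }
    cluster[best] <- NULL
    cluster[[length(cluster) + 1L]] <- newCluster
  }

  ## close the cycle on the remaining nodes, respecting linked pairs
  ord <- unlist(cluster)
  ## expand reductions in reverse
  for (k in rev(seq_along(stack))) {
    red <- stack[[k]]
    pu <- match(red$new[1], ord); pv <- match(red$new[2], ord)
    len <- length(ord)
    if (is.na(pu) || is.na(pv)) stopf("internal error: reduction replay failed")
    if ((pu %% len) + 1L == pv) {
      ord <- append(ord[-c(pu, pv)], red$old, after = pu - 1L)
    } else if ((pv %% len) + 1L == pu) {
      ord <- append(ord[-c(pu, pv)], rev(red$old), after = pv - 1L)
    } else stopf("internal error: reduced pair not adjacent in cycle")
  }
  ## rotate so taxon 1 leads (canonical, deterministic presentation)
  p1 <- match(1L, ord)
  ord <- c(ord[p1:length(ord)], ord[seq_len(p1 - 1L)])
  ## fix orientation: smaller second element (mirror-invariant canonical form)
  if (length(ord) > 2L && ord[2] > ord[length(ord)])
    ord <- c(ord[1], rev(ord[-1]))
  as.integer(ord)
}

## All circular splits of a cycle: for positions p < q the split side is
## cycle[p..(q-1)].  Returns list(sides=list of index vectors, design=matrix
## pairs x splits with 1 where the split separates the pair.)
.circularSplits <- function(cycle) {
  n <- length(cycle)
  pairs <- utils::combn(n, 2)          # taxon index pairs
  pos <- integer(n); pos[cycle] <- seq_len(n)
  sides <- list()
  cols <- list()
  for (p in seq_len(n - 1L)) for (q in seq((p + 1L), n)) {
    side <- cycle[p:(q - 1L)]
    inside <- logical(n); inside[side] <- TRUE
    sep <- xor(inside[pairs[1, ]], inside[pairs[2, ]])
    sides[[length(sides) + 1L]] <- sort(side)
    cols[[length(cols) + 1L]] <- as.numeric(sep)
  }
  list(sides = sides, design = do.call(cbind, cols), pairs = pairs)
}

#' NeighborNet circular split network from a distance matrix
#'
#' Produces the NeighborNet circular ordering by agglomeration
#' (neighbor-joining-style Q selection on cluster-averaged distances, with
#' ties broken by smallest node index) and estimates nonnegative split
#' weights by least squares over all n(n-1)/2 splits compatible with the
#' ordering.  Splits with weight below `tol` are dropped.  For 3 or fewer
#' taxa the closed-form star decomposition is used.
#'
#' @param d symmetric nonnegative distance matrix with labels and zero
#'   diagonal (e.g. from [uncorrectedPDistance()]).
#' @param tol weights at or below this are dropped (default 1e-9).
#' @return a [SplitNetwork-class].
#' @export
neighborNet <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (!isSymmetric(unname(d)) || any(d < 0) || any(diag(d) != 0))
    stopf("input must be a symmetric nonnegative matrix with zero diagonal")
  taxa <- rownames(d)
  n <- length(taxa)
  if (n < 2L) stopf("need at least 2 taxa")
  if (n == 2L) {
    return(new("SplitNetwork", taxa = taxa, cycle = 1:2,
               splits = list(1L), weights = d[1, 2],
               supports = NA_real_))
  }
  if (n == 3L) {
    w <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    keep <- w > tol
    return(new("SplitNetwork", taxa = taxa, cycle = 1:3,
               splits = as.list(1:3)[keep], weights = w[keep],
               supports = rep(NA_real_, sum(keep))))
  }
  cycle <- .nnOrder(unname(d))
  cs <- .circularSplits(cycle)
  y <- d[t(cs$pairs)]                 # observed distances per pair
  fit <- pracma::lsqnonneg(cs$design, y)
  w <- fit$x
  keep <- which(w > tol)
  new("SplitNetwork", taxa = taxa, cycle = cycle,
      splits = cs$sides[keep], weights = w[keep],
      supports = rep(NA_real_, length(keep)))
}

#' @describeIn neighborNet circular ordering (taxon indices).
#' @param x a `SplitNetwork`.
#' @export
setMethod("cycleOrder", "SplitNetwork", function(x) x@cycle)

#' @describeIn neighborNet list of split sides (taxon index vectors).
#' @export
setMethod("splits", "SplitNetwork", function(x) x@splits)

#' @describeIn neighborNet split weights.
#' @export
setMethod("splitWeights", "SplitNetwork", function(x) x@weights)

#' @describeIn neighborNet bootstrap supports (NA when not estimated).
#' @export
setMethod("splitSupports", "SplitNetwork", function(x) x@supports)

setMethod("show", "SplitNetwork", function(object) {
  cat(sprintf("SplitNetwork: %d taxa, %d weighted splits%s\n",
              length(object@taxa), length(object@splits),
              if (all(is.na(object@supports))) ""
              else " (with bootstrap supports)"))
  cat("  cycle:", paste(object@taxa[object@cycle], collapse = " "), "\n")
})

#' Pairwise distances implied by a split network
#'
#' Sum of the weights of the splits separating each pair; on
#' circular-decomposable input these reproduce the original distances.
#'
#' @param net a [SplitNetwork-class].
#' @return symmetric matrix with the network's taxon labels.
#' @export
splitDistances <- function(net) {
  n <- length(net@taxa)
  d <- matrix(0, n, n, dimnames = list(net@taxa, net@taxa))
  for (k in seq_along(net@splits)) {
    s <- net@splits[[k]]
    inside <- logical(n); inside[s] <- TRUE
    sep <- outer(inside, inside, xor)
    d <- d + net@weights[k] * sep
  }
  d
}

## canonical split key: side not containing taxon 1, as sorted labels
.splitKey <- function(side, taxa) {
  n <- length(taxa)
  idx <- if (1L %in% side) setdiff(seq_len(n), side) else side
  paste(sort(taxa[idx]), collapse = "|")
}

#' Locus-bootstrap supports and confidence filtering for a NeighborNet
#'
#' Resamples loci with replacement `nBoot` times, rebuilds the network each
#' time, and scores each split of the original network by the fraction of
#' replicates whose network contains the same bipartition of accessions.
#' Also returns the filtered network keeping splits with support at or
#' above `threshold` (the single-diagram confidence-set rendering).
#'
#' @param m a [MarkerMatrix-class].
#' @param nBoot number of bootstrap replicates (>= 1; 1000 in the standard
#'   setting).
#' @param threshold support threshold for the filtered network
#'   (default 0.95).
#' @param seed integer seed for resampling.
#' @param tol passed to [neighborNet()].
#' @return list with `network` (original network annotated with supports),
#'   `confidenceNetwork` (filtered), and `replicateSplits` (list of the
#'   split keys of each replicate, for replay checks).
#' @export
bootstrapConfidenceNetwork <- function(m, nBoot = 1000, threshold = 0.95,
                                       seed = NULL, tol = 1e-9) {
  stopifnot(is(m, "MarkerMatrix"))
  if (nBoot < 1) stopf("nBoot must be >= 1")
  net <- neighborNet(uncorrectedPDistance(m), tol = tol)
  calls <- markerCalls(m)
  L <- nrow(calls)
  repKeys <- withSeed(seed, lapply(seq_len(nBoot), function(i) {
    idx <- sample.int(L, L, replace = TRUE)
    mb <- MarkerMatrix(calls[idx, , drop = FALSE] |>
                         (\(x) { rownames(x) <- paste0("b", seq_len(L)); x })(),
                       teFamily = teFamily(m))
    nb <- neighborNet(uncorrectedPDistance(mb), tol = tol)
    unique(vapply(splits(nb), .splitKey, character(1), taxa = nb@taxa))
  }))
  keys <- vapply(net@splits, .splitKey, character(1), taxa = net@taxa)
  support <- vapply(keys, function(k)
    mean(vapply(repKeys, function(rk) k %in% rk, logical(1))), numeric(1))
  net@supports <- unname(support)
  keep <- which(net@supports >= threshold)
  conf <- new("SplitNetwork", taxa = net@taxa, cycle = net@cycle,
              splits = net@splits[keep], weights = net@weights[keep],
              supports = net@supports[keep])
  list(network = net, confidenceNetwork = conf, replicateSplits = repKeys)
}
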