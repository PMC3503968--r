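# Fixture builders and independent brute-force oracles used across tests.

randomCalls <- function(nLoci, nAcc, seed, p = 0.5) {
  set.seed(seed)
  matrix(rbinom(nLoci * nAcc, 1, p), nLoci, nAcc,
         dimnames = list(sprintf("L%03d", seq_len(nLoci)),
                         sprintf("a%02d", seq_len(nAcc))))
}

## balanced five-taxon scheme over nPer accessions per taxon
makeScheme <- function(nPer = 2) {
  taxa <- c("SYL", "TRI", "NUD", "REP", "ISL")
  acc <- paste0("a", sprintf("%02d", seq_len(5 * nPer)))
  TaxonScheme(setNames(rep(taxa, each = nPer), acc),
              maternalDiploid = "SYL", paternalDiploid = "TRI",
              polyploids = c("NUD", "REP", "ISL"))
}

randomMarker <- function(seed, nLoci = 30, nPer = 2, p = 0.5) {
  calls <- randomCalls(nLoci, 5 * nPer, seed, p)
  colnames(calls) <- paste0("a", sprintf("%02d", seq_len(5 * nPer)))
  MarkerMatrix(calls, teFamily = "TEST")
}

## brute-force parental classification by explicit set operations
bruteClassify <- function(calls, scheme) {
  present <- function(taxon) {
    acc <- accessionsOf(scheme, taxon)
    rownames(calls)[apply(calls[, acc, drop = FALSE] == 1, 1, any)]
  }
  mat <- present(maternalDiploid(scheme))
  pat <- present(paternalDiploid(scheme))
  status <- setNames(rep("absent_in_parents", nrow(calls)), rownames(calls))
  status[setdiff(mat, pat)] <- "maternal_specific"
  status[setdiff(pat, mat)] <- "paternal_specific"
  status[intersect(mat, pat)] <- "shared_parental"
  union_par <- union(mat, pat)
  lab <- sapply(polyploids(scheme), function(tx) {
    pp <- present(tx)
    out <- character(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      l <- rownames(calls)[i]
      out[i] <- if (l %in% union_par) {
        if (l %in% pp) "additive_present" else "missing"
      } else {
        if (l %in% pp) "new" else "absent_everywhere"
      }
    }
    out
  })
  rownames(lab) <- rownames(calls)
  list(status = status, labels = lab)
}

## powerset sharing-category counts by direct subset enumeration
brutePartition <- function(labels, want, polys) {
  counts <- integer(0)
  for (s in seq(length(polys), 1)) {
    for (j in seq_len(ncol(combn(length(polys), s)))) {
      sub <- polys[combn(length(polys), s)[, j]]
      nm <- paste(sub, collapse = "_")
      n <- 0L
      for (i in seq_len(nrow(labels))) {
        inSet <- polys[labels[i, ] == want]
        if (length(inSet) && setequal(inSet, sub)) n <- n + 1L
      }
      counts[nm] <- n
    }
  }
  counts
}

## one-sided Fisher p by full enumeration of tables with the observed margins
enumFisherP <- function(tab, direction) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  aRange <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- sapply(aRange, function(a) {
    choose(c1, a) * choose(N - c1, r1 - a) / choose(N, r1)
  })
  a0 <- tab[1, 1]
  if (direction == "greater") sum(probs[aRange >= a0])
  else sum(probs[aRange <= a0])
}

## distances implied by an explicit circular split system
circularMetric <- function(cyc, weights) {
  n <- length(cyc)
  sides <- list(); k <- 0
  for (p in 1:(n - 1)) for (q in (p + 1):n) {
    k <- k + 1; sides[[k]] <- cyc[p:(q - 1)]
  }
  D <- matrix(0, n, n)
  for (j in seq_len(k)) {
    ins <- logical(n); ins[sides[[j]]] <- TRUE
    D <- D + weights[j] * outer(ins, ins, xor)
  }
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  D
}

## unordered bipartition keys of a network's splits (label-based)
splitKeys <- function(net) {
  taxa <- net@taxa
  sapply(splits(net), function(s) {
    side <- sort(taxa[s]); other <- sort(setdiff(taxa, taxa[s]))
    paste(min(paste(side, collapse = ","), paste(other, collapse = ",")),
          max(paste(side, collapse = ","), paste(other, collapse = ",")),
          sep = "|")
  })
}

## all permutations of 1..n (iterative heap-style construction)
allPerms <- function(n) {
  out <- list(1L)
  for (m in 2:n) {
    nxt <- list()
    for (p in out) for (pos in 0:(m - 1)) {
      nxt[[length(nxt) + 1L]] <- append(p, m, after = pos)
    }
    out <- nxt
  }
  out
}

## simulator settings for the paternal-bias recovery study
recoveryParams <- function(seed, beta = 0.8) simulationParams(
  families = data.frame(te = "SIM", nShared = 0, nMaternal = 600,
                        nPaternal = 600, gainMean = 0, burst = 1),
  lossRates = c(anc = 0.35, first = 0.05, inner = 0.03, REP = 0.05,
                ISL = 0.05),
  paternalBias = beta,
  accessionsPerTaxon = c(SYL = 3, TRI = 3, NUD = 3, REP = 3, ISL = 3),
  seed = seed)

zeroEventParams <- function(seed = 1) {
  fam <- simulationParams()$families
  fam$gainMean <- 0
  simulationParams(families = fam,
                   lossRates = c(anc = 0, first = 0, inner = 0,
                                 REP = 0, ISL = 0),
                   seed = seed)
}
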