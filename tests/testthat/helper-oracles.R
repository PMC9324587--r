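# Independent brute-force oracles and small fixture builders. Oracles
# deliberately avoid the package's vectorized code paths: loops and
# first-principles formulas only.

# ---- fixture builders -------------------------------------------------

makeIndex <- function(n, kind, prefix = substr(kind, 1, 3)) {
  EntityIndex(sprintf("%s%02d", prefix, seq_len(n)), kind)
}

randomSimilarity <- function(n, kind, lo = 0, hi = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, lo, hi)
  m <- m + t(m)
  diag(m) <- 1
  SimilarityMatrix(m, makeIndex(n, kind))
}

randomRawAssoc <- function(rowIdx, colIdx, p = 0.3) {
  nr <- length(entityNames(rowIdx))
  nc <- length(entityNames(colIdx))
  AssociationMatrix(matrix(rbinom(nr * nc, 1, p), nr, nc),
                    rowIdx, colIdx, stage = "raw")
}

# ---- disease-semantics oracle ----------------------------------------
# Per-pair, loop-based evaluation of both semantic models straight from
# the tree codes: ancestors by prefix truncation, model-1 contribution
# phi^(min distance), model-2 contribution -log(count / N, base).

oracleAncestors <- function(code) {
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  sapply(seq_along(parts), function(k) paste(parts[1:k], collapse = "."))
}

# nodes of one disease with min distance, terms resolved against the
# universe's code ownership (unowned ancestor codes are their own terms)
oracleDagNodes <- function(disease, treeNumbers) {
  owner <- character()
  for (d in names(treeNumbers))
    for (cd in treeNumbers[[d]])
      if (is.na(owner[cd])) owner[cd] <- d  # first owner, as in the package
  dist <- integer()
  for (code in treeNumbers[[disease]]) {
    chain <- oracleAncestors(code)
    for (k in seq_along(chain)) {
      t <- if (k == length(chain)) disease
           else if (!is.na(owner[chain[k]])) unname(owner[chain[k]])
           else chain[k]
      d <- length(chain) - k
      dist[t] <- if (is.na(dist[t])) d else min(dist[t], d)
    }
  }
  dist
}

oracleModelSim <- function(treeNumbers, model, phi = 0.5, logBase = exp(1)) {
  dn <- names(treeNumbers)
  dags <- lapply(dn, oracleDagNodes, treeNumbers = treeNumbers)
  names(dags) <- dn
  counts <- table(unlist(lapply(dags, names)))
  contribOf <- function(d) {
    if (model == 1) {
      phi ^ dags[[d]]
    } else {
      v <- -log(as.numeric(counts[names(dags[[d]])]) / length(dn),
                base = logBase)
      names(v) <- names(dags[[d]])
      v
    }
  }
  profs <- lapply(dn, contribOf)
  names(profs) <- dn
  m <- diag(length(dn))
  dimnames(m) <- list(dn, dn)
  for (a in dn) for (b in dn) {
    if (a == b) next
    shared <- intersect(names(profs[[a]]), names(profs[[b]]))
    den <- sum(profs[[a]]) + sum(profs[[b]])
    m[a, b] <- if (!length(shared) || den == 0) 0 else
      sum(profs[[a]][shared] + profs[[b]][shared]) / den
  }
  m
}

# ---- reconstruction oracle -------------------------------------------
# Quadruple-sum evaluation of the propagated weight, cell by cell.

oracleReconstruct <- function(SRowV, SColV, AV) {
  out <- matrix(0, nrow(AV), ncol(AV))
  for (a in seq_len(nrow(AV)))
    for (c in seq_len(ncol(AV)))
      out[a, c] <- sum(outer(SRowV[a, ], SColV[c, ]) * AV)
  out
}

# ---- path-scoring oracle ---------------------------------------------
# Exhaustive enumeration of both length-2 path shapes, cell by cell.

oraclePathScores <- function(SRowV, SColV, AV, beta) {
  e <- beta * 2
  out <- AV
  for (a in seq_len(nrow(AV)))
    for (c in seq_len(ncol(AV))) {
      s1 <- sum((SRowV[a, -a] * AV[-a, c]) ^ e)
      s2 <- if (ncol(AV) > 1) sum((AV[a, -c] * SColV[-c, c]) ^ e) else 0
      out[a, c] <- AV[a, c] + s1 + s2
    }
  out
}

# per-pair maximum path product feeding a score cell, for decay-limit
# checks (similarity paths on W1 plus drug-mediated products)
oracleMaxPathProduct <- function(S1f, S3f, A1n, W2r, W3r) {
  p <- nrow(A1n); r <- ncol(A1n)
  out <- matrix(0, p, r)
  for (a in seq_len(p))
    for (c in seq_len(r)) {
      m1 <- if (p > 1) max(S1f[a, -a] * A1n[-a, c]) else 0
      m2 <- if (r > 1) max(A1n[a, -c] * S3f[-c, c]) else 0
      m3 <- max(W2r[a, ] * W3r[, c])
      out[a, c] <- max(m1, m2, m3)
    }
  out
}

# ---- AUC oracle -------------------------------------------------------

oracleAUC <- function(pos, neg) {
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
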