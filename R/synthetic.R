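# Synthetic heterogeneous-network generator. Entities of all three
# layers are assigned to shared blocks; similarity is high within a
# block and low across, and associations concentrate in matched blocks.
# This realizes the modelling premise that similar miRNAs associate with
# similar diseases, so planted (masked) associations are recoverable by
# the path pipeline and every stage is testable without any download.

blockSimilarity <- function(n, blocks, withinSim, betweenSim, noise, names) {
  s <- ifelse(outer(blocks, blocks, `==`), withinSim, betweenSim)
  if (noise > 0) {
    jit <- matrix(stats::runif(n * n, -noise, noise), n, n)
    jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
    s <- s + jit
  }
  s[s < 0] <- 0
  s[s > 1] <- 1
  diag(s) <- 1
  dimnames(s) <- list(names, names)
  s
}

blockAssociations <- function(rowBlocks, colBlocks, density) {
  p <- ifelse(outer(rowBlocks, colBlocks, `==`), density, 0)
  m <- matrix(stats::runif(length(p)) < p, nrow(p), ncol(p)) * 1
  m
}

#' Generate a block-structured synthetic heterogeneous network
#'
#' miRNAs, drugs and diseases are assigned round-robin to `nBlocks`
#' shared blocks. Similarities are `withinSim` inside a block and
#' `betweenSim` across, jittered by additive uniform noise (clipped to
#' `[0, 1]`, symmetrized, unit diagonal). Associations are drawn
#' independently with probability `assocDensity` for block-matched pairs
#' (and never across blocks), in all three bipartite layers, so
#' drug-mediated paths are informative about the same block structure;
#' departures from clean block structure enter through the similarity
#' jitter, not through the association layers.
#' Optionally a fraction of the miRNA-disease positives is masked out as
#' recoverable truth.
#'
#' @param nMirna,nDrug,nDisease entity counts (defaults 20 / 10 / 20).
#' @param nBlocks number of shared blocks (default 4).
#' @param withinSim,betweenSim similarity levels inside / across blocks
#'   (defaults 0.9 / 0.1).
#' @param assocDensity association probability within matched blocks
#'   (default 0.3).
#' @param noise half-width of the additive uniform similarity jitter
#'   (default 0.05).
#' @param seed integer seed; identical seeds give identical bundles.
#' @param maskFraction fraction of miRNA-disease positives masked into
#'   the truth set (default 0: nothing masked).
#' @return A [SyntheticBundle-class].
#' @examples
#' b <- generateBlockNetwork(seed = 1)
#' b
#' @export
generateBlockNetwork <- function(nMirna = 20, nDrug = 10, nDisease = 20,
                                 nBlocks = 4, withinSim = 0.9,
                                 betweenSim = 0.1, assocDensity = 0.3,
                                 noise = 0.05, seed = 1,
                                 maskFraction = 0) {
  if (nBlocks > min(nMirna, nDrug, nDisease))
    stop("infeasible parameters: more blocks than entities in some layer")
  if (!(betweenSim >= 0 && betweenSim < withinSim && withinSim <= 1))
    stop("infeasible parameters: need 0 <= betweenSim < withinSim <= 1")
  mirnas <- sprintf("mir-%03d", seq_len(nMirna))
  drugs <- sprintf("drug-%03d", seq_len(nDrug))
  diseases <- sprintf("disease-%03d", seq_len(nDisease))
  bm <- (seq_len(nMirna) - 1L) %% nBlocks + 1L
  bb <- (seq_len(nDrug) - 1L) %% nBlocks + 1L
  bd <- (seq_len(nDisease) - 1L) %% nBlocks + 1L
  out <- withSeed(seed, {
    S1 <- blockSimilarity(nMirna, bm, withinSim, betweenSim, noise, mirnas)
    S2 <- blockSimilarity(nDrug, bb, withinSim, betweenSim, noise, drugs)
    S3 <- blockSimilarity(nDisease, bd, withinSim, betweenSim, noise,
                          diseases)
    A1 <- blockAssociations(bm, bd, assocDensity)
    A2 <- blockAssociations(bm, bb, assocDensity)
    A3 <- blockAssociations(bb, bd, assocDensity)
    list(S1 = S1, S2 = S2, S3 = S3, A1 = A1, A2 = A2, A3 = A3)
  })
  if (sum(out$A1) < 5)
    stop("infeasible parameters: fewer than 5 miRNA-disease positives drawn")
  mi <- EntityIndex(mirnas, "miRNA")
  di <- EntityIndex(drugs, "drug")
  si <- EntityIndex(diseases, "disease")
  A1 <- AssociationMatrix(out$A1, mi, si, stage = "raw")
  truth <- data.frame(mirna = character(), disease = character(),
                      stringsAsFactors = FALSE)
  if (maskFraction > 0) {
    masked <- maskAssociations(A1, maskFraction, seed = deriveSeed(seed, 77L))
    A1 <- masked$train
    truth <- masked$heldOut
  }
  # toy MeSH-like hierarchy: diseases of one block share a parent code
  treeNumbers <- as.list(sprintf("C%02d.%03d", bd, seq_len(nDisease)))
  names(treeNumbers) <- diseases
  new("SyntheticBundle",
      S1 = SimilarityMatrix(out$S1, mi),
      S2 = SimilarityMatrix(out$S2, di),
      S3 = SimilarityMatrix(out$S3, si),
      A1 = A1,
      A2 = AssociationMatrix(out$A2, mi, di, stage = "raw"),
      A3 = AssociationMatrix(out$A3, di, si, stage = "raw"),
      treeNumbers = treeNumbers, truth = truth, seed = as.integer(seed))
}

#' Mask a fraction of known associations as held-out truth
#'
#' Zeroes `ceiling(fraction * positives)` randomly chosen positives of a
#' raw association matrix and returns the training matrix together with
#' the held-out pair set; held-out and remaining positives are disjoint
#' by construction.
#'
#' @param A raw [AssociationMatrix-class] with at least one positive.
#' @param fraction fraction of positives to mask, in (0, 1).
#' @param seed integer seed.
#' @return List with elements `train` (the masked
#'   [AssociationMatrix-class]) and `heldOut` (data.frame with columns
#'   `mirna`, `disease` — named after the row/column kinds' canonical
#'   roles).
#' @export
maskAssociations <- function(A, fraction, seed = 1) {
  stopifnot(is(A, "AssociationMatrix"))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  v <- A@values
  pos <- which(v == 1)
  if (!length(pos)) stop("association matrix has no positives")
  k <- ceiling(fraction * length(pos))
  held <- withSeed(seed, sample(pos, k))
  v[held] <- 0
  i <- (held - 1L) %% nrow(v) + 1L
  j <- (held - 1L) %/% nrow(v) + 1L
  list(train = AssociationMatrix(v, A@rowIndex, A@colIndex, stage = "raw"),
       heldOut = data.frame(mirna = A@rowIndex@names[i],
                            disease = A@colIndex@names[j],
                            stringsAsFactors = FALSE))
}

#' Generate a complete toy disease hierarchy
#'
#' A complete tree of diseases with dot-separated tree codes; every
#' internal node and leaf is a disease, so a universe of depth `d` and
#' branching `b` has `(b^d - 1) / (b - 1)` diseases (or `d` when
#' `b = 1`).
#'
#' @param depth number of levels (>= 1).
#' @param branching children per node (>= 1).
#' @return Named list disease name -> tree code, consumable by
#'   [fusedDiseaseSimilarity()].
#' @examples
#' length(generateToyDagUniverse(3, 2))  # 7
#' @export
generateToyDagUniverse <- function(depth, branching = 2) {
  stopifnot(depth >= 1, branching >= 1)
  codes <- "D01"
  frontier <- codes
  for (lev in seq_len(depth - 1)) {
    frontier <- as.vector(vapply(frontier, function(p)
      sprintf("%s.%03d", p, seq_len(branching)), character(branching)))
    codes <- c(codes, frontier)
  }
  out <- as.list(codes)
  names(out) <- paste0("disease-", tolower(codes))
  out
}
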