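# Path-based association scoring on the three-layer heterogeneous
# network. Each two-layer (similarity + bipartite) network is scored by
# enumerating all simple paths of length at most 2 between a row entity
# and a column entity; a path of length 2 contributes its edge-weight
# product raised to the decay exponent fdecay(len) = beta * len, so
# longer, less reliable evidence is attenuated (weights lie in [0, 1]).
# Finally direct miRNA-disease path weights and drug-mediated
# miRNA-drug-disease products are integrated into the association score.

#' Path-length decay exponent
#'
#' `fdecay(p) = beta * len(p)`: the exponent applied to a path's
#' edge-weight product. With the default `beta = 7` a length-2 path is
#' penalized by the 14th power of its weight product.
#'
#' @param pathLength number of edges of the path (>= 1).
#' @param beta decay factor (> 0).
#' @return The exponent value `beta * pathLength`.
#' @examples
#' fdecay(2, 7)   # 14
#' @export
fdecay <- function(pathLength, beta) {
  stopifnot(pathLength >= 1, beta > 0)
  beta * pathLength
}

#' Assemble the three-layer heterogeneous network
#'
#' Checks index consistency of the three filtered similarity layers and
#' the three normalized bipartite layers and bundles them; no numeric
#' change. The drug layer must be non-empty (three layers required).
#'
#' @param S1,S2,S3 filtered [SimilarityMatrix-class] (miRNA, drug,
#'   disease).
#' @param A1,A2,A3 normalized [AssociationMatrix-class] (miRNA-disease,
#'   miRNA-drug, drug-disease).
#' @return A [HeteroNetwork-class].
#' @export
assembleThreeLayer <- function(S1, S2, S3, A1, A2, A3) {
  new("HeteroNetwork", S1 = S1, S2 = S2, S3 = S3,
      A1 = A1, A2 = A2, A3 = A3)
}

# Core length-2 enumeration in closed form. Because the decay exponent
# distributes over the product ((x*y)^e = x^e * y^e) the sum over all
# similarity->association paths is (S_row^e) %*% (A^e) with zeroed
# diagonals, and association->similarity paths are (A^e) %*% (S_col^e).
# Zero-weight entries are absent edges and contribute nothing (0^e = 0).
pathSum2 <- function(SRowV, SColV, AV, expo) {
  Sr <- SRowV; diag(Sr) <- 0
  Sc <- SColV; diag(Sc) <- 0
  (Sr ^ expo) %*% (AV ^ expo) + (AV ^ expo) %*% (Sc ^ expo)
}

#' Score one two-layer network by decay-penalized paths
#'
#' `W(a, c) = A(a, c) + sum over simple length-2 paths p from a to c of
#' (prod of edge weights of p) ^ fdecay(2)`. Eligible length-2 shapes are
#' similarity-then-association (a -> a' -> c) and
#' association-then-similarity (a -> c' -> c). Applied identically to the
#' miRNA-disease, miRNA-drug and drug-disease two-layer networks.
#'
#' @param SRow,SCol filtered [SimilarityMatrix-class] over rows/columns.
#' @param A normalized [AssociationMatrix-class].
#' @param params [PathParams-class]; only `pathLength = 2` is supported.
#' @return A [ScoreMatrix-class] of path weights.
#' @export
twoLayerPathScores <- function(SRow, SCol, A, params = PathParams()) {
  stopifnot(is(SRow, "SimilarityMatrix"), is(SCol, "SimilarityMatrix"),
            is(A, "AssociationMatrix"), is(params, "PathParams"))
  if (params@pathLength != 2L)
    stop("unsupported parameter: only path length 2 is implemented")
  if (!identical(A@rowIndex@names, SRow@index@names) ||
      !identical(A@colIndex@names, SCol@index@names))
    stop("index mismatch between association matrix and similarity layers")
  expo <- fdecay(2L, params@beta)
  w <- A@values + pathSum2(SRow@values, SCol@values, A@values, expo)
  ScoreMatrix(w, A@rowIndex, A@colIndex)
}

#' Integrate direct and drug-mediated path weights
#'
#' `Score(a, c) = W1(a, c) + sum over drugs b of
#' (W2(a, b) * W3(b, c)) ^ fdecay(2)`: the direct miRNA-disease path
#' weight plus the decay-penalized contribution of every
#' miRNA-drug-disease path. `W2` and `W3` are used as given; rescale them
#' to `[0, 1]` beforehand (as [predictAssociations()] does) so the
#' exponent remains a decay.
#'
#' @param W1 [ScoreMatrix-class] of direct miRNA-disease path weights.
#' @param W2 [ScoreMatrix-class] of miRNA-drug path weights.
#' @param W3 [ScoreMatrix-class] of drug-disease path weights.
#' @param params [PathParams-class].
#' @return The final [ScoreMatrix-class] of association scores.
#' @export
integrateScores <- function(W1, W2, W3, params = PathParams()) {
  stopifnot(is(W1, "ScoreMatrix"), is(W2, "ScoreMatrix"),
            is(W3, "ScoreMatrix"))
  if (!identical(W2@colIndex@names, W3@rowIndex@names) ||
      !identical(W1@rowIndex@names, W2@rowIndex@names) ||
      !identical(W1@colIndex@names, W3@colIndex@names))
    stop("index mismatch among W1, W2, W3")
  expo <- fdecay(2L, params@beta)
  v <- W1@values + (W2@values ^ expo) %*% (W3@values ^ expo)
  ScoreMatrix(v, W1@rowIndex, W1@colIndex)
}

rescaleByMax <- function(W) {
  m <- max(W@values)
  if (m > 0) ScoreMatrix(W@values / m, W@rowIndex, W@colIndex) else W
}

#' Predict miRNA-disease association scores (full pipeline)
#'
#' Runs the complete deterministic pipeline: threshold pruning of the
#' three similarity layers, bipartite reconstruction and global-max
#' normalization of the three association layers, assembly of the
#' three-layer heterogeneous network, length-2 path scoring of each
#' two-layer network, optional rescaling of the miRNA-drug and
#' drug-disease path weights by their global maximum, and integration of
#' direct and drug-mediated paths.
#'
#' @param S1,S2,S3 raw [SimilarityMatrix-class] layers (miRNA functional,
#'   drug chemical, disease semantic).
#' @param A1,A2,A3 raw [AssociationMatrix-class] layers (miRNA-disease,
#'   miRNA-drug, drug-disease).
#' @param params [PathParams-class].
#' @return A [ScoreMatrix-class] of miRNA-disease association scores.
#' @export
predictAssociations <- function(S1, S2, S3, A1, A2, A3,
                                params = PathParams()) {
  S1f <- thresholdNeighbors(S1, params@threshold)
  S2f <- thresholdNeighbors(S2, params@threshold)
  S3f <- thresholdNeighbors(S3, params@threshold)
  A1n <- normalizeGlobalMax(reconstructBipartite(S1f, S3f, A1))
  A2n <- normalizeGlobalMax(reconstructBipartite(S1f, S2f, A2))
  A3n <- normalizeGlobalMax(reconstructBipartite(S2f, S3f, A3))
  net <- assembleThreeLayer(S1f, S2f, S3f, A1n, A2n, A3n)
  W1 <- twoLayerPathScores(net@S1, net@S3, net@A1, params)
  W2 <- twoLayerPathScores(net@S1, net@S2, net@A2, params)
  W3 <- twoLayerPathScores(net@S2, net@S3, net@A3, params)
  if (params@rescale) {
    W2 <- rescaleByMax(W2)
    W3 <- rescaleByMax(W3)
  }
  integrateScores(W1, W2, W3, params)
}

#' Predict from a synthetic bundle
#'
#' Convenience wrapper running [predictAssociations()] on the six layers
#' of a [SyntheticBundle-class].
#'
#' @param bundle a [SyntheticBundle-class].
#' @param params [PathParams-class].
#' @return A [ScoreMatrix-class].
#' @export
predictBundle <- function(bundle, params = PathParams()) {
  stopifnot(is(bundle, "SyntheticBundle"))
  predictAssociations(bundle@S1, bundle@S2, bundle@S3,
                      bundle@A1, bundle@A2, bundle@A3, params)
}
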