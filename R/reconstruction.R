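# Bipartite network reconstruction: similarity-propagated weighted sums
# with threshold pruning, then global-max normalization. Reconstruction
# gives isolated entities (no raw associations) informative weighted
# edges through their retained similar neighbors.

#' Prune weak similarity neighbors
#'
#' Sets off-diagonal similarities below the threshold `T` to 0. An entity
#' whose off-diagonal similarities all fall below the threshold keeps its
#' single most similar neighbor instead (all ties at the maximum are
#' retained; a neighbor is only kept if its similarity is positive). The
#' result is re-symmetrized by keeping an edge if either endpoint kept
#' it; the diagonal is untouched.
#'
#' @param S a [SimilarityMatrix-class].
#' @param threshold similarity threshold in `[0, 1]`.
#' @return The filtered [SimilarityMatrix-class].
#' @examples
#' idx <- EntityIndex(c("a", "b", "c"), "miRNA")
#' S <- SimilarityMatrix(matrix(c(1, .8, .3, .8, 1, .2, .3, .2, 1), 3), idx)
#' simValues(thresholdNeighbors(S, 0.7))
#' @export
thresholdNeighbors <- function(S, threshold) {
  stopifnot(is(S, "SimilarityMatrix"), threshold >= 0, threshold <= 1)
  v <- S@values
  n <- nrow(v)
  off <- v
  diag(off) <- NA_real_
  keep <- !is.na(off) & off >= threshold
  for (i in seq_len(n)) {
    if (n > 1L && !any(keep[i, ])) {
      m <- max(off[i, ], na.rm = TRUE)
      if (m > 0) keep[i, which(!is.na(off[i, ]) & off[i, ] == m)] <- TRUE
    }
  }
  keep <- keep | t(keep)  # edge survives if either endpoint kept it
  out <- v
  out[!keep] <- 0
  diag(out) <- 1
  SimilarityMatrix(out, S@index)
}

#' Reconstruct a bipartite association network
#'
#' Replaces the binary association matrix `A` by similarity-propagated
#' weighted sums: the reconstructed weight of a pair is the sum, over the
#' threshold-surviving neighbors of both endpoints (each entity included
#' with self-similarity 1), of the product of the two similarities and
#' the raw association — in matrix form `S_row %*% A %*% t(S_col)` with
#' the filtered similarity matrices.
#'
#' @param SRow filtered [SimilarityMatrix-class] over the row entities.
#' @param SCol filtered [SimilarityMatrix-class] over the column entities.
#' @param A raw [AssociationMatrix-class].
#' @return An [AssociationMatrix-class] at stage `"reconstructed"`.
#' @export
reconstructBipartite <- function(SRow, SCol, A) {
  stopifnot(is(SRow, "SimilarityMatrix"), is(SCol, "SimilarityMatrix"),
            is(A, "AssociationMatrix"))
  if (A@stage != "raw") stop("reconstruction expects a raw matrix")
  if (!identical(A@rowIndex@names, SRow@index@names) ||
      !identical(A@colIndex@names, SCol@index@names))
    stop("index mismatch between association matrix and similarity layers")
  v <- SRow@values %*% A@values %*% t(SCol@values)
  AssociationMatrix(v, A@rowIndex, A@colIndex, stage = "reconstructed")
}

#' Normalize a reconstructed matrix by its global maximum
#'
#' Divides every entry by the single largest reconstruction weight of the
#' matrix, so weights are comparable across the three bipartite layers.
#' An all-zero matrix is returned unchanged.
#'
#' @param APrime a reconstructed [AssociationMatrix-class] (any
#'   nonnegative matrix is accepted).
#' @return An [AssociationMatrix-class] at stage `"normalized"`.
#' @export
normalizeGlobalMax <- function(APrime) {
  stopifnot(is(APrime, "AssociationMatrix"))
  v <- APrime@values
  m <- max(v)
  if (m > 0) v <- v / m
  AssociationMatrix(v, APrime@rowIndex, APrime@colIndex,
                    stage = "normalized")
}
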