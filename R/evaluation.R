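# Cross-validated evaluation: repeated five-fold CV over the known
# miRNA-disease positives and global leave-one-out CV, both scored by
# rank-based AUC against all pairs never known positive.

#' Rank-based AUC from positive and negative score lists
#'
#' Mann-Whitney form: the probability that a random positive outranks a
#' random negative, with ties contributing 1/2.
#'
#' @param pos,neg non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' aucFromScores(c(0.9), c(0.1, 0.5))  # 1
#' aucFromScores(c(0.5), c(0.5))       # 0.5
#' @export
aucFromScores <- function(pos, neg) {
  if (!length(pos) || !length(neg))
    stop("both score lists must be non-empty")
  r <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

# Accept a SyntheticBundle or a plain named list of the six layers.
asLayerList <- function(inputs) {
  if (is(inputs, "SyntheticBundle")) return(bundleLayers(inputs))
  need <- c("S1", "S2", "S3", "A1", "A2", "A3")
  if (!is.list(inputs) || !all(need %in% names(inputs)))
    stop("inputs must be a SyntheticBundle or a named list with S1..S3, A1..A3")
  inputs[need]
}

runPredictWithA1 <- function(layers, A1values, params) {
  A1 <- AssociationMatrix(A1values, layers$A1@rowIndex,
                          layers$A1@colIndex, stage = "raw")
  scoreValues(predictAssociations(layers$S1, layers$S2, layers$S3,
                                  A1, layers$A2, layers$A3, params))
}

#' Repeated five-fold cross-validation
#'
#' The known miRNA-disease positives are partitioned at random into
#' `nFolds` groups; the positives of each group in turn are zeroed in the
#' association matrix, the full prediction pipeline is re-run, and the
#' held-out positives are scored. Per repeat, one pooled AUC ranks all
#' held-out positives (each scored in its own fold's run) against all
#' pairs never known positive (negative scores pooled over the fold
#' runs); a secondary fold-averaged AUC is also recorded. Repeats use
#' deterministically derived sub-seeds.
#'
#' @param inputs a [SyntheticBundle-class] or named list with elements
#'   `S1`, `S2`, `S3` ([SimilarityMatrix-class]) and `A1`, `A2`, `A3`
#'   (raw [AssociationMatrix-class]).
#' @param params [PathParams-class].
#' @param nRepeats number of repeats (default 5; the full protocol uses
#'   100).
#' @param seed integer seed driving the fold partitions.
#' @param nFolds number of folds (default 5).
#' @return A [CVResult-class].
#' @export
fiveFoldCV <- function(inputs, params = PathParams(), nRepeats = 5,
                       seed = 1, nFolds = 5) {
  layers <- asLayerList(inputs)
  A1v <- assocValues(layers$A1)
  pos <- which(A1v == 1)
  if (length(pos) < nFolds)
    stop(sprintf("need at least %d positives for %d-fold CV", nFolds, nFolds))
  negMask <- A1v == 0
  aucPooled <- numeric(nRepeats)
  aucFoldMean <- numeric(nRepeats)
  for (r in seq_len(nRepeats)) {
    folds <- withSeed(deriveSeed(seed, r),
                      sample(rep(seq_len(nFolds), length.out = length(pos))))
    posScores <- numeric(length(pos))
    negPool <- vector("list", nFolds)
    aucFold <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      held <- pos[folds == f]
      Atr <- A1v
      Atr[held] <- 0
      sc <- runPredictWithA1(layers, Atr, params)
      posScores[folds == f] <- sc[held]
      negPool[[f]] <- sc[negMask]
      aucFold[f] <- aucFromScores(sc[held], sc[negMask])
    }
    aucPooled[r] <- aucFromScores(posScores, unlist(negPool))
    aucFoldMean[r] <- mean(aucFold)
  }
  new("CVResult", aucPerRepeat = aucPooled,
      aucPerRepeatFoldMean = aucFoldMean, meanAuc = mean(aucPooled),
      params = params, nFolds = as.integer(nFolds),
      nRepeats = as.integer(nRepeats), seed = as.integer(seed))
}

#' Global leave-one-out cross-validation
#'
#' Each known positive is zeroed in turn, the pipeline re-run, and the
#' held-out pair's score ranked against all never-known pairs of that
#' run; the reported AUC is the mean over leave-outs of the per-positive
#' Mann-Whitney fraction. Deterministic: no randomness is involved.
#'
#' @inheritParams fiveFoldCV
#' @return AUC value in `[0, 1]`.
#' @export
globalLOOCV <- function(inputs, params = PathParams()) {
  layers <- asLayerList(inputs)
  A1v <- assocValues(layers$A1)
  pos <- which(A1v == 1)
  if (length(pos) < 2L) stop("need at least 2 positives for LOOCV")
  negMask <- A1v == 0
  nneg <- sum(negMask)
  frac <- vapply(pos, function(k) {
    Atr <- A1v
    Atr[k] <- 0
    sc <- runPredictWithA1(layers, Atr, params)
    s <- sc[k]
    neg <- sc[negMask]
    (sum(neg < s) + 0.5 * sum(neg == s)) / nneg
  }, 0)
  mean(frac)
}

#' Sweep the similarity threshold and decay factor
#'
#' Evaluates [fiveFoldCV()] on the cartesian grid of threshold and decay
#' values and returns (optionally writes) the table of mean AUCs. The
#' default grids are threshold 0.3 to 0.8 in steps of 0.1 and decay 2 to
#' 7 in steps of 1 (36 points).
#'
#' @inheritParams fiveFoldCV
#' @param thresholdValues numeric grid of similarity thresholds.
#' @param betaValues numeric grid of decay factors.
#' @param path optional TSV output path.
#' @return data.frame with columns `threshold`, `beta`, `meanAuc`.
#' @export
parameterSweep <- function(inputs, thresholdValues = seq(0.3, 0.8, by = 0.1),
                           betaValues = seq(2, 7, by = 1),
                           params = PathParams(), nRepeats = 5, seed = 1,
                           path = NULL) {
  if (!length(thresholdValues) || !length(betaValues))
    stop("empty parameter grid")
  grid <- expand.grid(threshold = thresholdValues, beta = betaValues,
                      KEEP.OUT.ATTRS = FALSE)
  grid$meanAuc <- vapply(seq_len(nrow(grid)), function(k) {
    p <- PathParams(threshold = grid$threshold[k],
                    pathLength = params@pathLength, beta = grid$beta[k],
                    phi = params@phi, rescale = params@rescale)
    meanAUC(fiveFoldCV(inputs, p, nRepeats = nRepeats, seed = seed))
  }, 0)
  if (!is.null(path))
    utils::write.table(grid, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  grid
}
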