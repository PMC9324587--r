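#' Accessors for triNetPath classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param names character vector of entity names to look up.
#' @name accessors
NULL

#' @describeIn accessors canonical entity names of an index (or of a
#'   similarity matrix's index).
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))

#' @export
setMethod("entityNames", "EntityIndex", function(x) x@names)

#' @export
setMethod("entityNames", "SimilarityMatrix", function(x) x@index@names)

#' @describeIn accessors entity kind of an index.
#' @export
setGeneric("entityKind", function(x) standardGeneric("entityKind"))

#' @export
setMethod("entityKind", "EntityIndex", function(x) x@kind)

#' @describeIn accessors positions of (possibly un-normalized) names in an
#'   index; `NA` where unknown.
#' @export
entityPosition <- function(x, names) {
  stopifnot(is(x, "EntityIndex"))
  match(normalizeEntityName(names), x@names)
}

#' @describeIn accessors numeric values of a similarity matrix.
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' @export
setMethod("simValues", "SimilarityMatrix", function(x) x@values)

#' @describeIn accessors the index of a similarity matrix.
#' @export
setGeneric("simIndex", function(x) standardGeneric("simIndex"))

#' @export
setMethod("simIndex", "SimilarityMatrix", function(x) x@index)

#' @describeIn accessors numeric values of an association matrix.
#' @export
setGeneric("assocValues", function(x) standardGeneric("assocValues"))

#' @export
setMethod("assocValues", "AssociationMatrix", function(x) x@values)

#' @describeIn accessors processing stage of an association matrix.
#' @export
setGeneric("assocStage", function(x) standardGeneric("assocStage"))

#' @export
setMethod("assocStage", "AssociationMatrix", function(x) x@stage)

#' @describeIn accessors row index of a rectangular matrix object.
#' @export
setGeneric("rowIndex", function(x) standardGeneric("rowIndex"))

#' @export
setMethod("rowIndex", "AssociationMatrix", function(x) x@rowIndex)

#' @export
setMethod("rowIndex", "ScoreMatrix", function(x) x@rowIndex)

#' @describeIn accessors column index of a rectangular matrix object.
#' @export
setGeneric("colIndex", function(x) standardGeneric("colIndex"))

#' @export
setMethod("colIndex", "AssociationMatrix", function(x) x@colIndex)

#' @export
setMethod("colIndex", "ScoreMatrix", function(x) x@colIndex)

#' @describeIn accessors numeric values of a score matrix.
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@values)

#' @describeIn accessors per-node semantic contributions of a profile.
#' @export
setGeneric("profileContrib", function(x) standardGeneric("profileContrib"))

#' @export
setMethod("profileContrib", "SemanticProfile", function(x) x@contrib)

#' @describeIn accessors total semantic value of a profile.
#' @export
setGeneric("profileTotal", function(x) standardGeneric("profileTotal"))

#' @export
setMethod("profileTotal", "SemanticProfile", function(x) x@total)

#' @describeIn accessors node layers (minimum hop distance from the
#'   disease term) of a disease DAG.
#' @export
setGeneric("dagLayers", function(x) standardGeneric("dagLayers"))

#' @export
setMethod("dagLayers", "DiseaseDAG", function(x) x@layer)

#' @describeIn accessors node terms of a disease DAG.
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))

#' @export
setMethod("dagNodes", "DiseaseDAG", function(x) names(x@layer))

#' @describeIn accessors mean pooled AUC of a cross-validation result.
#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))

#' @export
setMethod("meanAUC", "CVResult", function(x) x@meanAuc)

#' @describeIn accessors pooled AUC per repeat.
#' @export
setGeneric("aucPerRepeat", function(x) standardGeneric("aucPerRepeat"))

#' @export
setMethod("aucPerRepeat", "CVResult", function(x) x@aucPerRepeat)

#' @describeIn accessors secondary fold-averaged AUC per repeat.
#' @export
setGeneric("aucPerRepeatFoldMean",
           function(x) standardGeneric("aucPerRepeatFoldMean"))

#' @export
setMethod("aucPerRepeatFoldMean", "CVResult",
          function(x) x@aucPerRepeatFoldMean)

#' @describeIn accessors the six network layers of a synthetic bundle as a
#'   named list (`S1`, `S2`, `S3`, `A1`, `A2`, `A3`).
#' @export
setGeneric("bundleLayers", function(x) standardGeneric("bundleLayers"))

#' @export
setMethod("bundleLayers", "SyntheticBundle", function(x)
  list(S1 = x@S1, S2 = x@S2, S3 = x@S3, A1 = x@A1, A2 = x@A2, A3 = x@A3))

#' @describeIn accessors tree-number hierarchy of a synthetic bundle.
#' @export
setGeneric("bundleTreeNumbers",
           function(x) standardGeneric("bundleTreeNumbers"))

#' @export
setMethod("bundleTreeNumbers", "SyntheticBundle", function(x) x@treeNumbers)

#' @describeIn accessors masked truth pairs of a synthetic bundle.
#' @export
setGeneric("bundleTruth", function(x) standardGeneric("bundleTruth"))

#' @export
setMethod("bundleTruth", "SyntheticBundle", function(x) x@truth)

setMethod("show", "EntityIndex", function(object) {
  cat(sprintf("EntityIndex of %d %s entities\n", length(object@names),
              object@kind))
  cat("  ", paste(utils::head(object@names, 5), collapse = ", "),
      if (length(object@names) > 5) ", ..." else "", "\n", sep = "")
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d x %d (%s)\n",
              nrow(object@values), ncol(object@values), object@index@kind))
})

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix [%s]: %d %s x %d %s, %d nonzero\n",
              object@stage, nrow(object@values), object@rowIndex@kind,
              ncol(object@values), object@colIndex@kind,
              sum(object@values > 0)))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d %s x %d %s, score range [%.4g, %.4g]\n",
              nrow(object@values), object@rowIndex@kind,
              ncol(object@values), object@colIndex@kind,
              min(object@values), max(object@values)))
})

setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG for '%s': %d nodes, max layer %d\n",
              object@disease, length(object@layer), max(object@layer)))
})

setMethod("show", "SemanticProfile", function(object) {
  cat(sprintf("SemanticProfile: %d nodes, total %.4f\n",
              length(object@contrib), object@total))
})

setMethod("show", "PathParams", function(object) {
  cat(sprintf(
    "PathParams: threshold=%.2f, L=%d, beta=%.1f, phi=%.2f, rescale=%s\n",
    object@threshold, object@pathLength, object@beta, object@phi,
    object@rescale))
})

setMethod("show", "HeteroNetwork", function(object) {
  cat(sprintf(
    "HeteroNetwork: %d miRNAs, %d drugs, %d diseases\n",
    length(object@S1@index@names), length(object@S2@index@names),
    length(object@S3@index@names)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: %d-fold x %d repeats, mean AUC %.4f (fold-mean %.4f)\n",
    object@nFolds, object@nRepeats, object@meanAuc,
    mean(object@aucPerRepeatFoldMean)))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat(sprintf(
    "SyntheticBundle (seed %d): %d miRNAs, %d drugs, %d diseases; %d known M-DAs, %d masked truth pairs\n",
    object@seed, length(object@S1@index@names),
    length(object@S2@index@names), length(object@S3@index@names),
    sum(object@A1@values > 0), nrow(object@truth)))
})
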