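#' @import methods
NULL

#' EntityIndex: a stable name-to-position mapping for one node set
#'
#' Holds the ordered, case-normalized identifiers of one of the three node
#' sets of the heterogeneous network (miRNAs, drugs or diseases). All
#' matrices in the package carry an `EntityIndex` per dimension so that
#' rows/columns are addressable by name and permutation-safe.
#'
#' Names are stored in canonical form: lower-cased, trimmed, with internal
#' whitespace collapsed. Duplicates after normalization collapse to the
#' first occurrence, preserving first-occurrence order.
#'
#' @slot names character vector of unique canonical entity names.
#' @slot kind one of `"miRNA"`, `"drug"`, `"disease"`.
#' @exportClass EntityIndex
setClass("EntityIndex",
  representation(names = "character", kind = "character"))

setValidity("EntityIndex", function(object) {
  msgs <- character()
  if (length(object@names) == 0L)
    msgs <- c(msgs, "index must contain at least one entity")
  if (length(object@kind) != 1L ||
      !object@kind %in% c("miRNA", "drug", "disease"))
    msgs <- c(msgs, "kind must be one of 'miRNA', 'drug', 'disease'")
  if (anyDuplicated(normalizeEntityName(object@names)))
    msgs <- c(msgs, "entity names not unique after normalization")
  if (length(msgs)) msgs else TRUE
})

#' Build an EntityIndex from raw names
#'
#' @param names character vector of entity identifiers (non-empty).
#' @param kind entity kind: `"miRNA"`, `"drug"` or `"disease"`.
#' @return An [EntityIndex-class] object. Duplicates after case/whitespace
#'   normalization are collapsed to the first occurrence.
#' @examples
#' idx <- EntityIndex(c("mir-21", "MIR-21 ", "mir-155"), "miRNA")
#' length(entityNames(idx))  # 2
#' @export
EntityIndex <- function(names, kind = c("miRNA", "drug", "disease")) {
  kind <- match.arg(kind)
  if (length(names) == 0L) stop("'names' must be a non-empty character vector")
  norm <- normalizeEntityName(names)
  if (any(!nzchar(norm))) stop("blank entity name")
  new("EntityIndex", names = norm[!duplicated(norm)], kind = kind)
}

#' SimilarityMatrix: square entity-by-entity similarity in [0, 1]
#'
#' Wraps a symmetric similarity matrix with unit diagonal over one
#' [EntityIndex-class]. Houses the miRNA functional similarity, drug
#' chemical similarity and fused disease semantic similarity layers, as
#' well as their threshold-filtered forms.
#'
#' @slot values numeric matrix, symmetric (tolerance 1e-9), diagonal 1,
#'   entries in `[0, 1]`.
#' @slot index the [EntityIndex-class] labelling both dimensions.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(values = "matrix", index = "EntityIndex"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@index@names)
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (nrow(v) != n || ncol(v) != n)
    msgs <- c(msgs, "matrix dimensions do not match index size")
  else {
    if (any(abs(v - t(v)) > 1e-9)) msgs <- c(msgs, "matrix not symmetric")
    if (any(abs(diag(v) - 1) > 1e-9)) msgs <- c(msgs, "diagonal must equal 1")
    if (any(v < -1e-9) || any(v > 1 + 1e-9))
      msgs <- c(msgs, "entries outside [0, 1]")
    if (!identical(rownames(v), object@index@names) ||
        !identical(colnames(v), object@index@names))
      msgs <- c(msgs, "dimnames do not match index names")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values square numeric matrix in `[0, 1]`, symmetric; the diagonal
#'   is forced to 1.
#' @param index [EntityIndex-class] for both dimensions.
#' @return A [SimilarityMatrix-class].
#' @export
SimilarityMatrix <- function(values, index) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  diag(values) <- 1
  dimnames(values) <- list(index@names, index@names)
  new("SimilarityMatrix", values = values, index = index)
}

#' AssociationMatrix: rectangular bipartite association weights
#'
#' A nonnegative matrix over two entity sets, tagged with its processing
#' stage: `"raw"` (binary 0/1 experimentally confirmed associations),
#' `"reconstructed"` (similarity-propagated weights) or `"normalized"`
#' (reconstructed weights divided by their global maximum).
#'
#' @slot values numeric matrix, entries >= 0; binary when stage is raw.
#' @slot rowIndex,colIndex [EntityIndex-class] objects for the dimensions.
#' @slot stage one of `"raw"`, `"reconstructed"`, `"normalized"`.
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
  representation(values = "matrix", rowIndex = "EntityIndex",
                 colIndex = "EntityIndex", stage = "character"))

setValidity("AssociationMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!object@stage %in% c("raw", "reconstructed", "normalized"))
    msgs <- c(msgs, "stage must be raw, reconstructed or normalized")
  if (nrow(v) != length(object@rowIndex@names) ||
      ncol(v) != length(object@colIndex@names))
    msgs <- c(msgs, "matrix dimensions do not match indices")
  if (any(v < 0)) msgs <- c(msgs, "entries must be nonnegative")
  if (identical(object@stage, "raw") && !all(v %in% c(0, 1)))
    msgs <- c(msgs, "raw matrices must be binary 0/1")
  if (identical(object@stage, "normalized") && any(v > 0) &&
      abs(max(v) - 1) > 1e-9)
    msgs <- c(msgs, "normalized matrices must have maximum entry 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AssociationMatrix
#'
#' @param values numeric matrix of association weights.
#' @param rowIndex,colIndex [EntityIndex-class] objects for rows / columns.
#' @param stage processing stage (`"raw"`, `"reconstructed"`,
#'   `"normalized"`).
#' @return An [AssociationMatrix-class].
#' @export
AssociationMatrix <- function(values, rowIndex, colIndex, stage = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(rowIndex@names, colIndex@names)
  new("AssociationMatrix", values = values, rowIndex = rowIndex,
      colIndex = colIndex, stage = stage)
}

#' ScoreMatrix: miRNA-by-disease (or intermediate) association scores
#'
#' Holds the path-based association scores. Every stage of the scoring
#' pipeline only adds nonnegative path contributions, so a final score
#' matrix dominates, entrywise, the normalized direct-association matrix
#' it was built from (checked in the test suite, not enforceable from the
#' object alone).
#'
#' @slot values nonnegative finite numeric matrix.
#' @slot rowIndex,colIndex [EntityIndex-class] objects.
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  representation(values = "matrix", rowIndex = "EntityIndex",
                 colIndex = "EntityIndex"))

setValidity("ScoreMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != length(object@rowIndex@names) ||
      ncol(v) != length(object@colIndex@names))
    msgs <- c(msgs, "matrix dimensions do not match indices")
  if (any(!is.finite(v))) msgs <- c(msgs, "scores must be finite")
  if (any(v < 0)) msgs <- c(msgs, "scores must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

ScoreMatrix <- function(values, rowIndex, colIndex) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(rowIndex@names, colIndex@names)
  new("ScoreMatrix", values = values, rowIndex = rowIndex,
      colIndex = colIndex)
}

#' PathParams: tuning parameters of the path model
#'
#' @slot threshold similarity threshold T in `[0, 1]` below which
#'   off-diagonal similarity edges are pruned (default 0.7).
#' @slot pathLength maximum path length L in edges; only L = 2 is
#'   supported by the scoring model (default 2).
#' @slot beta decay factor of the path penalty exponent
#'   `fdecay(p) = beta * len(p)` (default 7).
#' @slot phi semantic contribution factor for disease DAG similarity,
#'   in (0, 1) (default 0.5).
#' @slot rescale logical; rescale the miRNA-drug and drug-disease path
#'   weight matrices by their global maximum before integrating
#'   drug-mediated paths (default TRUE).
#' @exportClass PathParams
setClass("PathParams",
  representation(threshold = "numeric", pathLength = "integer",
                 beta = "numeric", phi = "numeric", rescale = "logical"))

setValidity("PathParams", function(object) {
  msgs <- character()
  if (object@threshold < 0 || object@threshold > 1)
    msgs <- c(msgs, "threshold must lie in [0, 1]")
  if (object@pathLength < 1L) msgs <- c(msgs, "pathLength must be >= 1")
  if (object@beta <= 0) msgs <- c(msgs, "beta must be positive")
  if (object@phi <= 0 || object@phi >= 1)
    msgs <- c(msgs, "phi must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Construct path-model parameters
#'
#' @param threshold similarity threshold T (default 0.7).
#' @param pathLength maximum path length L in edges (default 2, the only
#'   supported value for scoring).
#' @param beta decay factor (default 7).
#' @param phi semantic contribution factor (default 0.5).
#' @param rescale rescale W2/W3 by their global max before integration.
#' @return A [PathParams-class] object.
#' @export
PathParams <- function(threshold = 0.7, pathLength = 2L, beta = 7,
                       phi = 0.5, rescale = TRUE) {
  new("PathParams", threshold = as.numeric(threshold),
      pathLength = as.integer(pathLength), beta = as.numeric(beta),
      phi = as.numeric(phi), rescale = isTRUE(rescale))
}

#' DiseaseDAG: a disease and its MeSH ancestor graph
#'
#' The directed acyclic graph of one disease term plus all its ancestors,
#' derived from dot-separated MeSH tree numbers by prefix truncation. A
#' term occupying several tree positions is a single node; the layer of a
#' node is its minimum hop distance upward from the disease term (0 for
#' the disease itself).
#'
#' @slot disease canonical disease name.
#' @slot layer named integer vector: node term -> minimum distance from
#'   the disease term; includes the disease at layer 0.
#' @slot edges two-column character matrix of parent -> child links.
#' @exportClass DiseaseDAG
setClass("DiseaseDAG",
  representation(disease = "character", layer = "integer",
                 edges = "matrix"))

setValidity("DiseaseDAG", function(object) {
  msgs <- character()
  lay <- object@layer
  if (is.null(names(lay)) || anyDuplicated(names(lay)))
    msgs <- c(msgs, "layer must be uniquely named by node term")
  if (!(object@disease %in% names(lay)) || lay[[object@disease]] != 0L)
    msgs <- c(msgs, "disease term must be a node at layer 0")
  if (any(lay < 0L)) msgs <- c(msgs, "layers must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' SemanticProfile: per-ancestor semantic contributions of a disease
#'
#' @slot contrib named numeric vector of nonnegative contribution values,
#'   one per DAG node.
#' @slot total sum of the contributions (the disease's semantic value).
#' @exportClass SemanticProfile
setClass("SemanticProfile",
  representation(contrib = "numeric", total = "numeric"))

setValidity("SemanticProfile", function(object) {
  msgs <- character()
  if (is.null(names(object@contrib)))
    msgs <- c(msgs, "contrib must be named by node term")
  if (any(object@contrib < 0)) msgs <- c(msgs, "contributions must be >= 0")
  if (abs(object@total - sum(object@contrib)) > 1e-9)
    msgs <- c(msgs, "total must equal the sum of contributions")
  if (length(msgs)) msgs else TRUE
})

#' HeteroNetwork: the assembled three-layer heterogeneous network
#'
#' Bundles the three threshold-filtered similarity layers with the three
#' normalized bipartite association layers, after checking index
#' consistency. Conceptually the block adjacency
#' `[S1 A1; S2 A2; S3 A3]` over miRNA + drug + disease nodes.
#'
#' @slot S1,S2,S3 filtered [SimilarityMatrix-class] (miRNA, drug, disease).
#' @slot A1,A2,A3 normalized [AssociationMatrix-class]
#'   (miRNA-disease, miRNA-drug, drug-disease).
#' @exportClass HeteroNetwork
setClass("HeteroNetwork",
  representation(S1 = "SimilarityMatrix", S2 = "SimilarityMatrix",
                 S3 = "SimilarityMatrix", A1 = "AssociationMatrix",
                 A2 = "AssociationMatrix", A3 = "AssociationMatrix"))

setValidity("HeteroNetwork", function(object) {
  msgs <- character()
  chk <- function(a, b, what) {
    if (!identical(a@names, b@names)) sprintf("index mismatch: %s", what)
    else character()
  }
  msgs <- c(msgs,
    chk(object@A1@rowIndex, object@S1@index, "miRNA-disease rows vs miRNA similarity"),
    chk(object@A1@colIndex, object@S3@index, "miRNA-disease cols vs disease similarity"),
    chk(object@A2@rowIndex, object@S1@index, "miRNA-drug rows vs miRNA similarity"),
    chk(object@A2@colIndex, object@S2@index, "miRNA-drug cols vs drug similarity"),
    chk(object@A3@rowIndex, object@S2@index, "drug-disease rows vs drug similarity"),
    chk(object@A3@colIndex, object@S3@index, "drug-disease cols vs disease similarity"))
  if (length(object@S2@index@names) < 1L)
    msgs <- c(msgs, "drug layer is empty; three layers required")
  if (length(msgs)) msgs else TRUE
})

#' CVResult: cross-validation outcome
#'
#' @slot aucPerRepeat pooled AUC per repeat (positives ranked in their own
#'   fold's run against all never-known pairs, pooled over the five folds).
#' @slot aucPerRepeatFoldMean secondary fold-averaged AUC per repeat.
#' @slot meanAuc arithmetic mean of `aucPerRepeat`.
#' @slot params the [PathParams-class] used.
#' @slot nFolds,nRepeats,seed protocol bookkeeping.
#' @exportClass CVResult
setClass("CVResult",
  representation(aucPerRepeat = "numeric", aucPerRepeatFoldMean = "numeric",
                 meanAuc = "numeric", params = "PathParams",
                 nFolds = "integer", nRepeats = "integer", seed = "integer"))

setValidity("CVResult", function(object) {
  msgs <- character()
  if (any(object@aucPerRepeat < 0 | object@aucPerRepeat > 1))
    msgs <- c(msgs, "AUC values must lie in [0, 1]")
  if (abs(object@meanAuc - mean(object@aucPerRepeat)) > 1e-12)
    msgs <- c(msgs, "meanAuc must equal mean(aucPerRepeat)")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticBundle: a generated heterogeneous-network fixture
#'
#' All six input matrices of the pipeline plus a toy disease tree-number
#' hierarchy and (optionally) a set of planted-and-masked miRNA-disease
#' truth pairs. Truth pairs are guaranteed absent (0) from the emitted
#' miRNA-disease association matrix.
#'
#' @slot S1,S2,S3 [SimilarityMatrix-class] layers (miRNA, drug, disease).
#' @slot A1,A2,A3 raw [AssociationMatrix-class] layers.
#' @slot treeNumbers named list: disease -> character vector of tree codes.
#' @slot truth data.frame with columns `mirna`, `disease` of masked pairs.
#' @slot seed integer seed the bundle was generated from.
#' @exportClass SyntheticBundle
setClass("SyntheticBundle",
  representation(S1 = "SimilarityMatrix", S2 = "SimilarityMatrix",
                 S3 = "SimilarityMatrix", A1 = "AssociationMatrix",
                 A2 = "AssociationMatrix", A3 = "AssociationMatrix",
                 treeNumbers = "list", truth = "data.frame",
                 seed = "integer"))

setValidity("SyntheticBundle", function(object) {
  msgs <- character()
  if (nrow(object@truth)) {
    v <- object@A1@values
    i <- match(object@truth$mirna, object@A1@rowIndex@names)
    j <- match(object@truth$disease, object@A1@colIndex@names)
    if (any(is.na(i)) || any(is.na(j)))
      msgs <- c(msgs, "truth pairs name unknown entities")
    else if (any(v[cbind(i, j)] != 0))
      msgs <- c(msgs, "truth pairs must be absent from the emitted A1")
  }
  if (length(msgs)) msgs else TRUE
})
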