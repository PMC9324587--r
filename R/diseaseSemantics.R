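# Disease semantic similarity from MeSH tree numbers.
#
# Each disease's tree codes induce, by prefix truncation at the dots, a
# directed acyclic graph of the disease and all its ancestors. Two
# semantic models weight the ancestors: model 1 decays geometrically with
# distance from the disease term (factor phi per edge, max over paths);
# model 2 uses the information content -log(frequency) of each term
# across the disease universe. Pairwise similarity is the shared-node
# contribution mass over the two profiles' totals, and the fused disease
# similarity averages the two models.

codeAncestors <- function(code) {
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(parts), function(k)
    paste(parts[seq_len(k)], collapse = "."), "")
}

# code -> owning disease term if some disease in the universe carries the
# code; otherwise the code itself acts as the (pseudo-)term id.
codeTermMap <- function(treeNumbers) {
  codes <- unlist(treeNumbers, use.names = FALSE)
  owner <- rep(names(treeNumbers), lengths(treeNumbers))
  # a code carried by several diseases keeps its first owner
  keep <- !duplicated(codes)
  structure(owner[keep], names = codes[keep])
}

lookupTerm <- function(code, map) {
  t <- map[code]
  ifelse(is.na(t), code, t)
}

#' Build the MeSH ancestor DAG of one disease
#'
#' Resolves each of the disease's tree codes into its chain of prefix
#' ancestors, maps codes to disease terms using the supplied universe
#' (ancestor codes carried by no disease in the universe become
#' code-named pseudo-terms), merges a term's multiple tree positions into
#' a single node, and records each node's minimum hop distance upward
#' from the disease term.
#'
#' @param disease disease name (normalized internally).
#' @param treeNumbers named list disease -> character vector of tree
#'   codes, as returned by [readTreeNumbers()]; must contain `disease`.
#' @return A [DiseaseDAG-class].
#' @examples
#' tn <- list("carcinoma x" = "C04.588.274")
#' dag <- buildDiseaseDAG("carcinoma x", tn)
#' dagLayers(dag)  # carcinoma x: 0, C04.588: 1, C04: 2
#' @export
buildDiseaseDAG <- function(disease, treeNumbers) {
  names(treeNumbers) <- normalizeEntityName(names(treeNumbers))
  disease <- normalizeEntityName(disease)
  codes <- treeNumbers[[disease]]
  if (is.null(codes) || !length(codes))
    stop(sprintf("disease '%s' has no tree codes", disease))
  map <- codeTermMap(treeNumbers)
  layer <- structure(0L, names = disease)
  edges <- matrix(character(), 0, 2)
  for (code in codes) {
    chain <- codeAncestors(code)         # shortest prefix first
    depth <- length(chain)
    terms <- lookupTerm(chain, map)
    terms[depth] <- disease              # the code itself is this disease
    dist <- rev(seq_len(depth)) - 1L     # hops up from the disease term
    for (k in seq_len(depth)) {
      t <- terms[k]
      if (is.na(layer[t]) || !t %in% names(layer)) {
        layer[t] <- dist[k]
      } else {
        layer[t] <- min(layer[t], dist[k])
      }
      if (k > 1L && terms[k - 1L] != terms[k])
        edges <- rbind(edges, c(terms[k - 1L], terms[k]))
    }
  }
  edges <- unique(edges)
  new("DiseaseDAG", disease = disease, layer = layer, edges = edges)
}

#' Count, per term, how many disease DAGs contain it
#'
#' @param dags list of [DiseaseDAG-class] objects (one per disease in the
#'   universe).
#' @return Named integer vector term -> number of DAGs containing it.
#' @export
dagTermCounts <- function(dags) {
  terms <- unlist(lapply(dags, function(d) names(d@layer)),
                  use.names = FALSE)
  tab <- table(terms)
  structure(as.integer(tab), names = names(tab))
}

#' Model-1 semantic profile: geometric decay from the disease term
#'
#' The disease term contributes 1; every ancestor contributes the maximum
#' over its DAG children of `phi` times the child's contribution, i.e.
#' `phi ^ (minimum hop distance from the disease term)`.
#'
#' @param dag a [DiseaseDAG-class].
#' @param phi semantic contribution factor in (0, 1); default 0.5.
#' @return A [SemanticProfile-class].
#' @export
model1Profile <- function(dag, phi = 0.5) {
  stopifnot(phi > 0, phi < 1)
  contrib <- phi ^ dag@layer
  names(contrib) <- names(dag@layer)
  new("SemanticProfile", contrib = contrib, total = sum(contrib))
}

#' Model-2 semantic profile: information content of each term
#'
#' Each node contributes `-log(DAG(a) / N)` (natural log), where `DAG(a)`
#' is the number of disease DAGs in the universe containing term `a` and
#' `N` the number of diseases in the universe. A term present in every
#' DAG contributes 0; a term unique to one DAG contributes `log(N)`.
#'
#' @param dag a [DiseaseDAG-class].
#' @param dagCounts named integer vector term -> DAG count, from
#'   [dagTermCounts()].
#' @param nDiseases size N of the disease universe.
#' @return A [SemanticProfile-class].
#' @export
model2Profile <- function(dag, dagCounts, nDiseases) {
  terms <- names(dag@layer)
  cnt <- dagCounts[terms]
  if (any(is.na(cnt)) || any(cnt < 1L))
    stop("inconsistent universe: DAG term with count 0")
  if (any(cnt > nDiseases))
    stop("term count exceeds the disease universe size")
  contrib <- -log(as.numeric(cnt) / nDiseases)
  names(contrib) <- terms
  new("SemanticProfile", contrib = contrib, total = sum(contrib))
}

#' Semantic similarity of two diseases from their profiles
#'
#' Sum over the shared DAG nodes of both diseases' contributions, divided
#' by the sum of the two profile totals; 0 when the DAGs share no node or
#' when both totals are 0.
#'
#' @param profileL,profileM [SemanticProfile-class] objects from the same
#'   model.
#' @return Similarity value in `[0, 1]`.
#' @export
pairSimilarity <- function(profileL, profileM) {
  denom <- profileL@total + profileM@total
  if (denom == 0) return(0)
  shared <- intersect(names(profileL@contrib), names(profileM@contrib))
  if (!length(shared)) return(0)
  sum(profileL@contrib[shared] + profileM@contrib[shared]) / denom
}

# Shared machinery: all DAGs and both profile sets for a universe.
universeProfiles <- function(treeNumbers, phi, onMissing) {
  names(treeNumbers) <- normalizeEntityName(names(treeNumbers))
  empty <- !lengths(treeNumbers)
  if (any(empty)) {
    if (identical(onMissing, "error"))
      stop(sprintf("disease '%s' has no tree codes",
                   names(treeNumbers)[which(empty)[1]]))
    warning(sprintf("excluding %d disease(s) with no tree codes",
                    sum(empty)))
    treeNumbers <- treeNumbers[!empty]
  }
  if (!length(treeNumbers)) stop("no diseases with tree codes")
  dags <- lapply(names(treeNumbers), buildDiseaseDAG,
                 treeNumbers = treeNumbers)
  names(dags) <- names(treeNumbers)
  counts <- dagTermCounts(dags)
  list(treeNumbers = treeNumbers, dags = dags,
       p1 = lapply(dags, model1Profile, phi = phi),
       p2 = lapply(dags, model2Profile, dagCounts = counts,
                   nDiseases = length(dags)))
}

# Pairwise similarity matrix for a profile list, computed via term
# incidence matrices: numerator(L, M) = sum over shared terms of
# c_L + c_M = (C B^T + B C^T)(L, M) with C the contribution matrix and B
# the 0/1 presence matrix.
profileSimilarityMatrix <- function(profiles) {
  terms <- sort(unique(unlist(lapply(profiles, function(p)
    names(p@contrib)), use.names = FALSE)))
  n <- length(profiles)
  C <- matrix(0, n, length(terms), dimnames = list(names(profiles), terms))
  B <- C
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    C[i, names(p@contrib)] <- p@contrib
    B[i, names(p@contrib)] <- 1
  }
  totals <- vapply(profiles, function(p) p@total, 0)
  num <- C %*% t(B) + B %*% t(C)
  den <- outer(totals, totals, `+`)
  out <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  diag(out) <- 1
  out
}

#' Disease similarity matrix under one semantic model
#'
#' @param treeNumbers named list disease -> tree codes.
#' @param model 1 (geometric decay) or 2 (information content).
#' @param phi semantic contribution factor for model 1.
#' @param onMissing `"exclude"` (default; drop diseases without codes,
#'   with a warning) or `"error"`.
#' @return A [SimilarityMatrix-class] over the (retained) diseases.
#' @export
modelSimilarityMatrix <- function(treeNumbers, model = 1, phi = 0.5,
                                  onMissing = c("exclude", "error")) {
  onMissing <- match.arg(onMissing)
  u <- universeProfiles(treeNumbers, phi, onMissing)
  profiles <- if (model == 1) u$p1 else if (model == 2) u$p2
              else stop("model must be 1 or 2")
  m <- profileSimilarityMatrix(profiles)
  SimilarityMatrix(m, EntityIndex(names(u$treeNumbers), "disease"))
}

#' Fused disease semantic similarity
#'
#' Averages the model-1 and model-2 similarity matrices over the same
#' disease universe; diagonal fixed at 1.
#'
#' @inheritParams modelSimilarityMatrix
#' @return A [SimilarityMatrix-class].
#' @examples
#' tn <- list(root = "C04", mid = "C04.100", leaf = "C04.100.200")
#' fds <- fusedDiseaseSimilarity(tn)
#' simValues(fds)["leaf", "mid"]
#' @export
fusedDiseaseSimilarity <- function(treeNumbers, phi = 0.5,
                                   onMissing = c("exclude", "error")) {
  onMissing <- match.arg(onMissing)
  u <- universeProfiles(treeNumbers, phi, onMissing)
  m <- (profileSimilarityMatrix(u$p1) + profileSimilarityMatrix(u$p2)) / 2
  diag(m) <- 1
  SimilarityMatrix(m, EntityIndex(names(u$treeNumbers), "disease"))
}
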