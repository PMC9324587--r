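test_that("the decay exponent is beta times path length", {
  expect_equal(fdecay(2, 7), 14)
  expect_equal(fdecay(1, 7), 7)
  expect_equal(fdecay(2, 1), 2)
  expect_error(fdecay(0, 7))
  expect_error(fdecay(2, 0))
})

test_that("network assembly validates index consistency and layer presence", {
  mi <- makeIndex(2, "miRNA")
  dr <- makeIndex(2, "drug")
  di <- makeIndex(2, "disease")
  S1 <- SimilarityMatrix(diag(2), mi)
  S2 <- SimilarityMatrix(diag(2), dr)
  S3 <- SimilarityMatrix(diag(2), di)
  z <- function(a, b) AssociationMatrix(matrix(0, 2, 2), a, b,
                                        stage = "normalized")
  net <- assembleThreeLayer(S1, S2, S3, z(mi, di), z(mi, dr), z(dr, di))
  expect_s4_class(net, "HeteroNetwork")

  # wrong disease count on A1 names the offending pair
  di3 <- makeIndex(3, "disease")
  bad <- AssociationMatrix(matrix(0, 2, 3), mi, di3, stage = "normalized")
  expect_error(assembleThreeLayer(S1, S2, S3, bad, z(mi, dr), z(dr, di)),
               "miRNA-disease cols")
})

test_that("two-layer path weights match the worked toy values", {
  mi <- makeIndex(2, "miRNA")
  di <- makeIndex(2, "disease")
  S1 <- SimilarityMatrix(matrix(c(1, .9, .9, 1), 2), mi)
  A <- AssociationMatrix(matrix(c(1, 0, 0, 0), 2), mi, di,
                         stage = "normalized")

  # only similarity edge mir1~mir2 (0.9) and association mir1-dis1
  W <- scoreValues(twoLayerPathScores(S1, SimilarityMatrix(diag(2), di), A,
                                      PathParams(beta = 7)))
  expect_equal(W["mir02", "dis01"], 0.9 ^ 14, tolerance = 1e-12)
  expect_equal(W["mir01", "dis01"], 1)

  # adding disease edge dis1~dis2 (0.8) opens the second path shape
  S3 <- SimilarityMatrix(matrix(c(1, .8, .8, 1), 2), di)
  W <- scoreValues(twoLayerPathScores(S1, S3, A, PathParams(beta = 7)))
  expect_equal(W["mir01", "dis02"], 0.8 ^ 14, tolerance = 1e-12)

  # no similarity edges at all: W equals A exactly
  W <- scoreValues(twoLayerPathScores(SimilarityMatrix(diag(2), mi),
                                      SimilarityMatrix(diag(2), di), A))
  expect_equal(W, assocValues(A))

  expect_error(twoLayerPathScores(S1, S3, A, PathParams(pathLength = 3L)),
               "path length 2")
})

test_that("path scoring equals exhaustive length-2 enumeration", {
  withr::local_seed(202)
  for (rep in 1:40) {
    p <- sample(2:15, 1)
    q <- sample(2:15, 1)
    beta <- sample(c(1, 2, 7), 1)
    Sr <- thresholdNeighbors(randomSimilarity(p, "miRNA"), runif(1, 0, .8))
    Sc <- thresholdNeighbors(randomSimilarity(q, "disease"), runif(1, 0, .8))
    A <- normalizeGlobalMax(
      reconstructBipartite(Sr, Sc, randomRawAssoc(simIndex(Sr),
                                                  simIndex(Sc), 0.3)))
    got <- scoreValues(twoLayerPathScores(Sr, Sc, A,
                                          PathParams(beta = beta)))
    want <- oraclePathScores(simValues(Sr), simValues(Sc), assocValues(A),
                             beta)
    expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("integration adds drug-mediated path products over all drugs", {
  mi <- makeIndex(1, "miRNA")
  dr <- makeIndex(1, "drug")
  di <- makeIndex(1, "disease")
  sm <- function(v, ri, ci) new("ScoreMatrix",
    values = matrix(v, length(entityNames(ri)), length(entityNames(ci)),
                    dimnames = list(entityNames(ri), entityNames(ci))),
    rowIndex = ri, colIndex = ci)
  sc <- integrateScores(sm(0.5, mi, di), sm(0.9, mi, dr), sm(0.8, dr, di),
                        PathParams(beta = 7))
  expect_equal(scoreValues(sc)[1, 1], 0.5 + 0.72 ^ 14, tolerance = 1e-12)

  # no drug evidence: score equals W1
  sc <- integrateScores(sm(0.5, mi, di), sm(0, mi, dr), sm(0.8, dr, di))
  expect_equal(scoreValues(sc)[1, 1], 0.5)

  # two drugs contribute additively
  dr2 <- makeIndex(2, "drug")
  W2 <- sm(c(0.9, 0.6), mi, dr2)
  W3 <- sm(c(0.8, 0.7), dr2, di)
  sc <- integrateScores(sm(0.5, mi, di), W2, W3, PathParams(beta = 7))
  expect_equal(scoreValues(sc)[1, 1],
               0.5 + (0.9 * 0.8) ^ 14 + (0.6 * 0.7) ^ 14, tolerance = 1e-12)
})

test_that("full pipeline: identity similarities leave direct associations", {
  mi <- makeIndex(3, "miRNA")
  dr <- makeIndex(2, "drug")
  di <- makeIndex(3, "disease")
  S1 <- SimilarityMatrix(diag(3), mi)
  S2 <- SimilarityMatrix(diag(2), dr)
  S3 <- SimilarityMatrix(diag(3), di)
  A1 <- AssociationMatrix(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 0), 3), mi, di,
                          stage = "raw")
  # drug layers wired so no miRNA and disease share a drug
  A2 <- AssociationMatrix(cbind(c(1, 0, 0), 0), mi, dr, stage = "raw")
  A3 <- AssociationMatrix(rbind(0, c(0, 0, 1)), dr, di, stage = "raw")
  sc <- predictAssociations(S1, S2, S3, A1, A2, A3, PathParams())
  expect_equal(scoreValues(sc), assocValues(A1))
})

test_that("full pipeline is deterministic and relabeling-equivariant", {
  withr::local_seed(77)
  b <- generateBlockNetwork(nMirna = 8, nDrug = 5, nDisease = 8,
                            nBlocks = 2, seed = 5)
  s1 <- scoreValues(predictBundle(b))
  s2 <- scoreValues(predictBundle(b))
  expect_identical(s1, s2)  # bit-identical reruns

  # permute miRNA and disease orders in every input consistently
  L <- bundleLayers(b)
  pm <- sample(8)
  pd <- sample(8)
  miP <- EntityIndex(entityNames(simIndex(L$S1))[pm], "miRNA")
  diP <- EntityIndex(entityNames(simIndex(L$S3))[pd], "disease")
  S1p <- SimilarityMatrix(simValues(L$S1)[pm, pm], miP)
  S3p <- SimilarityMatrix(simValues(L$S3)[pd, pd], diP)
  A1p <- AssociationMatrix(assocValues(L$A1)[pm, pd], miP, diP, "raw")
  A2p <- AssociationMatrix(assocValues(L$A2)[pm, ], miP, simIndex(L$S2), "raw")
  A3p <- AssociationMatrix(assocValues(L$A3)[, pd], simIndex(L$S2), diP, "raw")
  sp <- scoreValues(predictAssociations(S1p, L$S2, S3p, A1p, A2p, A3p))
  expect_equal(sp, s1[pm, pd], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("scores stack monotonically over the pipeline stages", {
  withr::local_seed(303)
  for (rep in 1:10) {
    b <- generateBlockNetwork(nMirna = 8, nDrug = 4, nDisease = 8,
                              nBlocks = 2, seed = 300 + rep)
    L <- bundleLayers(b)
    params <- PathParams()
    S1f <- thresholdNeighbors(L$S1, params@threshold)
    S2f <- thresholdNeighbors(L$S2, params@threshold)
    S3f <- thresholdNeighbors(L$S3, params@threshold)
    A1n <- normalizeGlobalMax(reconstructBipartite(S1f, S3f, L$A1))
    W1 <- twoLayerPathScores(S1f, S3f, A1n, params)
    sc <- predictBundle(b, params)
    expect_true(all(scoreValues(W1) >= assocValues(A1n) - 1e-12))
    expect_true(all(scoreValues(sc) >= scoreValues(W1) - 1e-12))
  }
})

test_that("large decay drives scores back to the normalized associations", {
  b <- generateBlockNetwork(nMirna = 8, nDrug = 4, nDisease = 8,
                            nBlocks = 2, seed = 9)
  L <- bundleLayers(b)
  params <- PathParams(beta = 400)
  S1f <- thresholdNeighbors(L$S1, params@threshold)
  S2f <- thresholdNeighbors(L$S2, params@threshold)
  S3f <- thresholdNeighbors(L$S3, params@threshold)
  A1n <- normalizeGlobalMax(reconstructBipartite(S1f, S3f, L$A1))
  A2n <- normalizeGlobalMax(reconstructBipartite(S1f, S2f, L$A2))
  A3n <- normalizeGlobalMax(reconstructBipartite(S2f, S3f, L$A3))
  W2r <- scoreValues(twoLayerPathScores(S1f, S2f, A2n, params))
  W3r <- scoreValues(twoLayerPathScores(S2f, S3f, A3n, params))
  W2r <- W2r / max(W2r)
  W3r <- W3r / max(W3r)
  gap <- scoreValues(predictBundle(b, params)) - assocValues(A1n)
  maxProd <- oracleMaxPathProduct(simValues(S1f), simValues(S3f),
                                  assocValues(A1n), W2r, W3r)
  # wherever every contributing path product is < 1 the gap vanishes
  # restrict to pairs whose strongest path product is clearly below 1;
  # products close to 1 need astronomically large decay to vanish
  sub <- maxProd < 0.95
  expect_true(any(sub))
  expect_lt(max(gap[sub]), 1e-10)
})
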