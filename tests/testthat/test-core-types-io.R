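test_that("entity indices normalize, deduplicate and invert lookups", {
  idx <- EntityIndex(c("mir-21", "mir-155"), "miRNA")
  expect_length(entityNames(idx), 2)
  expect_identical(entityKind(idx), "miRNA")

  collapsed <- EntityIndex(c("mir-21", "MIR-21 "), "miRNA")
  expect_length(entityNames(collapsed), 1)

  expect_error(EntityIndex(character(), "miRNA"), "non-empty")

  # position lookup inverts name lookup, through any case/padding
  nm <- entityNames(idx)
  expect_identical(entityPosition(idx, nm), seq_along(nm))
  expect_identical(entityPosition(idx, toupper(paste0(" ", nm))),
                   seq_along(nm))
  expect_true(is.na(entityPosition(idx, "mir-999")))
})

test_that("edge lists load as binary matrices with strict/skip semantics", {
  mi <- EntityIndex(c("mir-1", "mir-2", "mir-3"), "miRNA")
  di <- EntityIndex(c("asthma", "lymphoma"), "disease")
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("mir-1\tasthma", "mir-2\tlymphoma", "mir-3\tasthma"), f)
  A <- readAssociationEdges(f, mi, di)
  expect_identical(assocStage(A), "raw")
  expect_equal(sum(assocValues(A)), 3)

  # duplicate edges collapse to a single 1
  writeLines(c("mir-1\tasthma", "MIR-1 \tAsthma"), f)
  A <- readAssociationEdges(f, mi, di)
  expect_equal(assocValues(A)[["mir-1", "asthma"]], 1)
  expect_equal(sum(assocValues(A)), 1)

  # unknown entity: skipped (default) or an error naming it (strict)
  writeLines(c("mir-1\tasthma", "mir-9\tasthma"), f)
  expect_message(A <- readAssociationEdges(f, mi, di), "skipped 1")
  expect_equal(sum(assocValues(A)), 1)
  expect_error(readAssociationEdges(f, mi, di, strict = TRUE), "mir-9")

  # unparseable line reported with its line number
  writeLines(c("mir-1\tasthma", "just-one-field"), f)
  expect_error(readAssociationEdges(f, mi, di), "line 2")

  # CSV auto-detected
  writeLines(c("mir-1,asthma", "mir-2,lymphoma"), f)
  expect_equal(sum(assocValues(readAssociationEdges(f, mi, di))), 2)
})

test_that("association matrices round-trip exactly through text files", {
  withr::local_seed(42)
  mi <- makeIndex(6, "miRNA")
  di <- makeIndex(4, "disease")
  A <- randomRawAssoc(mi, di, 0.4)
  f <- withr::local_tempfile(fileext = ".tsv")

  writeAssociationEdges(A, f)
  expect_identical(assocValues(readAssociationEdges(f, mi, di)),
                   assocValues(A))

  # dense round trip preserves non-binary weights exactly
  An <- normalizeGlobalMax(
    AssociationMatrix(assocValues(A) * pi / 7, mi, di,
                      stage = "reconstructed"))
  writeDenseMatrix(An, f)
  back <- readAssociationMatrix(f, mi, di, stage = "normalized")
  expect_identical(assocValues(back), assocValues(An))
})

test_that("similarity matrices load order-independently and reject asymmetry", {
  withr::local_seed(7)
  idx <- makeIndex(5, "disease")
  S <- randomSimilarity(5, "disease")
  f <- withr::local_tempfile(fileext = ".tsv")

  writeDenseMatrix(S, f)
  expect_equal(simValues(readSimilarityMatrix(f, simIndex(S))),
               simValues(S), tolerance = 1e-12)

  # identity matrix returned unchanged
  I5 <- SimilarityMatrix(diag(5), idx)
  writeDenseMatrix(I5, f)
  expect_equal(simValues(readSimilarityMatrix(f, idx)), diag(5),
               ignore_attr = TRUE)

  # permuted rows/columns yield the same matrix under the index order
  v <- simValues(S)
  perm <- sample(5)
  vp <- v[perm, rev(perm)]
  writeLines(c(paste(c("", colnames(vp)), collapse = "\t"),
               sapply(seq_len(5), function(i)
                 paste(c(rownames(vp)[i], sprintf("%.17g", vp[i, ])),
                       collapse = "\t"))), f)
  expect_equal(simValues(readSimilarityMatrix(f, simIndex(S))),
               simValues(S), tolerance = 1e-12)

  # gross asymmetry is an error
  v2 <- v
  v2[1, 2] <- 0.9
  v2[2, 1] <- 0.1
  S2 <- S
  writeLines(c(paste(c("", colnames(v2)), collapse = "\t"),
               sapply(seq_len(5), function(i)
                 paste(c(rownames(v2)[i], sprintf("%.17g", v2[i, ])),
                       collapse = "\t"))), f)
  expect_error(readSimilarityMatrix(f, simIndex(S)), "asymmetric")
})

test_that("tree-number records aggregate per disease and validate codes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("hepatocellular carcinoma\tC04.588.274",
               "Hepatocellular Carcinoma\tC06.301",
               "asthma\tC08.127"), f)
  tn <- readTreeNumbers(f)
  expect_length(tn, 2)
  expect_setequal(tn[["hepatocellular carcinoma"]],
                  c("C04.588.274", "C06.301"))

  writeLines("bad disease\tC04..588", f)
  expect_error(readTreeNumbers(f), "line 1")
})

test_that("score tables rank per disease with deterministic ties", {
  mi <- EntityIndex(c("mir-a", "mir-b", "mir-c"), "miRNA")
  di <- EntityIndex(c("d1", "d2"), "disease")
  sc <- new("ScoreMatrix",
            values = matrix(c(0.2, 0.9, 0.5, 0.7, 0.7, 0.1), 3, 2,
                            dimnames = list(entityNames(mi),
                                            entityNames(di))),
            rowIndex = mi, colIndex = di)
  f <- withr::local_tempfile(fileext = ".tsv")

  tab <- writeScoreTable(sc, f, topK = 1)
  expect_equal(nrow(tab), 2)
  expect_identical(tab$mirna, c("mir-b", "mir-a"))  # d2 tie -> index order
  expect_identical(tab$rank, c(1L, 1L))

  # all-zero scores still rank deterministically by index order
  zero <- new("ScoreMatrix",
              values = matrix(0, 3, 2,
                              dimnames = list(entityNames(mi),
                                              entityNames(di))),
              rowIndex = mi, colIndex = di)
  tab <- writeScoreTable(zero, f)
  expect_identical(tab$mirna[tab$disease == "d1"],
                   c("mir-a", "mir-b", "mir-c"))
  written <- read.delim(f)
  expect_equal(nrow(written), 6)
})

test_that("invalid similarity and association values are rejected", {
  idx <- makeIndex(3, "miRNA")
  bad <- diag(3)
  bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(SimilarityMatrix(bad, idx), "outside")
  asym <- diag(3)
  asym[1, 2] <- 0.4
  expect_error(SimilarityMatrix(asym, idx), "symmetric")
  di <- makeIndex(2, "disease")
  expect_error(AssociationMatrix(matrix(0.5, 3, 2), idx, di, stage = "raw"),
               "binary")
  expect_error(AssociationMatrix(matrix(-1, 3, 2), idx, di,
                                 stage = "reconstructed"), "nonnegative")
})
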