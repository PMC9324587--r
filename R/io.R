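# Readers and writers for the plain-text interchange formats: association
# edge lists, dense similarity/association matrices, MeSH tree-number
# records and ranked score tables. All readers route names through the
# same normalization as EntityIndex, so files may mix case and padding.

splitDelimited <- function(lines, sep) {
  strsplit(lines, sep, fixed = TRUE)
}

#' Read a bipartite association edge list
#'
#' Reads a two-or-more-column delimited text file (TSV or CSV,
#' auto-detected unless `sep` is given) whose first two columns name a
#' row-set entity and a column-set entity, and returns the binary raw
#' association matrix over the supplied indices. Duplicate edges collapse
#' to a single 1.
#'
#' @param path file path.
#' @param rowIndex,colIndex [EntityIndex-class] objects defining the
#'   matrix dimensions.
#' @param strict if TRUE, an edge naming an unindexed entity is an error;
#'   if FALSE (default) such edges are skipped and their count reported in
#'   a message.
#' @param header logical; skip a header line (default FALSE).
#' @param sep field delimiter; NULL (default) auto-detects tab vs comma.
#' @return A raw [AssociationMatrix-class].
#' @export
readAssociationEdges <- function(path, rowIndex, colIndex, strict = FALSE,
                                 header = FALSE, sep = NULL) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  keep <- nzchar(trimws(lines))
  lineNo <- which(keep) + as.integer(header)
  lines <- lines[keep]
  m <- matrix(0, length(rowIndex@names), length(colIndex@names),
              dimnames = list(rowIndex@names, colIndex@names))
  if (!length(lines))
    return(AssociationMatrix(m, rowIndex, colIndex, stage = "raw"))
  if (is.null(sep)) sep <- detectDelim(lines[1])
  fields <- splitDelimited(lines, sep)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad))
    stop(sprintf("unparseable line %d in '%s': fewer than 2 fields",
                 lineNo[bad[1]], path))
  rn <- vapply(fields, `[[`, "", 1L)
  cn <- vapply(fields, `[[`, "", 2L)
  i <- entityPosition(rowIndex, rn)
  j <- entityPosition(colIndex, cn)
  unknown <- is.na(i) | is.na(j)
  if (any(unknown)) {
    if (strict) {
      k <- which(unknown)[1]
      nm <- if (is.na(i[k])) rn[k] else cn[k]
      stop(sprintf("unknown entity '%s' at line %d of '%s'",
                   nm, lineNo[k], path))
    }
    message(sprintf("skipped %d edge(s) naming unindexed entities",
                    sum(unknown)))
  }
  ij <- cbind(i[!unknown], j[!unknown])
  m[ij] <- 1
  AssociationMatrix(m, rowIndex, colIndex, stage = "raw")
}

#' Write a raw association matrix as an edge list
#'
#' Emits one `row-entity<TAB>col-entity` line per positive entry, in
#' row-major index order, so that reading the file back against the same
#' indices reproduces the matrix exactly.
#'
#' @param assoc a raw [AssociationMatrix-class].
#' @param path output file path.
#' @export
writeAssociationEdges <- function(assoc, path) {
  stopifnot(is(assoc, "AssociationMatrix"))
  if (assoc@stage != "raw")
    stop("edge-list output is defined for raw (binary) matrices only")
  pos <- which(t(assoc@values) > 0)  # row-major order
  nc <- ncol(assoc@values)
  i <- (pos - 1L) %/% nc + 1L
  j <- (pos - 1L) %% nc + 1L
  writeLines(paste(assoc@rowIndex@names[i], assoc@colIndex@names[j],
                   sep = "\t"), path)
}

readDenseTable <- function(path, sep = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- detectDelim(first)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           row.names = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  as.matrix(tab)
}

#' Read a dense similarity matrix
#'
#' Reads a square numeric table with row and column headers, permutes it
#' to the order of `index`, symmetrizes small numerical asymmetry
#' (maximum `|M - t(M)|` up to 1e-6; larger asymmetry is an error) and
#' forces the diagonal to 1.
#'
#' @param path file path (TSV/CSV with header row and row-name column).
#' @param index [EntityIndex-class] the matrix must cover.
#' @param sep delimiter; NULL auto-detects.
#' @return A [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path, index, sep = NULL) {
  m <- readDenseTable(path, sep)
  rn <- normalizeEntityName(rownames(m))
  cn <- normalizeEntityName(colnames(m))
  i <- match(index@names, rn)
  j <- match(index@names, cn)
  if (any(is.na(i)) || any(is.na(j)))
    stop(sprintf("similarity matrix '%s' is missing entity '%s'", path,
                 index@names[which(is.na(i) | is.na(j))[1]]))
  m <- m[i, j, drop = FALSE]
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    stop(sprintf("similarity matrix '%s' is asymmetric (max |M - t(M)| = %g)",
                 path, asym))
  m <- (m + t(m)) / 2
  stopIfNot01(m, sprintf("similarity matrix '%s'", path), tol = 1e-6)
  m[m < 0] <- 0
  m[m > 1] <- 1
  SimilarityMatrix(m, index)
}

#' Write a similarity or association matrix as a dense table
#'
#' Full-precision TSV with header row and row-name column; a round trip
#' through [readSimilarityMatrix()] / [readAssociationMatrix()]
#' reproduces the values exactly.
#'
#' @param x a [SimilarityMatrix-class] or [AssociationMatrix-class].
#' @param path output file path.
#' @export
writeDenseMatrix <- function(x, path) {
  v <- if (is(x, "SimilarityMatrix")) x@values
       else if (is(x, "AssociationMatrix")) x@values
       else stop("unsupported object")
  out <- c(paste(c("", colnames(v)), collapse = "\t"),
           vapply(seq_len(nrow(v)), function(i)
             paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])),
                   collapse = "\t"), ""))
  writeLines(out, path)
}

#' Read a dense association matrix
#'
#' Counterpart of [writeDenseMatrix()] for rectangular association
#' matrices at any processing stage.
#'
#' @param path file path.
#' @param rowIndex,colIndex [EntityIndex-class] objects.
#' @param stage processing stage tag of the stored matrix.
#' @param sep delimiter; NULL auto-detects.
#' @return An [AssociationMatrix-class].
#' @export
readAssociationMatrix <- function(path, rowIndex, colIndex, stage = "raw",
                                  sep = NULL) {
  m <- readDenseTable(path, sep)
  i <- match(rowIndex@names, normalizeEntityName(rownames(m)))
  j <- match(colIndex@names, normalizeEntityName(colnames(m)))
  if (any(is.na(i)) || any(is.na(j)))
    stop(sprintf("association matrix '%s' does not cover the indices", path))
  AssociationMatrix(m[i, j, drop = FALSE], rowIndex, colIndex, stage = stage)
}

# MeSH tree codes: dot-separated non-empty alphanumeric segments,
# e.g. "C04.588.274".
treeCodeOk <- function(code) {
  grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", code)
}

#' Read disease MeSH tree-number records
#'
#' Two-column delimited text (disease name, dot-separated tree code such
#' as `C04.588.274`); multiple rows per disease accumulate codes.
#'
#' @param path file path.
#' @param header logical; skip a header line.
#' @param sep delimiter; NULL auto-detects.
#' @return Named list mapping canonical disease name to a character
#'   vector of unique tree codes.
#' @export
readTreeNumbers <- function(path, header = FALSE, sep = NULL) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  keep <- nzchar(trimws(lines))
  lineNo <- which(keep) + as.integer(header)
  lines <- lines[keep]
  if (!length(lines)) return(structure(list(), names = character()))
  if (is.null(sep)) sep <- detectDelim(lines[1])
  fields <- splitDelimited(lines, sep)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad))
    stop(sprintf("unparseable line %d in '%s'", lineNo[bad[1]], path))
  dis <- normalizeEntityName(vapply(fields, `[[`, "", 1L))
  code <- trimws(vapply(fields, `[[`, "", 2L))
  badCode <- which(!treeCodeOk(code))
  if (length(badCode))
    stop(sprintf("malformed tree code '%s' at line %d of '%s'",
                 code[badCode[1]], lineNo[badCode[1]], path))
  lapply(split(code, factor(dis, levels = unique(dis))), unique)
}

#' Rank scores per disease and write a score table
#'
#' Produces a TSV with columns `mirna`, `disease`, `score`, `rank`, ranked
#' descending within each disease; ties are broken by miRNA index order
#' for reproducibility.
#'
#' @param scores a [ScoreMatrix-class].
#' @param path output file path.
#' @param topK optional: keep only the top `topK` miRNAs per disease.
#' @return Invisibly, the emitted data.frame.
#' @export
writeScoreTable <- function(scores, path, topK = NULL) {
  stopifnot(is(scores, "ScoreMatrix"))
  v <- scores@values
  if (any(!is.finite(v))) stop("scores must be finite")
  rows <- lapply(seq_len(ncol(v)), function(j) {
    ord <- order(-v[, j], seq_len(nrow(v)))
    if (!is.null(topK)) ord <- utils::head(ord, topK)
    data.frame(mirna = scores@rowIndex@names[ord],
               disease = scores@colIndex@names[j],
               score = v[ord, j], rank = seq_along(ord),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
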