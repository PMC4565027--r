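#' @include seq2gene.R
NULL

#' Construct a GeneScoreMatrix
#'
#' @param score numeric gene-by-sample matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param nLoci optional integer matrix of contributing-locus counts, same
#'   shape; defaults to all 0 (user-supplied provenance).
#' @return A [GeneScoreMatrix].
#' @export
GeneScoreMatrix <- function(score, nLoci = NULL) {
  score <- as.matrix(score)
  if (is.null(nLoci))
    nLoci <- matrix(0L, nrow(score), ncol(score), dimnames = dimnames(score))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = score, nLoci = as.matrix(nLoci)))
  new("GeneScoreMatrix", se)
}

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "GeneScoreMatrix",
          function(x) SummarizedExperiment::assay(x, "score"))

#' @rdname accessors
#' @export
setMethod("lociCounts", "GeneScoreMatrix",
          function(x) SummarizedExperiment::assay(x, "nLoci"))

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneScoreMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GeneScoreMatrix", function(x) colnames(x))

#' Collapse per-locus scores to one score per gene
#'
#' Reduces a [MappingTable] to a single-sample gene profile: each gene
#' receives one value computed from the scores of its contributing loci.
#' A locus mapping to the same gene via several structural types
#' contributes exactly once (type multiplicity is metadata, not weight);
#' this per-gene collapsing is what removes linkage-disequilibrium /
#' clustered-peak double counting downstream.
#'
#' @param mapping a non-empty [MappingTable].
#' @param sampleId sample name for the single output column.
#' @param method collapse statistic: `"max_abs"` (default; the score of
#'   largest magnitude, sign preserved -- ties broken by first occurrence),
#'   `"max"`, `"min"`, `"mean"`, `"median"`, or `"count"` (number of
#'   distinct contributing loci, ignoring scores).
#' @return A single-sample [GeneScoreMatrix] (genes sorted by id); the
#'   `nLoci` assay holds the distinct-locus count per gene.
#' @export
collapseToGenes <- function(mapping, sampleId = "sample_1",
                            method = c("max_abs", "max", "min", "mean",
                                       "median", "count")) {
  stopifnot(is(mapping, "MappingTable"))
  if (!is.character(method) || !all(method %in%
      c("max_abs", "max", "min", "mean", "median", "count")))
    stop("unknown collapse method; choices: max_abs, max, min, mean, ",
         "median, count")
  method <- match.arg(method)
  rec <- mapping@records
  if (!nrow(rec)) stop("mapping table has no records")
  key <- paste(rec$locus_id, rec$gene_id, sep = "\r")
  u <- rec[!duplicated(key), c("locus_id", "gene_id", "score")]
  sp <- split(u$score, u$gene_id)          # sorted by gene_id
  f <- switch(method,
    max_abs = function(v) v[which.max(abs(v))],
    max = max, min = min, mean = mean, median = stats::median,
    count = length)
  val <- vapply(sp, function(v) as.numeric(f(v)), 0)
  nl <- vapply(sp, length, 0L)
  GeneScoreMatrix(
    matrix(val, ncol = 1, dimnames = list(names(sp), sampleId)),
    matrix(nl, ncol = 1, dimnames = list(names(sp), sampleId)))
}

#' Merge single-sample gene profiles into one matrix
#'
#' Takes the union of genes across samples; a gene absent from a sample is
#' filled with `fillMissing` (default 0, "no evidence" on the score scale)
#' and locus count 0.
#'
#' @param matrices list of [GeneScoreMatrix] objects with distinct sample
#'   ids.
#' @param fillMissing fill value for genes missing in a sample.
#' @return A [GeneScoreMatrix] over the gene union (sorted by gene id).
#' @export
mergeSamples <- function(matrices, fillMissing = 0) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, is, TRUE, "GeneScoreMatrix")))
  samp <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(samp))
    stop("duplicate sample_id: ", samp[duplicated(samp)][1])
  genes <- sort(unique(unlist(lapply(matrices, rownames))))
  score <- matrix(fillMissing, length(genes), length(samp),
                  dimnames = list(genes, samp))
  nl <- matrix(0L, length(genes), length(samp),
               dimnames = list(genes, samp))
  for (m in matrices) {
    score[rownames(m), colnames(m)] <- scoreMatrix(m)
    nl[rownames(m), colnames(m)] <- lociCounts(m)
  }
  GeneScoreMatrix(score, nl)
}

#' Read a gene-by-sample score matrix from TSV
#'
#' Expects a header row of sample ids, gene ids in the first column, and a
#' numeric body (scientific notation allowed). `#`-prefixed lines are
#' skipped. Locus counts are set to 0 (user-supplied provenance), matching
#' the RNA-seq entry point where gene scores come from expression rather
#' than locus hits.
#'
#' @param path path to a TSV file.
#' @return A [GeneScoreMatrix].
#' @export
readGeneMatrix <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("gene matrix file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) stop("gene matrix '", path, "' has an empty body")
  if (ncol(df) < 2) stop("gene matrix '", path, "' has no sample columns")
  gid <- df[[1]]
  if (anyDuplicated(gid))
    stop("duplicate gene ids in '", path, "': ", gid[duplicated(gid)][1])
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", body[bad[1], bad[2]], "' at gene row ",
         bad[1], ", sample column ", bad[2])
  }
  dimnames(vals) <- list(gid, colnames(df)[-1])
  GeneScoreMatrix(vals)
}

#' Write a gene-by-sample score matrix as TSV
#'
#' @param x a [GeneScoreMatrix].
#' @param path output path; a `#`-prefixed provenance header is included
#'   (readable back via [readGeneMatrix()]).
#' @return `path`, invisibly.
#' @export
writeGeneMatrix <- function(x, path) {
  stopifnot(is(x, "GeneScoreMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cisPathway ",
                    as.character(utils::packageVersion("cisPathway")),
                    " gene score matrix"), con)
  df <- data.frame(gene_id = rownames(x), scoreMatrix(x),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "GeneScoreMatrix", function(object) {
  cat("GeneScoreMatrix:", nrow(object), "genes x", ncol(object),
      "samples\n")
  cat("  loci-backed genes:",
      sum(rowSums(lociCounts(object)) > 0), "\n")
})
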