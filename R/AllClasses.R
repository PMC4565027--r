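#' @import methods
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList findOverlaps seqnames start
#'   end width strand reduce
#' @importFrom GenomeInfoDb seqlevels seqnames<-
#' @importFrom stats rank p.adjust phyper pnorm ks.test rlnorm rexp rnorm
#'   runif rpois median setNames
#' @importFrom utils head combn
NULL

#' Gene models derived from a GTF file, with promoters and feature geometry
#'
#' A `GenomeAnnotation` holds the gene-level and transcript-level geometry
#' parsed from a GTF file: per-gene spans (the union range over the gene's
#' transcripts), strand-aware transcription start sites (TSS), promoter
#' windows, and per-transcript exon, CDS, UTR and intron intervals.
#' All coordinates are 1-based closed ([GenomicRanges::GRanges]).
#'
#' @slot genes `GRanges` of gene spans; metadata columns `gene_id`,
#'   `gene_symbol`, `tss` (1-based TSS position).
#' @slot promoters `GRanges` parallel to `genes`: the promoter window,
#'   `promoterUp` bp upstream to `promoterDown` bp downstream of the TSS,
#'   strand-aware, clamped at position 1.
#' @slot exons,cds,utrs,introns `GRangesList` keyed by transcript id.
#'   UTRs are derived as exons minus CDS; introns as the transcript range
#'   minus its exons. Non-coding transcripts have empty `cds` and `utrs`.
#' @slot txGene data.frame with columns `transcript_id`, `gene_id`.
#' @slot provenance list recording the source path and promoter window.
#'
#' @seealso [readGTF()], [queryOverlaps()], [queryRadius()]
#' @export
setClass("GenomeAnnotation",
  slots = c(
    genes = "GRanges",
    promoters = "GRanges",
    exons = "GRangesList",
    cds = "GRangesList",
    utrs = "GRangesList",
    introns = "GRangesList",
    txGene = "data.frame",
    provenance = "list"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  gid <- mcols(object@genes)$gene_id
  if (is.null(gid)) msg <- c(msg, "genes must carry a 'gene_id' metadata column")
  else if (anyDuplicated(gid)) msg <- c(msg, "gene_ids must be unique")
  if (length(object@genes) != length(object@promoters))
    msg <- c(msg, "genes and promoters must be parallel")
  if (!all(c("transcript_id", "gene_id") %in% names(object@txGene)))
    msg <- c(msg, "txGene must have transcript_id and gene_id columns")
  tx <- object@txGene$transcript_id
  if (!all(tx %in% names(object@exons)))
    msg <- c(msg, "every transcript must have an exons entry")
  if (length(msg)) msg else TRUE
})

#' Input genomic loci (peaks, SNPs or scored intervals)
#'
#' Thin wrapper around a `GRanges` of input loci with the metadata columns
#' `locus_id`, `score` (1 when the source BED had no score column) and
#' `is_snp` (width-1 loci). Coordinates are 1-based closed internally;
#' [readLociBed()] converts from BED's 0-based half-open convention.
#'
#' @slot ranges `GRanges` with metadata columns `locus_id`, `score`, `is_snp`.
#' @seealso [readLociBed()], [seq2gene()]
#' @export
setClass("LocusSet", slots = c(ranges = "GRanges"))

setValidity("LocusSet", function(object) {
  m <- mcols(object@ranges)
  msg <- character()
  need <- c("locus_id", "score", "is_snp")
  if (!all(need %in% names(m)))
    return("ranges must carry locus_id, score and is_snp metadata columns")
  if (anyDuplicated(m$locus_id)) msg <- c(msg, "locus_ids must be unique")
  if (!all(is.finite(m$score))) msg <- c(msg, "scores must be finite")
  if (any(width(object@ranges) < 1L)) msg <- c(msg, "loci must have width >= 1")
  if (any(m$is_snp & width(object@ranges) != 1L))
    msg <- c(msg, "SNP loci must have width 1")
  if (length(msg)) msg else TRUE
})

#' Many-to-many locus-to-gene mapping records
#'
#' The result of [seq2gene()]: one record per (locus, gene) pair, labelled
#' with its structural mapping type -- one of `cds`, `utr`, `exon`,
#' `intron`, `promoter`, `neighbor` -- and the signed distance from the
#' locus's nearest edge to the gene's TSS (negative when the locus lies
#' upstream of the TSS in the gene's orientation, 0 on TSS overlap).
#'
#' @slot records data.frame with columns `locus_id`, `chrom`, `start`,
#'   `end` (1-based closed), `score`, `gene_id`, `gene_symbol`, `type`,
#'   `distance`.
#' @slot parameters list: `radius`, `snpMode`, `promoterUp`, `promoterDown`.
#' @slot unmapped character vector of locus ids with zero records.
#' @export
setClass("MappingTable",
  slots = c(records = "data.frame", parameters = "list", unmapped = "character")
)

.mappingTypes <- c("cds", "utr", "exon", "intron", "promoter", "neighbor")

setValidity("MappingTable", function(object) {
  rec <- object@records
  need <- c("locus_id", "chrom", "start", "end", "score", "gene_id",
            "gene_symbol", "type", "distance")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(rec) && !all(rec$type %in% .mappingTypes))
    msg <- c(msg, "mapping type outside the six-label vocabulary")
  if (nrow(rec) &&
      anyDuplicated(paste(rec$locus_id, rec$gene_id, rec$type, sep = "\r")))
    msg <- c(msg, "(locus_id, gene_id, type) triples must be unique")
  nb <- rec$type == "neighbor"
  if (any(nb) && any(rec$distance[nb] == 0))
    msg <- c(msg, "neighbor records must have non-zero distance")
  if (length(msg)) msg else TRUE
})

#' Gene-set collection (GMT)
#'
#' Named gene sets as read from a GMT file: member ids are deduplicated,
#' set ids unique.
#'
#' @slot sets named list of character vectors (member gene ids).
#' @slot descriptions named character vector, parallel to `sets`.
#' @slot source character scalar, the file the collection came from.
#' @seealso [readGmt()], [filterSets()]
#' @export
setClass("GeneSetCollection",
  slots = c(sets = "list", descriptions = "character", source = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "set ids must be unique and named")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "set members must be deduplicated")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must be parallel to sets")
  if (length(msg)) msg else TRUE
})

#' Gene-by-sample score matrix (the gene profile)
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two assays:
#' `score` (the collapsed or user-supplied gene scores) and `nLoci`
#' (the number of contributing loci per gene and sample; all 0 for
#' user-supplied matrices). Rows are genes, columns samples.
#'
#' @seealso [collapseToGenes()], [mergeSamples()], [readGeneMatrix()]
#' @export
setClass("GeneScoreMatrix", contains = "SummarizedExperiment")

setValidity("GeneScoreMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  msg <- character()
  if (!all(c("score", "nLoci") %in% a))
    return("assays 'score' and 'nLoci' are required")
  if (anyNA(SummarizedExperiment::assay(object, "score")))
    msg <- c(msg, "score assay must have no missing values")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "rownames (gene ids) must be set and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "colnames (sample ids) must be set and unique")
  if (length(msg)) msg else TRUE
})

#' Gene-set-by-sample results (the gene-set profile)
#'
#' A [SummarizedExperiment::SummarizedExperiment] with assays `score`
#' (FAIME f, odds ratio, KS D or cumulative-rank z, per method), `p`
#' (empirical p for FAIME, analytic for the alternatives) and `q`
#' (Benjamini-Hochberg FDR, adjusted per sample across sets). Rows are
#' gene sets, columns samples; `rowData` carries `n_genes`, the
#' post-intersection set size. `metadata()` records the method and its
#' parameters.
#'
#' @seealso [scorePathways()]
#' @export
setClass("PathwayResult", contains = "SummarizedExperiment")

setValidity("PathwayResult", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("score", "p", "q") %in% a))
    return("assays 'score', 'p' and 'q' are required")
  p <- SummarizedExperiment::assay(object, "p")
  q <- SummarizedExperiment::assay(object, "q")
  msg <- character()
  if (any(p < 0 | p > 1, na.rm = TRUE)) msg <- c(msg, "p must lie in [0, 1]")
  if (any(q < p - 1e-12, na.rm = TRUE)) msg <- c(msg, "q must be >= p elementwise")
  if (length(msg)) msg else TRUE
})
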