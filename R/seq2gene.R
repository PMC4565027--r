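#' @include annotation-io.R
NULL

#' Construct a LocusSet
#'
#' Programmatic constructor for input loci. Coordinates are 1-based closed
#' (use [readLociBed()] for BED files, which converts from 0-based
#' half-open).
#'
#' @param chrom,start,end parallel vectors of locus coordinates (1-based
#'   closed).
#' @param locusId optional locus ids (default `locus_1`, `locus_2`, ...).
#' @param score numeric locus scores, recycled (default 1).
#' @return A [LocusSet]; width-1 loci are flagged as SNPs.
#' @export
LocusSet <- function(chrom, start, end, locusId = NULL, score = 1) {
  n <- length(start)
  if (length(end) != n) stop("start and end must have equal length")
  chrom <- rep_len(chrom, n)
  if (any(start > end)) stop("locus start > end")
  if (is.null(locusId)) locusId <- sprintf("locus_%d", seq_len(n))
  gr <- GRanges(chrom, IRanges(start, end))
  mcols(gr) <- S4Vectors::DataFrame(
    locus_id = as.character(locusId),
    score = as.numeric(rep_len(score, n)),
    is_snp = width(gr) == 1L)
  new("LocusSet", ranges = gr)
}

#' Read loci from a BED file
#'
#' Reads BED3+ (0-based half-open) into a [LocusSet] (1-based closed
#' internally). Column 4, when present and not `"."`, provides locus ids;
#' otherwise ids are `locus_<row>`. Loci of width 1 are flagged as SNPs.
#'
#' @param path path to a BED file; `track`/`browser`/`#` lines are skipped.
#' @param scoreColumn 1-based column index holding a numeric score, or
#'   `NULL` (default) for score 1 on every locus (pure count mode).
#' @return A [LocusSet], loci in file order.
#' @export
readLociBed <- function(path, scoreColumn = NULL) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) stop("no loci in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("malformed BED row ", which(lengths(fields) < 3L)[1],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(s0) || anyNA(e0))
    stop("non-numeric coordinate at BED row ", which(is.na(s0) | is.na(e0))[1])
  if (any(s0 >= e0))
    stop("start >= end at BED row ", which(s0 >= e0)[1])
  n <- length(lines)
  ids <- paste0("locus_", seq_len(n))
  has4 <- lengths(fields) >= 4L
  nm <- rep(NA_character_, n)
  nm[has4] <- vapply(fields[has4], `[`, "", 4L)
  use <- !is.na(nm) & nzchar(nm) & nm != "."
  ids[use] <- nm[use]
  if (anyDuplicated(ids))
    stop("duplicate locus ids in BED (column 4): ", ids[duplicated(ids)][1])
  score <- rep(1, n)
  if (!is.null(scoreColumn)) {
    if (any(lengths(fields) < scoreColumn))
      stop("BED row ", which(lengths(fields) < scoreColumn)[1],
           " has no column ", scoreColumn)
    sc <- suppressWarnings(as.numeric(vapply(fields, `[`, "", scoreColumn)))
    if (anyNA(sc))
      stop("non-numeric score at BED row ", which(is.na(sc))[1],
           ", column ", scoreColumn)
    score <- sc
  }
  LocusSet(chrom, s0 + 1, e0, locusId = ids, score = score)
}

#' @rdname accessors
#' @export
setMethod("loci", "LocusSet", function(x) x@ranges)

setMethod("length", "LocusSet", function(x) length(x@ranges))

setMethod("show", "LocusSet", function(object) {
  cat("LocusSet with", length(object@ranges), "loci (",
      sum(mcols(object@ranges)$is_snp), "SNPs )\n")
})

#' @rdname LocusSet
#' @param x a [LocusSet] (for `as.data.frame`, which returns the loci as a
#'   data.frame in 1-based closed coordinates).
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "LocusSet", function(x, ...) {
  gr <- x@ranges
  data.frame(locus_id = mcols(gr)$locus_id,
             chrom = as.character(seqnames(gr)),
             start = start(gr), end = end(gr),
             score = mcols(gr)$score, is_snp = mcols(gr)$is_snp,
             stringsAsFactors = FALSE)
})

#' Classify how a locus overlaps a gene
#'
#' Returns the single highest-priority structural label for a locus that
#' intersects a gene's body or promoter, under the specificity ordering
#' `cds > utr > exon > intron` for body overlaps; `promoter` only when the
#' locus intersects the promoter window but not the gene body. Labels are
#' resolved jointly over all of the gene's transcripts, so exonic overlap
#' of a non-coding transcript yields `exon` (never `cds`/`utr`).
#'
#' @param annotation a [GenomeAnnotation].
#' @param geneId gene to classify against.
#' @param chrom,start,end locus interval, 1-based closed.
#' @return One of `"cds"`, `"utr"`, `"exon"`, `"intron"`, `"promoter"`.
#'   Calling on a non-intersecting pair is a contract violation (error).
#' @export
classifyOverlap <- function(annotation, geneId, chrom, start, end) {
  stopifnot(is(annotation, "GenomeAnnotation"))
  gi <- match(geneId, names(annotation@genes))
  if (is.na(gi)) stop("unknown gene_id: ", geneId)
  lev <- union(seqlevels(annotation@genes), chrom)
  q <- GRanges(factor(chrom, levels = lev), IRanges(start, end))
  hits <- function(sub) {
    length(sub) > 0 &&
      length(findOverlaps(q, sub, ignore.strand = TRUE)) > 0
  }
  g <- annotation@genes[gi]
  tx <- annotation@txGene$transcript_id[annotation@txGene$gene_id == geneId]
  if (hits(g)) {
    if (hits(unlist(annotation@cds[tx]))) return("cds")
    if (hits(unlist(annotation@utrs[tx]))) return("utr")
    if (hits(unlist(annotation@exons[tx]))) return("exon")
    return("intron")
  }
  if (hits(annotation@promoters[gi])) return("promoter")
  stop("locus ", chrom, ":", start, "-", end,
       " does not intersect body or promoter of gene ", geneId)
}

## batched core: loci GRanges (with locus metadata) -> records data.frame
.mapLociBatch <- function(lr, annotation, radius, snpMode) {
  g <- annotation@genes
  emptyRec <- data.frame(locus_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         score = numeric(), gene_id = character(),
                         gene_symbol = character(), type = character(),
                         distance = numeric(), stringsAsFactors = FALSE)
  if (!length(lr)) return(emptyRec)
  lchr <- as.character(seqnames(lr))
  known <- lchr %in% seqlevels(g)
  if (!any(known)) return(emptyRec)
  idx <- which(known)
  q <- GRanges(factor(lchr[known], levels = seqlevels(g)),
               IRanges(start(lr)[known], end(lr)[known]))

  gid <- mcols(g)$gene_id
  gsym <- mcols(g)$gene_symbol
  tss <- mcols(g)$tss
  gstr <- as.character(strand(g))

  pairKey <- function(li, geneId) paste(li, geneId, sep = "\r")

  ## feature-level overlap keys (locus index x gene_id), per feature class
  txGeneVec <- setNames(annotation@txGene$gene_id,
                        annotation@txGene$transcript_id)
  featKeys <- function(frl) {
    u <- unlist(frl, use.names = FALSE)
    if (!length(u)) return(character())
    geneOfFeat <- rep(unname(txGeneVec[names(frl)]), lengths(frl))
    h <- findOverlaps(q, u, ignore.strand = TRUE)
    unique(pairKey(idx[queryHits(h)], geneOfFeat[subjectHits(h)]))
  }
  cdsK <- featKeys(annotation@cds)
  utrK <- featKeys(annotation@utrs)
  exonK <- featKeys(annotation@exons)

  bh <- findOverlaps(q, g, ignore.strand = TRUE)
  bLoc <- idx[queryHits(bh)]
  bGene <- subjectHits(bh)
  bKey <- pairKey(bLoc, gid[bGene])
  bType <- ifelse(bKey %in% cdsK, "cds",
                  ifelse(bKey %in% utrK, "utr",
                         ifelse(bKey %in% exonK, "exon", "intron")))

  ph <- findOverlaps(q, annotation@promoters, ignore.strand = TRUE)
  pLoc <- idx[queryHits(ph)]
  pGene <- subjectHits(ph)
  pKeep <- !pairKey(pLoc, gid[pGene]) %in% bKey
  pLoc <- pLoc[pKeep]
  pGene <- pGene[pKeep]

  sLoc <- c(bLoc, pLoc)
  sGene <- c(bGene, pGene)
  sType <- c(bType, rep("promoter", length(pLoc)))
  sKey <- pairKey(sLoc, gid[sGene])

  ## neighbor candidates: TSS within radius of the locus edge
  tssWin <- GRanges(seqnames(g), IRanges(pmax(1, tss - radius), tss + radius))
  nh <- findOverlaps(q, tssWin, ignore.strand = TRUE)
  nLoc <- idx[queryHits(nh)]
  nGene <- subjectHits(nh)
  nd <- .tssSignedDistance(start(lr)[nLoc], end(lr)[nLoc],
                           tss[nGene], gstr[nGene])
  hasBody <- unique(bLoc)
  eligible <- if (snpMode) rep(TRUE, length(nLoc)) else !(nLoc %in% hasBody)
  nKeep <- eligible & abs(nd) <= radius & nd != 0 &
    !pairKey(nLoc, gid[nGene]) %in% sKey
  nLoc <- nLoc[nKeep]
  nGene <- nGene[nKeep]
  nd <- nd[nKeep]

  allLoc <- c(sLoc, nLoc)
  allGene <- c(sGene, nGene)
  allType <- c(sType, rep("neighbor", length(nLoc)))
  sDist <- .tssSignedDistance(start(lr)[sLoc], end(lr)[sLoc],
                              tss[sGene], gstr[sGene])
  allDist <- c(sDist, nd)

  rec <- data.frame(
    locus_id = mcols(lr)$locus_id[allLoc],
    chrom = lchr[allLoc],
    start = start(lr)[allLoc],
    end = end(lr)[allLoc],
    score = mcols(lr)$score[allLoc],
    gene_id = gid[allGene],
    gene_symbol = gsym[allGene],
    type = allType,
    distance = allDist,
    stringsAsFactors = FALSE)
  rec <- rec[order(allLoc, abs(rec$distance), rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Map one locus to its candidate target genes
#'
#' Emits one mapping record per gene whose body or promoter the locus
#' intersects (typed by [classifyOverlap()]), plus `neighbor` records for
#' genes whose TSS lies within `radius` of the locus edge. Neighbor records
#' are emitted only for loci that touch no gene body -- unless `snpMode`
#' is `TRUE`, in which case intragenic loci also receive neighbor records
#' (a point variant may regulate a neighboring gene rather than its host).
#' Genes already reported as structural hits are never duplicated as
#' neighbors.
#'
#' @inheritParams classifyOverlap
#' @param locusId,score locus id and score carried into the records.
#' @param radius neighbor search radius in bp (default 100 kb).
#' @param snpMode logical; emit neighbor records even for intragenic loci.
#' @return data.frame of mapping records (possibly 0 rows), ordered by
#'   `|distance|` then `gene_id`.
#' @export
mapLocus <- function(annotation, chrom, start, end, locusId = "locus_1",
                     score = 1, radius = 1e5, snpMode = FALSE) {
  ls <- LocusSet(chrom, start, end, locusId = locusId, score = score)
  .mapLociBatch(ls@ranges, annotation, radius, snpMode)
}

#' Map genomic loci to target genes, many-to-many
#'
#' The locus-to-gene mapping step: every locus is linked to all candidate
#' target genes with a typed relation (`cds`, `utr`, `exon`, `intron`,
#' `promoter` or `neighbor`) and a signed TSS distance, per [mapLocus()].
#' A locus may map to several genes and a gene may receive several loci.
#'
#' @param lociSet a [LocusSet].
#' @param annotation a [GenomeAnnotation].
#' @param radius neighbor search radius in bp (default 100 kb).
#' @param snpMode logical; when `TRUE`, intragenic loci also receive
#'   neighbor records (SNP semantics).
#' @return A [MappingTable]; loci with zero records are listed in
#'   `unmappedLoci()`.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "cisPathway")
#' ann <- readGTF(gtf)
#' ls <- LocusSet("chr1", c(1100, 9000), c(1150, 9100))
#' seq2gene(ls, ann, radius = 5000)
#' @export
seq2gene <- function(lociSet, annotation, radius = 1e5, snpMode = FALSE) {
  stopifnot(is(lociSet, "LocusSet"), is(annotation, "GenomeAnnotation"),
            radius >= 0)
  lr <- lociSet@ranges
  params <- list(radius = radius, snpMode = snpMode,
                 promoterUp = annotation@provenance$promoterUp,
                 promoterDown = annotation@provenance$promoterDown)
  if (length(lr)) {
    unknownFrac <- mean(!as.character(seqnames(lr)) %in%
                          seqlevels(annotation@genes))
    if (unknownFrac > 0.9)
      stop("more than 90% of loci lie on chromosomes absent from the ",
           "annotation -- likely a chromosome-name dialect mismatch ",
           "('chr1' vs '1')")
  }
  rec <- .mapLociBatch(lr, annotation, radius, snpMode)
  unmapped <- setdiff(mcols(lr)$locus_id, rec$locus_id)
  new("MappingTable", records = rec, parameters = params,
      unmapped = as.character(unmapped))
}

#' @rdname accessors
#' @export
setMethod("mappingRecords", "MappingTable", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("mappingParams", "MappingTable", function(x) x@parameters)

#' @rdname accessors
#' @export
setMethod("unmappedLoci", "MappingTable", function(x) x@unmapped)

setMethod("show", "MappingTable", function(object) {
  rec <- object@records
  cat("MappingTable:", nrow(rec), "locus-gene records,",
      length(unique(rec$locus_id)), "loci mapped,",
      length(object@unmapped), "unmapped\n")
  if (nrow(rec))
    print(table(factor(rec$type, levels = .mappingTypes)))
  cat("  radius:", object@parameters$radius, "bp; snpMode:",
      object@parameters$snpMode, "\n")
})

#' Write a MappingTable as TSV
#'
#' Tab-separated records with a `#`-prefixed provenance header (package
#' version and mapping parameters). Coordinates are 1-based closed.
#'
#' @param x a [MappingTable].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMappingTable <- function(x, path) {
  stopifnot(is(x, "MappingTable"))
  hdr <- c(
    paste0("# cisPathway ",
           as.character(utils::packageVersion("cisPathway")),
           " mapping table"),
    paste0("# radius=", x@parameters$radius,
           " snpMode=", x@parameters$snpMode,
           " promoterUp=", x@parameters$promoterUp,
           " promoterDown=", x@parameters$promoterDown),
    paste0("# unmapped=", paste(x@unmapped, collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x@records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
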