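#' @include AllGenerics.R
NULL

## signed TSS distance, vectorized over pairs; 1-based closed coordinates.
## 0 when the locus covers the TSS; magnitude = coordinate difference from the
## nearest locus edge to the TSS; negative when the locus lies upstream of the
## TSS in the gene's orientation, positive downstream.
.tssSignedDistance <- function(start, end, tss, strand) {
  left <- tss < start                      # TSS on the lower-coordinate side
  right <- tss > end
  mag <- ifelse(left, start - tss, ifelse(right, tss - end, 0))
  upstream <- ifelse(strand == "+", right, left)
  ifelse(mag == 0, 0, ifelse(upstream, -mag, mag))
}

## strand-aware promoter window around a TSS, clamped at position 1;
## zero-width (end = start - 1) when the window is fully off-chromosome.
.promoterWindow <- function(tss, strand, up, down) {
  plus <- strand == "+"
  s <- ifelse(plus, tss - up, tss - down + 1)
  e <- ifelse(plus, tss + down - 1, tss + up)
  s <- pmax(1, s)
  e <- pmax(e, s - 1)
  cbind(start = s, end = e)
}

#' Read gene models from a GTF file
#'
#' Parses a GTF 2.2 file (1-based closed coordinates, attributes `gene_id`,
#' `transcript_id`, optionally `gene_name`) into a [GenomeAnnotation].
#' Transcript geometry is built from `exon` and `CDS` rows; explicit
#' `gene`/`transcript`/`UTR` rows are not required (genes lacking them are
#' synthesized from their exon rows). Per transcript, UTRs are derived as
#' exons minus CDS and introns as the transcript range minus its exons;
#' transcripts without CDS rows are treated as non-coding (empty CDS and
#' UTR). The gene span is the union range over the gene's transcripts, the
#' TSS its strand-aware 5' end, and the promoter a strand-aware window
#' around the TSS.
#'
#' @param path path to a GTF file.
#' @param promoterUp,promoterDown promoter window in bp upstream /
#'   downstream of the TSS (defaults 2000 and 0; the window is clamped at
#'   the chromosome start).
#' @param symbolAttr attribute holding the gene symbol (default
#'   `"gene_name"`; falls back to `gene_id` when absent).
#' @return A [GenomeAnnotation].
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "cisPathway")
#' readGTF(gtf)
#' @export
readGTF <- function(path, promoterUp = 2000, promoterDown = 0,
                    symbolAttr = "gene_name") {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  if (promoterUp < 0 || promoterDown < 0)
    stop("promoter window sizes must be non-negative")

  lines <- readLines(path)
  isData <- !grepl("^#", lines) & nzchar(lines)
  if (!any(isData)) stop("no gene records in '", path, "'")
  fields <- strsplit(lines[isData], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("malformed GTF line ", which(isData)[bad[1]],
         ": expected >= 9 tab-separated fields")
  ftype <- vapply(fields, `[`, "", 3L)
  fstrand <- vapply(fields, `[`, "", 7L)
  used <- ftype %in% c("exon", "CDS")
  badStrand <- which(used & !fstrand %in% c("+", "-"))
  if (length(badStrand))
    stop("unknown strand symbol '", fstrand[badStrand[1]], "' at GTF line ",
         which(isData)[badStrand[1]])
  if (!any(used)) stop("no gene records (no exon rows) in '", path, "'")

  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[mcols(gr)$type == "exon"]
  cdsRows <- gr[mcols(gr)$type == "CDS"]

  exGene <- as.character(mcols(ex)$gene_id)
  exTx <- mcols(ex)$transcript_id
  exTx <- if (is.null(exTx)) exGene else ifelse(is.na(exTx), exGene,
                                                as.character(exTx))
  txIds <- unique(exTx)
  exons <- reduce(S4Vectors::split(GenomicRanges::granges(ex),
                                   factor(exTx, levels = txIds)))

  if (length(cdsRows)) {
    cdsTx <- mcols(cdsRows)$transcript_id
    cdsTx <- if (is.null(cdsTx)) as.character(mcols(cdsRows)$gene_id) else
      as.character(cdsTx)
    orphan <- setdiff(cdsTx, txIds)
    if (length(orphan))
      stop("CDS rows without exon rows for transcript(s): ",
           paste(head(orphan, 3), collapse = ", "))
    cds <- reduce(S4Vectors::split(GenomicRanges::granges(cdsRows),
                                   factor(cdsTx, levels = txIds)))
  } else {
    cds <- reduce(S4Vectors::split(GenomicRanges::granges(ex[0]),
                                   factor(character(), levels = txIds)))
  }

  ## non-coding transcripts (no CDS rows) have no UTR: all-exon geometry
  utrs <- GRangesList(lapply(seq_along(txIds), function(i)
    if (length(cds[[i]]) == 0) cds[[i]]
    else GenomicRanges::setdiff(exons[[i]], cds[[i]])))
  introns <- GRangesList(lapply(seq_along(txIds), function(i) {
    e <- exons[[i]]
    GenomicRanges::setdiff(range(e), e)
  }))
  names(utrs) <- names(introns) <- txIds

  txGene <- unique(data.frame(transcript_id = exTx, gene_id = exGene,
                              stringsAsFactors = FALSE))
  if (anyDuplicated(txGene$transcript_id))
    stop("transcript assigned to multiple genes: ",
         txGene$transcript_id[duplicated(txGene$transcript_id)][1])

  sym <- mcols(ex)[[symbolAttr]]
  sym <- if (is.null(sym)) exGene else ifelse(is.na(sym), exGene,
                                              as.character(sym))
  geneSym <- vapply(split(sym, exGene), `[`, "", 1L)

  geneIds <- unique(exGene)
  gex <- S4Vectors::split(GenomicRanges::granges(ex),
                          factor(exGene, levels = geneIds))
  spanL <- range(gex)
  if (any(lengths(spanL) != 1L)) {
    badg <- geneIds[lengths(spanL) != 1L][1]
    stop("gene '", badg, "' has exons on multiple chromosomes or strands")
  }
  genes <- unlist(spanL, use.names = FALSE)
  st <- as.character(strand(genes))
  tss <- ifelse(st == "+", start(genes), end(genes))
  mcols(genes)$gene_id <- geneIds
  mcols(genes)$gene_symbol <- unname(geneSym[geneIds])
  mcols(genes)$tss <- as.integer(tss)
  names(genes) <- geneIds

  pw <- .promoterWindow(tss, st, promoterUp, promoterDown)
  promoters <- GRanges(seqnames(genes), IRanges(pw[, "start"], pw[, "end"]),
                       strand = strand(genes))
  mcols(promoters)$gene_id <- geneIds
  names(promoters) <- geneIds

  new("GenomeAnnotation", genes = genes, promoters = promoters,
      exons = exons, cds = cds, utrs = utrs, introns = introns,
      txGene = txGene,
      provenance = list(source = path, promoterUp = promoterUp,
                        promoterDown = promoterDown))
}

#' Write a GenomeAnnotation back to GTF
#'
#' Emits `gene`, `transcript`, `exon` and `CDS` rows reconstructing the
#' annotation's geometry, such that [readGTF()] on the written file yields
#' identical feature geometry (round-trip property).
#'
#' @param annotation a [GenomeAnnotation].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGTF <- function(annotation, path) {
  stopifnot(is(annotation, "GenomeAnnotation"))
  g <- annotation@genes
  txg <- annotation@txGene
  rows <- character()
  gtfRow <- function(chrom, feat, s, e, strand, attrs) {
    paste(chrom, "cisPathway", feat, s, e, ".", strand, ".", attrs,
          sep = "\t")
  }
  for (i in seq_along(g)) {
    gid <- mcols(g)$gene_id[i]
    sym <- mcols(g)$gene_symbol[i]
    chrom <- as.character(seqnames(g))[i]
    st <- as.character(strand(g))[i]
    gattr <- sprintf('gene_id "%s"; gene_name "%s";', gid, sym)
    rows <- c(rows, gtfRow(chrom, "gene", start(g)[i], end(g)[i], st, gattr))
    for (tx in txg$transcript_id[txg$gene_id == gid]) {
      tattr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                       gid, tx, sym)
      e <- annotation@exons[[tx]]
      rows <- c(rows,
                gtfRow(chrom, "transcript", min(start(e)), max(end(e)), st,
                       tattr),
                gtfRow(chrom, "exon", start(e), end(e), st, tattr))
      cd <- annotation@cds[[tx]]
      if (length(cd))
        rows <- c(rows, gtfRow(chrom, "CDS", start(cd), end(cd), st, tattr))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Genes overlapping an interval
#'
#' Returns every gene whose span or promoter intersects the query interval
#' (1-based closed). A gene hit in both its body and its promoter is
#' reported once, as a body hit.
#'
#' @param annotation a [GenomeAnnotation].
#' @param chrom chromosome name.
#' @param start,end query interval, 1-based closed.
#' @return data.frame with columns `gene_id` and `region`
#'   (`"body"` or `"promoter"`), sorted by `gene_id`. A chromosome absent
#'   from the annotation yields an empty result (with a message, not an
#'   error).
#' @export
queryOverlaps <- function(annotation, chrom, start, end) {
  stopifnot(is(annotation, "GenomeAnnotation"), start <= end)
  empty <- data.frame(gene_id = character(), region = character(),
                      stringsAsFactors = FALSE)
  g <- annotation@genes
  if (!chrom %in% seqlevels(g)) {
    message("chromosome '", chrom, "' not present in annotation")
    return(empty)
  }
  q <- GRanges(factor(chrom, levels = seqlevels(g)), IRanges(start, end))
  body <- subjectHits(findOverlaps(q, g, ignore.strand = TRUE))
  prom <- subjectHits(findOverlaps(q, annotation@promoters,
                                   ignore.strand = TRUE))
  prom <- setdiff(prom, body)
  out <- data.frame(
    gene_id = c(mcols(g)$gene_id[body], mcols(g)$gene_id[prom]),
    region = c(rep("body", length(body)), rep("promoter", length(prom))),
    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Genes with a TSS within a search radius of an interval
#'
#' Finds every gene whose TSS lies within `radius` bp of the interval's
#' nearest edge (closed inclusion, `|distance| <= radius`). The signed
#' distance is 0 when the interval covers the TSS, negative when the
#' interval lies upstream of the TSS in the gene's orientation, positive
#' downstream.
#'
#' @inheritParams queryOverlaps
#' @param radius maximum TSS-to-edge distance in bp (>= 0).
#' @return data.frame with columns `gene_id` and `distance`, ordered by
#'   `|distance|` then `gene_id`.
#' @export
queryRadius <- function(annotation, chrom, start, end, radius) {
  stopifnot(is(annotation, "GenomeAnnotation"), radius >= 0, start <= end)
  g <- annotation@genes
  empty <- data.frame(gene_id = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (!chrom %in% seqlevels(g)) {
    message("chromosome '", chrom, "' not present in annotation")
    return(empty)
  }
  onChrom <- as.character(seqnames(g)) == chrom
  if (!any(onChrom)) return(empty)
  gg <- g[onChrom]
  d <- .tssSignedDistance(start, end, mcols(gg)$tss,
                          as.character(strand(gg)))
  keep <- abs(d) <= radius
  out <- data.frame(gene_id = mcols(gg)$gene_id[keep], distance = d[keep],
                    stringsAsFactors = FALSE)
  out[order(abs(out$distance), out$gene_id), , drop = FALSE]
}

#' @rdname accessors
#' @export
setMethod("geneIds", "GenomeAnnotation", function(x) names(x@genes))

#' @rdname accessors
#' @export
setMethod("geneRanges", "GenomeAnnotation", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("promoterRanges", "GenomeAnnotation", function(x) x@promoters)

#' @rdname accessors
#' @export
setMethod("features", "GenomeAnnotation", function(x, type = "exon") {
  type <- match.arg(type, c("exon", "cds", "utr", "intron"))
  switch(type, exon = x@exons, cds = x@cds, utr = x@utrs, intron = x@introns)
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@genes), "genes,",
      nrow(object@txGene), "transcripts on",
      length(seqlevels(object@genes)), "chromosome(s)\n")
  cat("  promoter window:", object@provenance$promoterUp, "bp up /",
      object@provenance$promoterDown, "bp down of TSS\n")
  cat("  source:", object@provenance$source, "\n")
})
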