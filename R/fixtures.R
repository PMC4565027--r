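#' @include empirical-null.R
NULL

## draw locus scores from a named distribution family
.drawScores <- function(n, scoreDist) {
  fam <- scoreDist$family
  if (is.null(fam)) stop("scoreDist must name a 'family'")
  switch(fam,
    constant = rep(if (is.null(scoreDist$value)) 1 else scoreDist$value, n),
    normal = rnorm(n, scoreDist$mean %||% 0, scoreDist$sd %||% 1),
    uniform = runif(n, scoreDist$min %||% 0, scoreDist$max %||% 1),
    lognormal = rlnorm(n, scoreDist$meanlog %||% 0,
                       scoreDist$sdlog %||% 1),
    stop("unknown score distribution family: ", fam))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a deterministic toy genome annotation
#'
#' Writes a synthetic GTF of non-overlapping genes and returns it parsed
#' through [readGTF()], so the on-disk file and the in-memory annotation
#' are the same object by construction. Gene lengths are log-normal
#' (heavy-tailed, like real gene catalogs -- the feature that drives
#' gene-length bias in count-based enrichment), intergenic gaps
#' exponential, each gene has 1-3 transcripts with 1-4 exons, and a
#' configurable fraction of genes is non-coding (no CDS rows). A fixed
#' seed yields a byte-identical GTF across runs.
#'
#' @param path output GTF path (default: a tempfile).
#' @param nChroms,nGenes number of chromosomes and genes (genes split
#'   evenly across chromosomes).
#' @param chromLength chromosome length in bp; an error is raised if the
#'   drawn genes cannot be packed into it.
#' @param geneLengthMeanlog,geneLengthSdlog log-normal gene-length
#'   parameters (defaults `log(1e4)` and 0.8: median 10 kb, heavy tail).
#' @param gapMean mean exponential intergenic gap (default 10 kb).
#' @param promoterUp,promoterDown promoter window passed to [readGTF()].
#' @param fracNoncoding fraction of genes without CDS (default 0.2).
#' @param seed integer seed; all randomness is local to this call.
#' @return list with `path`, `annotation` (a [GenomeAnnotation]),
#'   `genes` (a truth data.frame: gene_id, chrom, start, end, strand,
#'   length, coding) and `chromLengths` (named vector).
#' @export
makeToyGenome <- function(path = tempfile(fileext = ".gtf"), nChroms = 1,
                          nGenes = 20, chromLength = 2e6,
                          geneLengthMeanlog = log(1e4),
                          geneLengthSdlog = 0.8, gapMean = 1e4,
                          promoterUp = 2000, promoterDown = 0,
                          fracNoncoding = 0.2, seed = 1) {
  stopifnot(nChroms >= 1, nGenes >= 1, chromLength > 0,
            fracNoncoding >= 0, fracNoncoding <= 1)
  perChrom <- diff(round(seq(0, nGenes, length.out = nChroms + 1)))
  rows <- character()
  truth <- list()
  .withSeed(seed, {
    gi <- 0L
    for (ci in seq_len(nChroms)) {
      chrom <- paste0("chr", ci)
      pos <- 0L
      for (gci in seq_len(perChrom[ci])) {
        gi <- gi + 1L
        gid <- sprintf("G%04d", gi)
        sym <- sprintf("SYM%04d", gi)
        gap <- max(2500L, as.integer(round(rexp(1, 1 / gapMean))))
        glen <- max(500L, as.integer(round(rlnorm(1, geneLengthMeanlog,
                                                  geneLengthSdlog))))
        gstart <- pos + gap
        gend <- gstart + glen - 1L
        if (gend > chromLength)
          stop("toy genome packing infeasible: gene ", gid,
               " exceeds chromosome length ", chromLength,
               " (reduce nGenes or gene lengths)")
        pos <- gend
        st <- sample(c("+", "-"), 1)
        coding <- runif(1) >= fracNoncoding
        attr0 <- sprintf('gene_id "%s"; gene_name "%s";', gid, sym)
        rows <- c(rows, paste(chrom, "toy", "gene", gstart, gend, ".",
                              st, ".", attr0, sep = "\t"))
        nTx <- sample(1:3, 1)
        for (ti in seq_len(nTx)) {
          tid <- sprintf("%s.T%d", gid, ti)
          tattr <- sprintf(
            'gene_id "%s"; transcript_id "%s"; gene_name "%s";',
            gid, tid, sym)
          if (ti == 1L) {
            ts <- gstart; te <- gend
          } else {
            off <- floor(glen * 0.3)
            ts <- gstart + sample(0:off, 1)
            te <- gend - sample(0:off, 1)
            if (te - ts + 1 < 400) { ts <- gstart; te <- gend }
          }
          tlen <- te - ts + 1L
          k <- sample(seq_len(max(1, min(4, tlen %/% 600))), 1)
          if (k == 1L) {
            exS <- ts; exE <- te
          } else {
            nseg <- 2L * k - 1L
            extra <- as.vector(stats::rmultinom(1, tlen - 60L * nseg,
                                                rep(1, nseg)))
            wseg <- 60L + extra
            bnd <- ts + cumsum(c(0L, wseg))
            exS <- bnd[seq(1, nseg, by = 2)]
            exE <- bnd[seq(2, nseg + 1, by = 2)] - 1L
            exE[k] <- te
          }
          rows <- c(rows,
                    paste(chrom, "toy", "transcript", ts, te, ".", st, ".",
                          tattr, sep = "\t"),
                    paste(chrom, "toy", "exon", exS, exE, ".", st, ".",
                          tattr, sep = "\t"))
          if (coding) {
            trim5 <- sample(0:min(120L, exE[1] - exS[1]), 1)
            trim3 <- sample(0:min(120L, exE[k] - exS[k]), 1)
            cs <- exS[1] + trim5
            ce <- exE[k] - trim3
            if (cs < ce) {
              keep <- exS <= ce & exE >= cs
              cS <- pmax(exS[keep], cs)
              cE <- pmin(exE[keep], ce)
              rows <- c(rows, paste(chrom, "toy", "CDS", cS, cE, ".", st,
                                    ".", tattr, sep = "\t"))
            }
          }
        }
        truth[[gi]] <- data.frame(gene_id = gid, chrom = chrom,
                                  start = gstart, end = gend, strand = st,
                                  length = glen, coding = coding,
                                  stringsAsFactors = FALSE)
      }
    }
  })
  writeLines(rows, path)
  truthDf <- do.call(rbind, truth)
  chromLengths <- setNames(rep(chromLength, nChroms),
                           paste0("chr", seq_len(nChroms)))
  list(path = path,
       annotation = readGTF(path, promoterUp = promoterUp,
                            promoterDown = promoterDown),
       genes = truthDf, chromLengths = chromLengths)
}

#' Sample null loci over a toy genome
#'
#' Draws loci carrying no biological signal. `mode = "uniform_genome"`
#' places loci uniformly over the concatenated genome, so the number of
#' loci hitting a gene is proportional to its length -- the null under
#' which count-based enrichment inherits gene-length bias.
#' `mode = "per_gene_poisson"` instead drops a Poisson number of loci
#' inside each gene span (length-free per-gene counts). Scores are i.i.d.
#' from `scoreDist`.
#'
#' @param chromLengths named vector of chromosome lengths (as returned by
#'   [makeToyGenome()]).
#' @param nLoci number of loci (>= 1; for `per_gene_poisson` the expected
#'   total).
#' @param mode `"uniform_genome"` (default) or `"per_gene_poisson"`.
#' @param annotation a [GenomeAnnotation]; required for
#'   `per_gene_poisson`.
#' @param lociWidth locus width in bp (default 200); forced to 1 when
#'   `snp = TRUE`.
#' @param snp logical; generate 1-bp SNP loci.
#' @param scoreDist list naming a score distribution: `family` one of
#'   `"constant"` (`value`), `"normal"` (`mean`, `sd`), `"uniform"`
#'   (`min`, `max`), `"lognormal"` (`meanlog`, `sdlog`).
#' @param seed integer seed; randomness is local to this call.
#' @param path optional BED5 output path (0-based half-open, score in
#'   column 5, re-readable via `readLociBed(path, scoreColumn = 5)`).
#' @return list with `loci` (a [LocusSet]) and `path` (or `NULL`).
#' @export
sampleNullLoci <- function(chromLengths, nLoci,
                           mode = c("uniform_genome", "per_gene_poisson"),
                           annotation = NULL, lociWidth = 200, snp = FALSE,
                           scoreDist = list(family = "constant", value = 1),
                           seed = 1, path = NULL) {
  mode <- match.arg(mode)
  if (nLoci < 1) stop("nLoci must be >= 1")
  stopifnot(!is.null(names(chromLengths)))
  w <- if (snp) 1L else as.integer(lociWidth)
  res <- .withSeed(seed, {
    if (mode == "uniform_genome") {
      chrom <- sample(names(chromLengths), nLoci, replace = TRUE,
                      prob = chromLengths)
      maxStart <- pmax(1, chromLengths[chrom] - w + 1)
      start <- floor(runif(nLoci, 1, maxStart + 1))
      data.frame(chrom = chrom, start = start, end = start + w - 1L,
                 stringsAsFactors = FALSE)
    } else {
      if (is.null(annotation))
        stop("per_gene_poisson mode requires an annotation")
      g <- geneRanges(annotation)
      counts <- rpois(length(g), nLoci / length(g))
      gi <- rep(seq_along(g), counts)
      maxStart <- pmax(start(g)[gi], end(g)[gi] - w + 1)
      s <- floor(runif(length(gi), start(g)[gi], maxStart + 1))
      data.frame(chrom = as.character(seqnames(g))[gi], start = s,
                 end = s + w - 1L, stringsAsFactors = FALSE)
    }
  })
  n <- nrow(res)
  if (n == 0) stop("no loci generated (all Poisson counts were 0); ",
                   "increase nLoci")
  scores <- .withSeed(seed + 1L, .drawScores(n, scoreDist))
  ids <- sprintf("null_%05d", seq_len(n))
  ls <- LocusSet(res$chrom, res$start, res$end, locusId = ids,
                 score = scores)
  if (!is.null(path)) {
    writeLines(paste(res$chrom, res$start - 1L, res$end, ids,
                     format(scores, trim = TRUE, digits = 10),
                     sep = "\t"), path)
  }
  list(loci = ls, path = path)
}

#' Generate random gene sets over a universe
#'
#' Samples `nSets` gene sets with sizes uniform over `sizeRange`. With
#' `weights` (e.g. gene lengths), membership is drawn with probability
#' proportional to the weight -- emulating real pathways whose member
#' genes have correlated lengths, the configuration under which naive
#' count-based enrichment shows gene-length bias.
#'
#' @param universe character vector of gene ids.
#' @param nSets number of sets.
#' @param sizeRange integer range of set sizes (default `c(5, 30)`).
#' @param weights optional per-gene sampling weights, parallel to
#'   `universe` (default: uniform).
#' @param seed integer seed; randomness is local to this call.
#' @param path optional GMT output path.
#' @return A [GeneSetCollection].
#' @export
makeToyGeneSets <- function(universe, nSets, sizeRange = c(5, 30),
                            weights = NULL, seed = 1, path = NULL) {
  stopifnot(length(universe) > sizeRange[2], nSets >= 1,
            sizeRange[1] >= 1, sizeRange[1] <= sizeRange[2])
  if (!is.null(weights)) stopifnot(length(weights) == length(universe))
  sets <- .withSeed(seed, {
    sizes <- sample(seq(sizeRange[1], sizeRange[2]), nSets, replace = TRUE)
    lapply(sizes, function(k)
      sort(sample(universe, k, prob = weights)))
  })
  ids <- sprintf("SET%04d", seq_len(nSets))
  names(sets) <- ids
  coll <- new("GeneSetCollection", sets = sets,
              descriptions = setNames(
                rep("synthetic gene set", nSets), ids),
              source = if (is.null(path)) "synthetic" else path)
  if (!is.null(path)) writeGmt(coll, path)
  coll
}

#' Spike an additive signal into a gene-set's scores
#'
#' Shifts the scores of the target genes by `delta` in every sample,
#' leaving all other genes untouched. Used to test signal recovery:
#' a spiked set should reach the minimal empirical p-value
#' `1/(nPerm+1)` when `delta` is large relative to the noise.
#'
#' @param x a [GeneScoreMatrix].
#' @param targetGenes gene ids to shift (must all be in the matrix).
#' @param delta additive shift (negative flips the enrichment sign).
#' @return A [GeneScoreMatrix] with shifted scores.
#' @export
spikeSignal <- function(x, targetGenes, delta) {
  stopifnot(is(x, "GeneScoreMatrix"))
  missing <- setdiff(targetGenes, rownames(x))
  if (length(missing))
    stop("target genes not in matrix: ", paste(head(missing, 3),
                                               collapse = ", "))
  sm <- scoreMatrix(x)
  sm[targetGenes, ] <- sm[targetGenes, , drop = FALSE] + delta
  GeneScoreMatrix(sm, lociCounts(x))
}
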