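#' @include fixtures.R
NULL

#' Run the full locus-to-pathway pipeline
#'
#' One-call composition of the two-step workflow: locus-to-gene mapping
#' ([seq2gene()]), per-gene collapsing ([collapseToGenes()]), gene-set
#' filtering ([filterSets()]) and gene-set scoring ([scorePathways()]).
#' The joint run is exactly equivalent to calling the stages separately
#' with the same parameters (a tested contract), so the two entry styles
#' are interchangeable.
#'
#' Inputs may be given as objects or as file paths (BED for loci, GTF for
#' the annotation, GMT for the gene sets), which are read with the
#' package's own readers.
#'
#' @param lociSet a [LocusSet] or a BED file path.
#' @param annotation a [GenomeAnnotation] or a GTF file path.
#' @param geneSets a [GeneSetCollection] or a GMT file path.
#' @param radius neighbor search radius in bp (default 100 kb).
#' @param snpMode logical; SNP semantics for intragenic loci (see
#'   [seq2gene()]).
#' @param scoreColumn BED score column passed to [readLociBed()] when
#'   `lociSet` is a path.
#' @param promoterUp,promoterDown promoter window passed to [readGTF()]
#'   when `annotation` is a path.
#' @param collapse collapse statistic (see [collapseToGenes()]).
#' @param sampleId sample name for the single-sample profile.
#' @param method,alpha,nPerm,seed,alternative,sigRule scoring parameters,
#'   passed to [scorePathways()].
#' @param minSize,maxSize gene-set size filter, applied against the
#'   collapsed gene universe (default `minSize = 5`).
#' @return list with elements `mapping` ([MappingTable]), `geneScores`
#'   ([GeneScoreMatrix]) and `pathways` ([PathwayResult]).
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "cisPathway")
#' bed <- system.file("extdata", "toy.bed", package = "cisPathway")
#' gmt <- system.file("extdata", "toy.gmt", package = "cisPathway")
#' res <- runSeq2pathway(bed, gtf, gmt, radius = 5000, scoreColumn = 5,
#'                       minSize = 2, nPerm = 50, seed = 1)
#' resultTable(res$pathways)
#' @export
runSeq2pathway <- function(lociSet, annotation, geneSets, radius = 1e5,
                           snpMode = FALSE, scoreColumn = NULL,
                           promoterUp = 2000, promoterDown = 0,
                           collapse = "max_abs", sampleId = "sample_1",
                           method = "faime", alpha = 5, nPerm = 1000,
                           seed = NULL, alternative = "two_sided",
                           sigRule = NULL, minSize = 5, maxSize = NULL) {
  if (is.character(lociSet))
    lociSet <- readLociBed(lociSet, scoreColumn = scoreColumn)
  if (is.character(annotation))
    annotation <- readGTF(annotation, promoterUp = promoterUp,
                          promoterDown = promoterDown)
  if (is.character(geneSets))
    geneSets <- readGmt(geneSets)
  stopifnot(is(lociSet, "LocusSet"), is(annotation, "GenomeAnnotation"),
            is(geneSets, "GeneSetCollection"))

  mapping <- seq2gene(lociSet, annotation, radius = radius,
                      snpMode = snpMode)
  geneScores <- collapseToGenes(mapping, sampleId = sampleId,
                                method = collapse)
  filtered <- filterSets(geneSets, universe = geneIds(geneScores),
                         minSize = minSize, maxSize = maxSize)
  if (!length(filtered))
    stop("gene2pathway: no gene set passed the size filter against the ",
         length(geneIds(geneScores)), "-gene universe; lower minSize or ",
         "check gene id conventions")
  pathways <- scorePathways(geneScores, filtered, method = method,
                            alpha = alpha, nPerm = nPerm, seed = seed,
                            alternative = alternative, sigRule = sigRule)
  list(mapping = mapping, geneScores = geneScores, pathways = pathways)
}
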