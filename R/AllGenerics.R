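#' @include AllClasses.R
NULL

#' Accessors for cisPathway classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `geneIds` returns gene identifiers; `sampleIds` sample identifiers;
#' `geneRanges`/`promoterRanges` the gene-span and promoter `GRanges` of a
#' [GenomeAnnotation]; `features` a per-transcript `GRangesList` of one
#' feature class; `loci` the `GRanges` inside a [LocusSet];
#' `mappingRecords`/`mappingParams`/`unmappedLoci` the parts of a
#' [MappingTable]; `geneSets`/`setIds`/`setDescriptions` the parts of a
#' [GeneSetCollection]; `scoreMatrix`/`lociCounts` the assays of a
#' [GeneScoreMatrix]; `pathwayScores`/`pathwayPvalues`/`pathwayQvalues`
#' the assays of a [PathwayResult]; `resultTable` a long-format data.frame
#' of a [PathwayResult].
#'
#' @param x an object of the class named above.
#' @param type for `features`: one of `"exon"`, `"cds"`, `"utr"`, `"intron"`.
#' @return See the description for each accessor.
#' @name accessors
#' @aliases geneIds sampleIds geneRanges promoterRanges features loci
#'   mappingRecords mappingParams unmappedLoci geneSets setIds
#'   setDescriptions scoreMatrix lociCounts pathwayScores pathwayPvalues
#'   pathwayQvalues resultTable
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "cisPathway")
#' ann <- readGTF(gtf)
#' geneIds(ann)
#' geneRanges(ann)
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname accessors
#' @export
setGeneric("promoterRanges", function(x) standardGeneric("promoterRanges"))

#' @rdname accessors
#' @export
setGeneric("features", function(x, type = "exon") standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname accessors
#' @export
setGeneric("mappingRecords", function(x) standardGeneric("mappingRecords"))

#' @rdname accessors
#' @export
setGeneric("mappingParams", function(x) standardGeneric("mappingParams"))

#' @rdname accessors
#' @export
setGeneric("unmappedLoci", function(x) standardGeneric("unmappedLoci"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("lociCounts", function(x) standardGeneric("lociCounts"))

#' @rdname accessors
#' @export
setGeneric("pathwayScores", function(x) standardGeneric("pathwayScores"))

#' @rdname accessors
#' @export
setGeneric("pathwayPvalues", function(x) standardGeneric("pathwayPvalues"))

#' @rdname accessors
#' @export
setGeneric("pathwayQvalues", function(x) standardGeneric("pathwayQvalues"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
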