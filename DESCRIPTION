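Package: cisPathway
Title: Pathway Analysis of Genomic Loci via Many-to-Many Gene Mapping
    and Single-Sample Gene-Set Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Associates genomic loci (ChIP-seq peaks, SNPs, or any scored
    intervals) with candidate target genes in a many-to-many mapping with
    typed relations (CDS, UTR, exon, intron, promoter, neighbor), collapses
    per-locus scores into gene-level profiles, and condenses gene profiles
    into per-sample gene-set (pathway) scores using a rank-weighted FAIME
    statistic together with Fisher's exact, Kolmogorov-Smirnov and
    cumulative-rank alternatives. Significance is assessed by
    permutation-based empirical p-values (shuffling gene scores within a
    sample) with Benjamini-Hochberg FDR control, which corrects the
    gene-length bias that inflates naive count-based enrichment of
    sequencing-derived loci. A deterministic synthetic-data generator
    produces toy GTF annotations, BED loci and GMT gene-set collections so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation-io.R'
    'seq2gene.R'
    'genescore.R'
    'gene2pathway.R'
    'empirical-null.R'
    'fixtures.R'
    'run.R'
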