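# two-gene fixture used throughout: GA coding (+) with an intron,
# GB non-coding (-) downstream on the same chromosome
two_gene_gtf <- function() {
  write_gtf_rows(list(
    c("chr1", "exon", 10001, 10500, "+", "GA", "GA.T1"),
    c("chr1", "exon", 11001, 11500, "+", "GA", "GA.T1"),
    c("chr1", "CDS", 10101, 10400, "+", "GA", "GA.T1"),
    c("chr1", "exon", 40001, 41000, "-", "GB", "GB.T1")))
}

test_that("readLociBed converts BED and validates input", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t101", "chr1\t200\t400\tpk\t3.7"), bed)
  ls <- readLociBed(bed)
  df <- as.data.frame(ls)
  # SNP: width-1 locus, default score 1
  expect_equal(df$start, c(101, 201))
  expect_equal(df$end, c(101, 400))
  expect_equal(df$is_snp, c(TRUE, FALSE))
  expect_equal(df$score, c(1, 1))
  expect_equal(df$locus_id, c("locus_1", "pk"))

  bed5 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t101\ts1\t3.7", "chr1\t200\t400\tpk\t-2e-3"), bed5)
  df5 <- as.data.frame(readLociBed(bed5, scoreColumn = 5))
  expect_equal(df5$score, c(3.7, -2e-3))

  # asking for a score column a row does not have is an error
  expect_error(readLociBed(bed, scoreColumn = 5), "column 5")
})

test_that("readLociBed rejects malformed rows", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t500\t400", bed)
  expect_error(readLociBed(bed), "row 1")

  bed2 <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tpk\tnot_a_number", bed2)
  expect_error(readLociBed(bed2, scoreColumn = 5), "row 1")
})

test_that("classifyOverlap follows the cds > utr > exon > intron > promoter priority", {
  ann <- readGTF(two_gene_gtf())
  cases <- list(
    list(10150, 10160, "cds"),      # inside the CDS
    list(10020, 10050, "utr"),      # 5' UTR segment of the coding exon
    list(10090, 10150, "cds"),      # straddles utr/cds: cds outranks utr
    list(10450, 10600, "utr"),      # straddles utr/intron: utr outranks intron
    list(10600, 10700, "intron"),
    list(40100, 40200, "exon"),     # non-coding transcript: exon, never cds/utr
    list(40990, 41200, "exon"),     # straddles exon/promoter: body hit wins
    list(9500, 9800, "promoter"),   # upstream window of GA, no body overlap
    list(41100, 41500, "promoter")) # minus-strand promoter of GB
  for (cs in cases)
    expect_equal(classifyOverlap(ann, if (cs[[1]] > 20000) "GB" else "GA",
                                 "chr1", cs[[1]], cs[[2]]), cs[[3]],
                 label = paste(cs[[1]], cs[[2]]))
  expect_error(classifyOverlap(ann, "GA", "chr1", 30000, 30100),
               "does not intersect")
})

test_that("mapLocus neighbor rule and SNP mode behave per contract", {
  # GA TSS at 10001, GB TSS at 41000
  ann <- readGTF(two_gene_gtf())

  # intergenic locus: TSS distances 3 kb (GA, upstream) and 8 kb (GB)
  rec <- mapLocus(ann, "chr1", 6901, 7001, radius = 5000)
  expect_equal(rec$gene_id, "GA")
  expect_equal(rec$type, "neighbor")
  expect_equal(rec$distance, -3000)

  # intronic locus in GA; GB TSS far: snpMode off -> intron record only
  rec2 <- mapLocus(ann, "chr1", 10600, 10700, radius = 50000)
  expect_equal(rec2$type, "intron")
  expect_equal(rec2$gene_id, "GA")

  # same locus, snpMode on -> intron + neighbor (superset of non-SNP output)
  rec3 <- mapLocus(ann, "chr1", 10600, 10700, radius = 50000, snpMode = TRUE)
  expect_setequal(rec3$type, c("intron", "neighbor"))
  expect_equal(rec3$gene_id[rec3$type == "neighbor"], "GB")
  expect_true(all(paste(rec2$gene_id, rec2$type) %in%
                  paste(rec3$gene_id, rec3$type)))
})

test_that("seq2gene handles edge cases and detects chromosome dialect mismatch", {
  ann <- readGTF(two_gene_gtf())

  empty <- LocusSet(character(), integer(), integer())
  mt <- seq2gene(empty, ann)
  expect_equal(nrow(mappingRecords(mt)), 0)
  expect_length(unmappedLoci(mt), 0)

  # one locus spanning both genes' neighborhoods -> many-to-many
  wide <- LocusSet("chr1", 10400, 40100, locusId = "wide")
  mtw <- seq2gene(wide, ann, radius = 1000)
  expect_equal(sort(mtw@records$gene_id), c("GA", "GB"))

  # all loci beyond radius of any gene -> all unmapped
  far <- LocusSet("chr1", c(200000, 300000), c(200100, 300100))
  mtf <- seq2gene(far, ann, radius = 1000)
  expect_equal(nrow(mappingRecords(mtf)), 0)
  expect_setequal(unmappedLoci(mtf), c("locus_1", "locus_2"))

  # "1" vs "chr1" dialect
  bad <- LocusSet("1", 10001, 10100)
  expect_error(seq2gene(bad, ann), "dialect")
})

test_that("mapping is monotone in radius and dominated by SNP mode", {
  f <- makeToyGenome(nGenes = 25, seed = 31)
  nl <- sampleNullLoci(f$chromLengths, 120, lociWidth = 300,
                       scoreDist = list(family = "normal"), seed = 32)
  key <- function(mt) {
    r <- mappingRecords(mt)
    paste(r$locus_id, r$gene_id, r$type)
  }
  prev <- NULL
  for (radius in c(0, 2000, 20000, 1e5)) {
    cur <- key(seq2gene(nl$loci, f$annotation, radius = radius))
    if (!is.null(prev)) expect_true(all(prev %in% cur), label = radius)
    prev <- cur
    snp <- key(seq2gene(nl$loci, f$annotation, radius = radius,
                        snpMode = TRUE))
    expect_true(all(cur %in% snp), label = paste("snp", radius))
  }
})

test_that("every record is consistent with classifyOverlap and queryRadius", {
  f <- makeToyGenome(nGenes = 20, seed = 41)
  nl <- sampleNullLoci(f$chromLengths, 80, lociWidth = 500,
                       scoreDist = list(family = "uniform"), seed = 42)
  radius <- 20000
  mt <- seq2gene(nl$loci, f$annotation, radius = radius)
  rec <- mappingRecords(mt)
  expect_gt(nrow(rec), 0)
  for (i in seq_len(nrow(rec))) {
    if (rec$type[i] == "neighbor") {
      qr <- queryRadius(f$annotation, rec$chrom[i], rec$start[i],
                        rec$end[i], radius)
      expect_true(rec$gene_id[i] %in% qr$gene_id)
      expect_equal(qr$distance[match(rec$gene_id[i], qr$gene_id)],
                   rec$distance[i])
      expect_true(abs(rec$distance[i]) > 0 &&
                  abs(rec$distance[i]) <= radius)
    } else {
      expect_equal(classifyOverlap(f$annotation, rec$gene_id[i],
                                   rec$chrom[i], rec$start[i], rec$end[i]),
                   rec$type[i])
    }
  }
})
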