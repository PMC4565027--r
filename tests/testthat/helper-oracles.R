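# Independent oracles: plain base-R reimplementations used to cross-check
# the package (no GRanges/IRanges machinery, no package internals).
# Intervals are 2-column matrices (start, end), 1-based closed.

orc_overlaps <- function(s, e, ivl) {
  nrow(ivl) > 0 && any(ivl[, 1] <= e & ivl[, 2] >= s)
}

# A minus union(B), both interval matrices
orc_setdiff <- function(A, B) {
  out <- NULL
  for (i in seq_len(nrow(A))) {
    segs <- list(c(A[i, 1], A[i, 2]))
    for (j in seq_len(nrow(B))) {
      bs <- B[j, 1]; be <- B[j, 2]
      segs <- unlist(lapply(segs, function(sg) {
        if (be < sg[1] || bs > sg[2]) return(list(sg))
        res <- list()
        if (bs > sg[1]) res <- c(res, list(c(sg[1], bs - 1)))
        if (be < sg[2]) res <- c(res, list(c(be + 1, sg[2])))
        res
      }), recursive = FALSE)
    }
    for (sg in segs) out <- rbind(out, sg)
  }
  if (is.null(out)) matrix(numeric(), 0, 2) else unname(out)
}

orc_parse_gtf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(f, `[`, "", 1L), type = vapply(f, `[`, "", 3L),
    start = as.numeric(vapply(f, `[`, "", 4L)),
    end = as.numeric(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L), attr = vapply(f, `[`, "", 9L),
    stringsAsFactors = FALSE)
  df$gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", df$attr)
  df$tx_id <- ifelse(grepl('transcript_id "', df$attr),
                     sub('.*transcript_id "([^"]+)".*', "\\1", df$attr),
                     df$gene_id)
  df
}

# per-gene geometry derived from exon/CDS rows only, as a plain list
orc_gene_models <- function(gtf, promoterUp = 2000, promoterDown = 0) {
  ex <- gtf[gtf$type == "exon", ]
  cds <- gtf[gtf$type == "CDS", ]
  models <- list()
  for (gid in unique(ex$gene_id)) {
    ge <- ex[ex$gene_id == gid, ]
    chrom <- ge$chrom[1]; strand <- ge$strand[1]
    span <- c(min(ge$start), max(ge$end))
    tss <- if (strand == "+") span[1] else span[2]
    if (strand == "+") {
      ps <- tss - promoterUp; pe <- tss + promoterDown - 1
    } else {
      ps <- tss - promoterDown + 1; pe <- tss + promoterUp
    }
    ps <- max(1, ps)
    txs <- list()
    for (tid in unique(ge$tx_id)) {
      te <- ge[ge$tx_id == tid, c("start", "end")]
      te <- as.matrix(te[order(te$start), , drop = FALSE])
      tc <- cds[cds$tx_id == tid, c("start", "end")]
      tc <- as.matrix(tc[order(tc$start), , drop = FALSE])
      txspan <- matrix(c(min(te[, 1]), max(te[, 2])), 1)
      txs[[tid]] <- list(exons = te, cds = tc,
                         utr = if (nrow(tc) == 0) tc
                               else orc_setdiff(te, tc),
                         introns = orc_setdiff(txspan, te))
    }
    models[[gid]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                          span = span, tss = tss, promoter = c(ps, pe),
                          txs = txs)
  }
  models
}

orc_distance <- function(s, e, tss, strand) {
  mag <- if (tss < s) s - tss else if (tss > e) tss - e else 0
  if (mag == 0) return(0)
  upstream <- if (strand == "+") tss > e else tss < s
  if (upstream) -mag else mag
}

orc_classify <- function(s, e, gm) {
  if (gm$span[1] <= e && gm$span[2] >= s) {
    anyhit <- function(field)
      any(vapply(gm$txs, function(tx) orc_overlaps(s, e, tx[[field]]), TRUE))
    if (anyhit("cds")) return("cds")
    if (anyhit("utr")) return("utr")
    if (anyhit("exons")) return("exon")
    return("intron")  # intronic or inside union-span between transcripts
  }
  if (gm$promoter[1] <= e && gm$promoter[2] >= s) return("promoter")
  NA_character_
}

# full brute-force mapping: all (locus x gene) pairs, loci as a data.frame
# with locus_id, chrom, start, end (1-based closed)
orc_map <- function(lociDf, models, radius, snp) {
  rows <- list()
  for (i in seq_len(nrow(lociDf))) {
    s <- lociDf$start[i]; e <- lociDf$end[i]; chrom <- lociDf$chrom[i]
    struct <- character(); sdist <- numeric()
    bodyHit <- FALSE
    for (gm in models) {
      if (gm$chrom != chrom) next
      lab <- orc_classify(s, e, gm)
      if (is.na(lab)) next
      if (lab != "promoter") bodyHit <- TRUE
      struct[gm$gene_id] <- lab
      sdist[gm$gene_id] <- orc_distance(s, e, gm$tss, gm$strand)
    }
    nb <- character(); nbd <- numeric()
    if (!bodyHit || snp) {
      for (gm in models) {
        if (gm$chrom != chrom || gm$gene_id %in% names(struct)) next
        d <- orc_distance(s, e, gm$tss, gm$strand)
        if (d != 0 && abs(d) <= radius) {
          nb[gm$gene_id] <- "neighbor"
          nbd[gm$gene_id] <- d
        }
      }
    }
    gids <- c(names(struct), names(nb))
    if (length(gids))
      rows[[i]] <- data.frame(locus_id = lociDf$locus_id[i],
                              gene_id = gids,
                              type = c(unname(struct), unname(nb)),
                              distance = c(unname(sdist), unname(nbd)),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_id = character(), gene_id = character(),
                      type = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  out[order(out$locus_id, out$gene_id, out$type), , drop = FALSE]
}

# exact hypergeometric upper tail P[X >= a], X ~ Hyper(N, K in-set, n drawn)
orc_hyper_tail <- function(a, K, N, n) {
  xs <- a:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# brute-force two-sample KS statistic
orc_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), 0)))
}

# exhaustive rank-subset enumeration for the cumulative rank test
orc_ranksum_p <- function(x, k, Tobs, alternative) {
  r <- rank(-x, ties.method = "average")
  sums <- colSums(combn(r, k))
  eps <- 1e-9
  pl <- mean(sums <= Tobs + eps)
  ph <- mean(sums >= Tobs - eps)
  switch(alternative, greater = pl, less = ph,
         two_sided = min(1, 2 * min(pl, ph)))
}

# small hand-built GTF writer: rows is a list of c(chrom, type, start, end,
# strand, gene_id, tx_id or NA)
write_gtf_rows <- function(rows, path = tempfile(fileext = ".gtf")) {
  ln <- vapply(rows, function(r) {
    attr <- if (is.na(r[7]))
      sprintf('gene_id "%s"; gene_name "%s";', r[6], r[6])
    else
      sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
              r[6], r[7], r[6])
    paste(r[1], "toy", r[2], r[3], r[4], ".", r[5], ".", attr, sep = "\t")
  }, "")
  writeLines(ln, path)
  path
}

# combine LocusSets / data.frames of loci into one LocusSet
combine_loci <- function(...) {
  dfs <- lapply(list(...), function(x)
    if (is(x, "LocusSet")) as.data.frame(x) else x)
  df <- do.call(rbind, dfs)
  LocusSet(df$chrom, df$start, df$end, locusId = df$locus_id,
           score = df$score)
}
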