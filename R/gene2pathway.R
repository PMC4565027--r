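#' @include genescore.R
NULL

#' Read gene sets from a GMT file
#'
#' One set per line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are deduplicated with a warning;
#' duplicate set ids or lines with fewer than 3 fields are errors.
#'
#' @param path path to a GMT file.
#' @return A [GeneSetCollection].
#' @export
readGmt <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", which(keep)[short[1]], " has fewer than 3 fields")
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set_id in GMT: ", ids[duplicated(ids)][1])
  desc <- vapply(fields, `[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  hadDup <- vapply(members, anyDuplicated, 0L) > 0L
  if (any(hadDup))
    warning("duplicate genes within set(s) ",
            paste(head(ids[hadDup], 3), collapse = ", "),
            " were deduplicated")
  members <- lapply(members, unique)
  new("GeneSetCollection", sets = setNames(members, ids),
      descriptions = setNames(desc, ids), source = path)
}

#' Write a GeneSetCollection as GMT
#'
#' @param x a [GeneSetCollection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  lines <- vapply(names(x@sets), function(id)
    paste(c(id, x@descriptions[[id]], x@sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets against a gene universe
#'
#' Members are first intersected with the universe; sets whose
#' post-intersection size falls below `minSize` (default 5, the
#' conventional floor below which set statistics are unstable) or above
#' `maxSize` are removed. The returned sets carry the intersected
#' members, so the operation is idempotent.
#'
#' @param x a [GeneSetCollection].
#' @param universe character vector of gene ids (non-empty).
#' @param minSize minimum post-intersection size (>= 1).
#' @param maxSize maximum post-intersection size, or `NULL` for none.
#' @return A filtered [GeneSetCollection].
#' @export
filterSets <- function(x, universe, minSize = 5, maxSize = NULL) {
  stopifnot(is(x, "GeneSetCollection"))
  if (!length(universe)) stop("universe must be non-empty")
  if (minSize < 1) stop("minSize must be >= 1")
  inter <- lapply(x@sets, intersect, universe)
  sz <- lengths(inter)
  keep <- sz >= minSize
  if (!is.null(maxSize)) keep <- keep & sz <= maxSize
  new("GeneSetCollection", sets = inter[keep],
      descriptions = x@descriptions[keep], source = x@source)
}

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("setIds", "GeneSetCollection", function(x) names(x@sets))

#' @rdname accessors
#' @export
setMethod("setDescriptions", "GeneSetCollection",
          function(x) x@descriptions)

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat("GeneSetCollection: ", length(object@sets), " sets; sizes ",
      if (length(sz)) paste0(min(sz), "-", max(sz)) else "-",
      "; source: ", object@source, "\n", sep = "")
})

## FAIME on one sample: ranks descending (1 = highest score, ties
## averaged), exponential rank down-weighting, in-set vs out-set contrast.
.faime1 <- function(x, inMask, alpha) {
  N <- length(x)
  r <- rank(-x, ties.method = "average")
  w <- x * exp(-alpha * r / N)
  mean(w[inMask]) - mean(w[!inMask])
}

.memberMask <- function(x, members) {
  m <- names(x) %in% members
  if (!any(m) || all(m))
    stop("set must be a proper non-empty subset of the gene universe")
  m
}

#' Single-sample FAIME gene-set score
#'
#' The rank-weighted FAIME statistic: per sample, gene scores `x_g` are
#' ranked descending (ties averaged), weighted
#' `w_g = x_g * exp(-alpha * r_g / N)`, and the set score is
#' `f = mean(w, in-set) - mean(w, out-set)`. The exponential factor
#' down-weights low-ranked genes so the contrast is driven by each
#' sample's top signal; `alpha` controls how fast the weight decays.
#' `f` is exactly antisymmetric under set complementation and 0 when all
#' gene scores are equal.
#'
#' @param x a named numeric vector of gene scores (one sample) or a
#'   [GeneScoreMatrix].
#' @param members character vector of member gene ids; the intersection
#'   with the universe must be a proper non-empty subset.
#' @param alpha positive rank-weight exponent (default 5).
#' @return A numeric scalar (vector input) or a named per-sample vector
#'   ([GeneScoreMatrix] input).
#' @export
faimeScore <- function(x, members, alpha = 5) {
  stopifnot(alpha > 0)
  if (is(x, "GeneScoreMatrix")) {
    sm <- scoreMatrix(x)
    return(vapply(colnames(sm), function(s)
      faimeScore(setNames(sm[, s], rownames(sm)), members, alpha), 0))
  }
  stopifnot(is.numeric(x), !is.null(names(x)))
  if (length(x) < 2) stop("gene universe must have at least 2 genes")
  .faime1(x, .memberMask(x, members), alpha)
}

#' Fisher's exact enrichment test for a gene set
#'
#' Binarizes the gene scores of one sample into significant /
#' non-significant by an explicit rule (there is no default: the choice
#' of threshold is experiment-specific and a silent default would
#' manufacture results), builds the 2x2 in-set x significant table, and
#' computes the one-sided enrichment p-value as the exact hypergeometric
#' upper tail. The odds ratio uses the Haldane 0.5 correction only when a
#' table cell is 0 (the p-value is unaffected).
#'
#' @param x named numeric vector of gene scores (one sample).
#' @param members member gene ids (proper non-empty subset of the
#'   universe).
#' @param sigRule either `list(type = "threshold", value = t)` (significant
#'   means score >= t) or `list(type = "top_k", k = k)` (the k top-scoring
#'   genes, ties broken by gene id).
#' @return list with `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
fisherSetTest <- function(x, members, sigRule) {
  stopifnot(is.numeric(x), !is.null(names(x)))
  if (!is.list(sigRule) || is.null(sigRule$type) ||
      !sigRule$type %in% c("threshold", "top_k"))
    stop("sigRule must be list(type = 'threshold', value = t) or ",
         "list(type = 'top_k', k = k)")
  inSet <- .memberMask(x, members)
  sig <- switch(sigRule$type,
    threshold = {
      if (is.null(sigRule$value)) stop("sigRule 'threshold' needs a value")
      x >= sigRule$value
    },
    top_k = {
      k <- sigRule$k
      if (is.null(k) || k < 1 || k > length(x))
        stop("sigRule 'top_k' needs 1 <= k <= number of genes")
      seq_along(x) %in% order(-x, names(x))[seq_len(k)]
    })
  if (all(sig) || !any(sig))
    stop("significance rule (", sigRule$type, ") marks ",
         if (all(sig)) "all" else "no", " genes significant; degenerate ",
         "margin")
  a <- sum(inSet & sig); b <- sum(inSet & !sig)
  cc <- sum(!inSet & sig); d <- sum(!inSet & !sig)
  N <- length(x); K <- a + b; n <- a + cc
  p <- phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  oddsRatio <- if (a == 0 || b == 0 || cc == 0 || d == 0)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else (a * d) / (b * cc)
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(c("in_set", "out_set"),
                                c("significant", "not_significant")))
  list(odds_ratio = oddsRatio, p = p, table = tab)
}

#' Kolmogorov-Smirnov gene-set test
#'
#' Two-sample two-sided KS test comparing the score distribution of in-set
#' genes against out-set genes for one sample;
#' `D = sup |ECDF_in - ECDF_out|` with the asymptotic p-value.
#'
#' @inheritParams fisherSetTest
#' @return list with `D` and `p`.
#' @export
ksSetTest <- function(x, members) {
  stopifnot(is.numeric(x), !is.null(names(x)))
  inSet <- .memberMask(x, members)
  kt <- suppressWarnings(ks.test(x[inSet], x[!inSet],
                                 alternative = "two.sided", exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Cumulative rank gene-set test
#'
#' Sums the descending ranks (ties averaged) of the in-set genes:
#' `T = sum of in-set ranks`. Under the null of exchangeable ranks,
#' `E[T] = k(N+1)/2` and `Var[T] = k(N-k)(N+1)/12`; the z-score uses a
#' 0.5 continuity correction toward the mean. For `N <= 10` the p-value is
#' computed by exhaustive enumeration of all `choose(N, k)` rank subsets
#' instead of the normal approximation. `"greater"` means greater
#' enrichment, i.e. in-set scores ranked high (small `T`, lower tail).
#'
#' @inheritParams fisherSetTest
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return list with `statistic` (T), `z`, `p`, and `exact` (logical,
#'   whether the enumeration path was used).
#' @export
cumulativeRankTest <- function(x, members,
                               alternative = c("two_sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x), !is.null(names(x)))
  inSet <- .memberMask(x, members)
  N <- length(x)
  k <- sum(inSet)
  r <- rank(-x, ties.method = "average")
  T <- sum(r[inSet])
  E <- k * (N + 1) / 2
  V <- k * (N - k) * (N + 1) / 12
  dz <- T - E
  Tadj <- if (abs(dz) < 0.5) E else T - sign(dz) * 0.5
  z <- (Tadj - E) / sqrt(V)
  if (N <= 10) {
    sums <- colSums(combn(r, k))
    eps <- 1e-9
    pLow <- mean(sums <= T + eps)
    pHigh <- mean(sums >= T - eps)
    exact <- TRUE
  } else {
    pLow <- pnorm(z)
    pHigh <- pnorm(z, lower.tail = FALSE)
    exact <- FALSE
  }
  p <- switch(alternative,
              greater = pLow,
              less = pHigh,
              two_sided = min(1, 2 * min(pLow, pHigh)))
  list(statistic = T, z = z, p = p, exact = exact)
}

#' Score all gene sets across all samples
#'
#' Condenses a gene-by-sample profile into a gene-set-by-sample profile:
#' the chosen statistic is applied per (set, sample). For
#' `method = "faime"` the p-value is the permutation empirical p from
#' [empiricalP()] (gene scores shuffled within the sample; the stream for
#' set `i`, sample `j` is seeded with `seed + (j-1)*nSets + (i-1)`, so the
#' result is reproducible and equals calling [faimeScore()] +
#' [empiricalP()] manually with that seed). The alternative tests use
#' their analytic p-values. Benjamini-Hochberg q-values are computed per
#' sample across sets.
#'
#' @param x a [GeneScoreMatrix].
#' @param collection a [GeneSetCollection], already filtered against the
#'   matrix universe (see [filterSets()]); sets that are empty or cover
#'   the whole universe after intersection are an error.
#' @param method `"faime"` (default), `"fisher"`, `"ks"` or
#'   `"cumulative_rank"`.
#' @param alpha FAIME rank-weight exponent (default 5).
#' @param nPerm number of permutations for the FAIME empirical p
#'   (default 1000).
#' @param seed integer base seed for the permutation streams, or `NULL`
#'   to use the current RNG state (not reproducible).
#' @param alternative extremity rule for empirical / cumulative-rank
#'   p-values: `"two_sided"` (default), `"greater"`, `"less"`.
#' @param sigRule significance rule for `method = "fisher"`; see
#'   [fisherSetTest()]. Required for that method.
#' @return A [PathwayResult] with assays `score` (FAIME f, odds ratio,
#'   KS D, or cumulative-rank z), `p` and `q`.
#' @export
scorePathways <- function(x, collection,
                          method = c("faime", "fisher", "ks",
                                     "cumulative_rank"),
                          alpha = 5, nPerm = 1000, seed = NULL,
                          alternative = "two_sided", sigRule = NULL) {
  method <- match.arg(method)
  stopifnot(is(x, "GeneScoreMatrix"), is(collection, "GeneSetCollection"),
            nPerm >= 1, alpha > 0)
  universe <- rownames(x)
  sets <- lapply(geneSets(collection), intersect, universe)
  if (!length(sets))
    stop("no gene sets to score; check minSize and the gene universe ",
         "(filterSets)")
  sz <- lengths(sets)
  if (any(sz == 0 | sz == length(universe)))
    stop("set '", names(sets)[which(sz == 0 | sz == length(universe))[1]],
         "' is empty or spans the whole universe after intersection; ",
         "run filterSets against the matrix universe first")
  sm <- scoreMatrix(x)
  nSets <- length(sets)
  nSamp <- ncol(sm)
  score <- p <- matrix(NA_real_, nSets, nSamp,
                       dimnames = list(names(sets), colnames(sm)))
  for (j in seq_len(nSamp)) {
    xv <- setNames(sm[, j], universe)
    if (method == "fisher") {
      if (is.null(sigRule))
        stop("method 'fisher' requires an explicit sigRule ",
             "(threshold or top_k); no default is provided")
      for (i in seq_len(nSets)) {
        ft <- fisherSetTest(xv, sets[[i]], sigRule)
        score[i, j] <- ft$odds_ratio
        p[i, j] <- ft$p
      }
    } else if (method == "ks") {
      for (i in seq_len(nSets)) {
        kt <- ksSetTest(xv, sets[[i]])
        score[i, j] <- kt$D
        p[i, j] <- kt$p
      }
    } else if (method == "cumulative_rank") {
      for (i in seq_len(nSets)) {
        ct <- cumulativeRankTest(xv, sets[[i]], alternative = alternative)
        score[i, j] <- ct$z
        p[i, j] <- ct$p
      }
    } else {
      ## fast permutation path: the ranks of a permuted score vector are
      ## the permuted ranks, so each permuted FAIME value is the in/out
      ## contrast of the fixed weight vector w at permuted positions.
      ## RNG consumption (one sample.int(N) per permutation) and floating
      ## arithmetic are identical to empiricalP() + .faime1 on the
      ## shuffled vector, so results are bit-identical with the manual
      ## two-step call at the documented per-(set, sample) seed.
      N <- length(xv)
      r <- rank(-xv, ties.method = "average")
      w <- xv * exp(-alpha * r / N)
      for (i in seq_len(nSets)) {
        inMask <- universe %in% sets[[i]]
        mIdx <- which(inMask)
        oIdx <- which(!inMask)
        obs <- mean(w[mIdx]) - mean(w[oIdx])
        sd <- if (is.null(seed)) NULL else
          as.integer(seed + (j - 1) * nSets + (i - 1))
        null <- .withSeed(sd,
          vapply(seq_len(nPerm), function(b) {
            perm <- sample.int(N)
            mean(w[perm[mIdx]]) - mean(w[perm[oIdx]])
          }, 0))
        extreme <- switch(alternative,
                          two_sided = abs(null) >= abs(obs),
                          greater = null >= obs,
                          less = null <= obs)
        score[i, j] <- obs
        p[i, j] <- (1 + sum(extreme)) / (nPerm + 1)
      }
    }
  }
  q <- apply(p, 2, bhFdr)
  if (is.null(dim(q))) q <- matrix(q, nSets, nSamp, dimnames = dimnames(p))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = score, p = p, q = q),
    rowData = S4Vectors::DataFrame(
      n_genes = sz,
      description = unname(collection@descriptions[names(sets)])))
  metadata(se) <- list(method = method, alpha = alpha, nPerm = nPerm,
                       seed = seed, alternative = alternative,
                       sigRule = sigRule)
  new("PathwayResult", se)
}

#' @rdname accessors
#' @export
setMethod("pathwayScores", "PathwayResult",
          function(x) SummarizedExperiment::assay(x, "score"))

#' @rdname accessors
#' @export
setMethod("pathwayPvalues", "PathwayResult",
          function(x) SummarizedExperiment::assay(x, "p"))

#' @rdname accessors
#' @export
setMethod("pathwayQvalues", "PathwayResult",
          function(x) SummarizedExperiment::assay(x, "q"))

#' @rdname accessors
#' @export
setMethod("setIds", "PathwayResult", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "PathwayResult", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("resultTable", "PathwayResult", function(x) {
  sc <- pathwayScores(x)
  data.frame(
    set_id = rep(rownames(sc), ncol(sc)),
    sample_id = rep(colnames(sc), each = nrow(sc)),
    score = as.vector(sc),
    p = as.vector(pathwayPvalues(x)),
    q = as.vector(pathwayQvalues(x)),
    n_genes = rep(SummarizedExperiment::rowData(x)$n_genes, ncol(sc)),
    stringsAsFactors = FALSE)
})

setMethod("show", "PathwayResult", function(object) {
  md <- metadata(object)
  cat("PathwayResult:", nrow(object), "gene sets x", ncol(object),
      "samples; method:", md$method, "\n")
  q <- pathwayQvalues(object)
  cat("  sets with q < 0.05 in any sample:",
      sum(apply(q < 0.05, 1, any)), "\n")
})

#' Write pathway results as TSV
#'
#' `format = "long"` writes one row per (set, sample) with score, p, q and
#' set size; `format = "wide"` writes the score matrix. Both carry a
#' `#`-prefixed provenance header with the method and parameters.
#'
#' @param x a [PathwayResult].
#' @param path output path.
#' @param format `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
writePathwayResult <- function(x, path, format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(is(x, "PathwayResult"))
  md <- metadata(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# cisPathway ",
           as.character(utils::packageVersion("cisPathway")),
           " pathway result (", format, ")"),
    paste0("# method=", md$method, " alpha=", md$alpha, " nPerm=", md$nPerm,
           " seed=", if (is.null(md$seed)) "NULL" else md$seed,
           " alternative=", md$alternative)), con)
  if (format == "long") {
    utils::write.table(resultTable(x), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df <- data.frame(set_id = rownames(x), pathwayScores(x),
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
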