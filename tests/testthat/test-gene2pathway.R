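test_that("GMT parsing: dedup, field and id validation", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tfirst\tA\tB\tC", "S2\tsecond\tB\tD"), gmt)
  coll <- readGmt(gmt)
  expect_length(coll, 2)
  expect_equal(geneSets(coll), list(S1 = c("A", "B", "C"), S2 = c("B", "D")))

  dupGene <- tempfile()
  writeLines("S1\tdesc\tA\tA\tB", dupGene)
  expect_warning(colld <- readGmt(dupGene), "deduplicated")
  expect_equal(geneSets(colld)$S1, c("A", "B"))

  short <- tempfile()
  writeLines(c("S1\tdesc\tA", "S2\tdesc"), short)
  expect_error(readGmt(short), "line 2")

  dupId <- tempfile()
  writeLines(c("S1\td\tA\tB", "S1\td\tC\tD"), dupId)
  expect_error(readGmt(dupId), "duplicate set_id")
})

test_that("filterSets enforces the post-intersection size floor", {
  coll <- new("GeneSetCollection",
              sets = list(S4 = paste0("g", 1:4),
                          S5 = paste0("g", 1:5),
                          SX = c(paste0("g", 1:6), "not_in_universe")),
              descriptions = c(S4 = "", S5 = "", SX = ""), source = "mem")
  uni <- paste0("g", 1:10)
  # a set with 4 universe genes is removed at the 5-gene floor; 5 is kept
  f5 <- filterSets(coll, uni, minSize = 5)
  expect_setequal(setIds(f5), c("S5", "SX"))
  expect_equal(geneSets(f5)$SX, paste0("g", 1:6))  # intersected members
  # minSize 1 keeps everything
  expect_length(filterSets(coll, uni, minSize = 1), 3)
  # idempotent
  expect_identical(geneSets(filterSets(f5, uni, minSize = 5)), geneSets(f5))
  expect_true(all(lengths(geneSets(f5)) >= 5))
  expect_error(filterSets(coll, uni, minSize = 0), "minSize")
  expect_error(filterSets(coll, character()), "universe")
})

test_that("FAIME matches direct evaluation and its algebraic identities", {
  # N = 4, x = (4, 3, 2, 1), alpha = 5, members = top 2 genes:
  # direct transcription of the definition
  x <- setNames(c(4, 3, 2, 1), paste0("g", 1:4))
  w <- c(4 * exp(-5 * 1 / 4), 3 * exp(-5 * 2 / 4),
         2 * exp(-5 * 3 / 4), 1 * exp(-5 * 4 / 4))
  fHand <- mean(w[1:2]) - mean(w[3:4])
  expect_equal(faimeScore(x, c("g1", "g2"), alpha = 5), fHand,
               tolerance = 1e-15)

  # all scores equal -> all ranks average -> f = 0 exactly
  expect_equal(faimeScore(setNames(rep(2.2, 6), paste0("g", 1:6)),
                          c("g1", "g4")), 0)

  # ties: average ranks (x with a tie, computed by hand)
  xt <- setNames(c(5, 3, 3, 1), paste0("g", 1:4))
  rt <- c(1, 2.5, 2.5, 4)
  wt <- xt * exp(-5 * rt / 4)
  expect_equal(faimeScore(xt, c("g1", "g3")),
               mean(wt[c(1, 3)]) - mean(wt[c(2, 4)]))

  # degenerate membership errors
  expect_error(faimeScore(x, character()), "proper non-empty subset")
  expect_error(faimeScore(x, names(x)), "proper non-empty subset")
  expect_error(faimeScore(x, "not_a_gene"), "proper non-empty subset")
})

test_that("fisherSetTest equals the exact hypergeometric tail", {
  # table a=3 b=2 c=1 d=14: N=20, K=5 in-set, n=4 significant
  x <- setNames(c(rep(10, 3), rep(0, 2), 10, rep(0, 14)), paste0("g", 1:20))
  members <- paste0("g", 1:5)
  ft <- fisherSetTest(x, members, list(type = "threshold", value = 5))
  expect_equal(unname(ft$table[1, 1]), 3)
  expect_equal(ft$p, orc_hyper_tail(3, K = 5, N = 20, n = 4),
               tolerance = 1e-14)
  expect_equal(ft$p, (choose(5, 3) * 15 + choose(5, 4)) / choose(20, 4))
  expect_equal(ft$odds_ratio, (3 * 14) / (2 * 1))

  # zero overlap: P[X >= 0] = 1
  x0 <- setNames(c(rep(0, 5), rep(10, 4), rep(0, 11)), paste0("g", 1:20))
  expect_equal(fisherSetTest(x0, members,
                             list(type = "threshold", value = 5))$p, 1)

  # all significant genes inside the set at maximal a: tail has one term
  xm <- setNames(c(rep(10, 4), rep(0, 16)), paste0("g", 1:20))
  ftm <- fisherSetTest(xm, members, list(type = "threshold", value = 5))
  expect_equal(ftm$p, choose(5, 4) * choose(15, 0) / choose(20, 4),
               tolerance = 1e-14)
  # a margin cell is 0 -> Haldane-corrected odds ratio (a=4 b=1 c=0 d=15)
  expect_equal(ftm$odds_ratio, (4.5 * 15.5) / (1.5 * 0.5))

  # top_k rule and degenerate margins
  expect_equal(fisherSetTest(x, members, list(type = "top_k", k = 4))$p,
               orc_hyper_tail(3, 5, 20, 4), tolerance = 1e-14)
  expect_error(fisherSetTest(x, members,
                             list(type = "threshold", value = -99)),
               "all genes significant")
  expect_error(fisherSetTest(x, members, list(type = "wrong")), "sigRule")
})

test_that("ksSetTest D equals the brute-force ECDF supremum", {
  mk <- function(v) setNames(v, paste0("g", seq_along(v)))
  # disjoint ranges -> complete separation
  x <- mk(c(1, 2, 3, 4, 5))
  expect_equal(ksSetTest(x, c("g1", "g2"))$D, 1)
  # identical in/out values -> D = 0
  x2 <- mk(c(7, 7, 7, 7))
  expect_equal(ksSetTest(x2, c("g1", "g3"))$D, 0)
  # in {1,3} vs out {2,4}
  x3 <- mk(c(1, 2, 3, 4))
  expect_equal(ksSetTest(x3, c("g1", "g3"))$D, 0.5)
  # random vectors vs oracle
  set.seed(8)
  for (rep in 1:15) {
    n <- sample(6:50, 1)
    v <- mk(round(rnorm(n), 2))  # rounding induces ties
    m <- paste0("g", sample(n, sample(2:(n - 2), 1)))
    got <- ksSetTest(v, m)$D
    expect_equal(got, orc_ks_D(v[names(v) %in% m], v[!names(v) %in% m]),
                 tolerance = 1e-12)
  }
})

test_that("cumulativeRankTest: exact enumeration path and normal tail", {
  mk <- function(v) setNames(v, paste0("g", seq_along(v)))
  # N=5, k=2, in-set holds the top 2 scores: T = 3, only {1,2} sums <= 3
  x <- mk(c(10, 8, 6, 4, 2))
  ct <- cumulativeRankTest(x, c("g1", "g2"), "greater")
  expect_equal(ct$statistic, 3)
  expect_true(ct$exact)
  expect_equal(ct$p, 1 / 10)
  # in-set ranks the k worst: lower-tail p = 1 (every subset sum <= max)
  ctw <- cumulativeRankTest(x, c("g4", "g5"), "greater")
  expect_equal(ctw$p, 1)
  expect_equal(cumulativeRankTest(x, c("g4", "g5"), "less")$p,
               1 / 10)
  # symmetric case: in/out rank sums equal -> z = 0, two-sided p = 1
  x4 <- mk(c(4, 3, 2, 1))
  cts <- cumulativeRankTest(x4, c("g1", "g4"))
  expect_equal(cts$z, 0)
  expect_equal(cts$p, 1)

  # random small fixtures (with ties) vs the enumeration oracle
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    v <- mk(sample(round(rnorm(n), 1), n))
    k <- sample(1:(n - 1), 1)
    m <- paste0("g", sample(n, k))
    for (alt in c("two_sided", "greater", "less")) {
      got <- cumulativeRankTest(v, m, alt)
      expect_equal(got$p, orc_ranksum_p(v, k, got$statistic, alt),
                   label = paste(n, k, alt))
    }
  }

  # tie-free exact lower tail is the Wilcoxon rank-sum distribution
  set.seed(13)
  v <- mk(sample(1:10))
  m <- paste0("g", sample(10, 4))
  gotp <- cumulativeRankTest(v, m, "greater")
  W <- gotp$statistic - 4 * 5 / 2
  expect_equal(gotp$p, pwilcox(W, 4, 6), tolerance = 1e-12)

  expect_error(cumulativeRankTest(mk(1:4), character()), "subset")
})

test_that("normal approximation tracks the exact rank-sum tail at N = 50", {
  set.seed(14)
  x <- setNames(sample(1:50), paste0("g", 1:50))  # tie-free
  for (rep in 1:10) {
    m <- paste0("g", sample(50, 10))
    ct <- cumulativeRankTest(x, m, "greater")
    expect_false(ct$exact)
    exact <- pwilcox(ct$statistic - 10 * 11 / 2, 10, 40)
    expect_lt(abs(ct$p - exact), 0.05)
  }
})

test_that("scorePathways composes statistics, BH per sample, and validates", {
  u <- paste0("g", 1:30)
  set.seed(3)
  sm <- matrix(rnorm(60), 30, 2, dimnames = list(u, c("sA", "sB")))
  gm <- GeneScoreMatrix(sm)
  coll <- new("GeneSetCollection",
              sets = list(S1 = u[1:8], S2 = u[10:21], S3 = u[c(2, 5, 25:29)]),
              descriptions = c(S1 = "", S2 = "", S3 = ""), source = "mem")

  for (meth in c("faime", "ks", "cumulative_rank")) {
    pr <- scorePathways(gm, coll, method = meth, nPerm = 99, seed = 11)
    expect_s4_class(pr, "PathwayResult")
    expect_equal(dim(pr), c(3L, 2L))
    # q is BH of p within each sample
    for (j in 1:2)
      expect_equal(pathwayQvalues(pr)[, j],
                   stats::p.adjust(pathwayPvalues(pr)[, j], "BH"))
    expect_true(all(pathwayQvalues(pr) >= pathwayPvalues(pr) - 1e-12))
  }

  # empirical p respects the add-one floor
  prf <- scorePathways(gm, coll, method = "faime", nPerm = 99, seed = 11)
  expect_true(all(pathwayPvalues(prf) >= 1 / 100))

  # scores invariant under gene-row permutation (rank-based statistics)
  perm <- sample(30)
  gmp <- GeneScoreMatrix(sm[perm, , drop = FALSE])
  for (meth in c("ks", "cumulative_rank")) {
    a <- scorePathways(gm, coll, method = meth)
    b <- scorePathways(gmp, coll, method = meth)
    expect_equal(pathwayScores(a), pathwayScores(b))
    expect_equal(pathwayPvalues(a), pathwayPvalues(b))
  }
  expect_equal(pathwayScores(scorePathways(gmp, coll, "faime", nPerm = 1,
                                           seed = 1)),
               pathwayScores(prf))

  # 1 set x 1 sample works
  one <- new("GeneSetCollection", sets = list(S = u[1:6]),
             descriptions = c(S = ""), source = "mem")
  pr1 <- scorePathways(GeneScoreMatrix(sm[, 1, drop = FALSE]), one,
                       method = "faime", nPerm = 19, seed = 2)
  expect_equal(dim(pr1), c(1L, 1L))

  # validation: fisher needs a sigRule; degenerate sets are rejected
  expect_error(scorePathways(gm, coll, method = "fisher"), "sigRule")
  degen <- new("GeneSetCollection", sets = list(S = "absent_gene"),
               descriptions = c(S = ""), source = "mem")
  expect_error(scorePathways(gm, degen, "faime"), "filterSets")

  # fisher route end-to-end with an explicit rule
  prF <- scorePathways(gm, coll, method = "fisher",
                       sigRule = list(type = "top_k", k = 6))
  expect_true(all(pathwayPvalues(prF) > 0 & pathwayPvalues(prF) <= 1))
})

test_that("pathway results round-trip to long and wide TSV", {
  u <- paste0("g", 1:12)
  gm <- GeneScoreMatrix(matrix(rnorm(12), 12, 1, dimnames = list(u, "s")))
  coll <- new("GeneSetCollection", sets = list(S1 = u[1:5], S2 = u[6:11]),
              descriptions = c(S1 = "one", S2 = "two"), source = "mem")
  pr <- scorePathways(gm, coll, method = "cumulative_rank")
  long <- tempfile(fileext = ".tsv")
  writePathwayResult(pr, long)
  back <- utils::read.delim(long, comment.char = "#")
  expect_equal(back$set_id, c("S1", "S2"))
  expect_equal(back$p, unname(pathwayPvalues(pr)[, 1]))
  wide <- tempfile(fileext = ".tsv")
  writePathwayResult(pr, wide, format = "wide")
  backw <- utils::read.delim(wide, comment.char = "#", check.names = FALSE)
  expect_equal(backw$s, unname(pathwayScores(pr)[, 1]))
})
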