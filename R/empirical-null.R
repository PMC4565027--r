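#' @include gene2pathway.R
NULL

## run expr with a locally seeded RNG, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Permutation empirical p-value for a gene-set statistic
#'
#' Shuffles the gene-score vector over gene labels within a sample
#' `nPerm` times, recomputes the statistic, and reports the add-one
#' empirical p-value `p = (1 + #extreme) / (nPerm + 1)`, which is always
#' positive and a valid p-value. Extremity follows `alternative`:
#' `"two_sided"` counts `|stat_b| >= |observed|`, `"greater"` counts
#' `stat_b >= observed`, `"less"` counts `stat_b <= observed`. Shuffling
#' spans the full gene universe, which detaches score magnitude (and any
#' gene-length signal it carries) from set membership -- the
#' bias-correction core of the empirical assessment.
#'
#' The permutation stream is R's default Mersenne-Twister seeded with
#' `seed`; a fixed seed gives bit-identical p-values across runs. The
#' caller's RNG state is restored on exit.
#'
#' @param observed the observed statistic value.
#' @param statistic `function(scores, members)` returning a scalar;
#'   deterministic given its inputs.
#' @param x named numeric vector of gene scores (one sample).
#' @param members member gene ids (fixed across permutations).
#' @param nPerm number of permutations (>= 1; default 1000).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return list with `p` (in `[1/(nPerm+1), 1]`) and `null` (the
#'   `nPerm` permuted statistic values, e.g. for diagnostics).
#' @export
empiricalP <- function(observed, statistic, x, members, nPerm = 1000,
                       seed = NULL, alternative = c("two_sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  if (nPerm < 1) stop("nPerm must be >= 1")
  stopifnot(is.numeric(x), !is.null(names(x)), is.function(statistic))
  N <- length(x)
  nm <- names(x)
  null <- .withSeed(seed,
    vapply(seq_len(nPerm), function(b)
      statistic(setNames(x[sample.int(N)], nm), members), 0))
  extreme <- switch(alternative,
                    two_sided = abs(null) >= abs(observed),
                    greater = null >= observed,
                    less = null <= observed)
  list(p = (1 + sum(extreme)) / (nPerm + 1), null = null)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1,
#' with the original order restored; `q >= p` elementwise.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bhFdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  p.adjust(p, method = "BH")
}
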