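# Randomization tests and multiple-comparison handling.

#' Permutation test for a difference in means
#'
#' Two-sided Monte-Carlo permutation (randomization) test. Paired:
#' random sign flips of the per-pair differences. Unpaired: random
#' reassignment of group labels. The p value uses the add-one
#' estimator `p = (1 + #{|null| >= |observed|}) / (1 + n)`, so its
#' floor is `1 / (n + 1)` and it can never be zero.
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @param nIterations Monte-Carlo iterations (default 10000).
#' @param seed integer seed.
#' @return list of class `ppc_permutation` with `p.value`, `effect`
#'   (difference of means), `nIterations`, `paired`.
#' @examples
#' permutationTest(rnorm(10), rnorm(10), nIterations = 999, seed = 1)
#' @export
permutationTest <- function(x, y, paired = FALSE, nIterations = 10000L,
                            seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (paired) {
    if (length(x) != length(y))
      stop("paired samples must have equal length")
    d <- x - y
    d <- d[is.finite(d)]
    if (length(d) < 2L) stop("fewer than 2 effective samples")
    obs <- mean(d)
    null <- withSeed(seed, {
      signs <- matrix(sample(c(-1, 1), length(d) * nIterations,
                             replace = TRUE), nrow = length(d))
      colMeans(d * signs)
    })
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 1L || length(y) < 1L || length(x) + length(y) < 2L)
      stop("fewer than 2 effective samples")
    obs <- mean(x) - mean(y)
    pooled <- c(x, y)
    nX <- length(x); n <- length(pooled); tot <- sum(pooled)
    null <- withSeed(seed, {
      vapply(seq_len(nIterations), function(k) {
        sX <- sum(pooled[sample.int(n, nX)])
        sX / nX - (tot - sX) / (n - nX)
      }, numeric(1))
    })
  }
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + nIterations)
  structure(list(p.value = p, effect = obs,
                 nIterations = as.integer(nIterations),
                 paired = paired),
            class = "ppc_permutation")
}

#' @export
print.ppc_permutation <- function(x, ...) {
  cat(sprintf("%s permutation test: effect = %.4g, p = %.4g (%d iterations)\n",
              if (x$paired) "Paired" else "Unpaired",
              x$effect, x$p.value, x$nIterations))
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` via [stats::p.adjust].
#'
#' @param p p value(s).
#' @param m number of comparisons (default: `length(p)`).
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  p.adjust(p, method = "bonferroni", n = max(m, length(p)))
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test] returning the
#' tie-corrected H statistic and chi-square p value; degenerate input
#' (all values identical) yields H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list with `H`, `p.value`, `df`.
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop("need at least two non-empty groups")
  allv <- unlist(groups)
  if (length(unique(allv)) == 1L)
    return(list(H = 0, p.value = 1, df = length(groups) - 1L))
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter))
}
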