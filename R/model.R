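## The asymmetric two-state substitution model for adjacency characters.
##
## Under a uniform DCJ on a genome with n genes, a present adjacency is
## destroyed with probability about 2/(n + O(1)) per operation, while any one
## absent adjacency (out of up to choose(2n+2, 2) possible ones) is created
## with probability about 2/(2n^2 + O(n)); loss is therefore roughly 2n times
## more likely than gain. We embed that ratio in a reversible continuous-time
## two-state chain (states: 0 = absent, 1 = present) and let branch length
## absorb the event count, normalizing rates so one unit of branch length is
## one expected change per character at stationarity.

#' Two-state adjacency evolution model
#'
#' @param n Number of distinct gene families (positive integer).
#' @param ratio Loss/gain rate ratio; defaults to \code{2 * n}.
#' @return A \code{go_model}: list with rates \code{q01} (gain), \code{q10}
#'   (loss), stationary distribution \code{pi = c(pi0, pi1)}, and the ratio.
#' @examples
#' m <- adjacency_model(100)
#' m$q10 / m$q01   # 200
#' @export
adjacency_model <- function(n, ratio = NULL) {
  n <- as.numeric(n)
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive count")
  r <- if (is.null(ratio)) 2 * n else as.numeric(ratio)
  if (length(r) != 1L || is.na(r) || r <= 0) stop("ratio must be > 0")
  ## pi1 = 1/(1+r); normalization: 2 * pi0 * q01 = 1 expected change/unit time
  q01 <- (1 + r) / (2 * r)
  q10 <- r * q01
  structure(list(n = n, ratio = r, q01 = q01, q10 = q10,
                 pi = c(r, 1) / (1 + r)),
            class = "go_model")
}

#' @export
print.go_model <- function(x, ...) {
  cat("Two-state adjacency model: n =", x$n, " loss/gain ratio =", x$ratio,
      "\n  gain rate q01 =", signif(x$q01, 6),
      " loss rate q10 =", signif(x$q10, 6),
      " stationary pi1 =", signif(x$pi[2L], 6), "\n")
  invisible(x)
}

#' Transition probability matrix over a branch
#'
#' Closed form for the two-state chain: \code{P01(t) = pi1 (1 - exp(-s t))}
#' with \code{s = q01 + q10}, etc. Rows index the starting state (0, 1).
#'
#' @param model A \code{go_model}.
#' @param t Branch length (non-negative).
#' @return A 2x2 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "go_model"))
  if (length(t) != 1L || is.na(t) || t < 0) stop("branch length must be >= 0")
  e <- exp(-(model$q01 + model$q10) * t)
  p0 <- model$pi[1L]; p1 <- model$pi[2L]
  matrix(c(p0 + p1 * e, p0 * (1 - e),
           p1 * (1 - e), p1 + p0 * e),
         2L, 2L, dimnames = list(c("0", "1"), c("0", "1")))
}

#' Count the possible adjacencies and telomeres for n genes
#'
#' Enumerates unordered pairs over the 2n gene extremities (a head and a tail
#' per family) plus two chromosome-end markers; their number is
#' \code{choose(2n+2, 2)}, the denominator behind the model's gain
#' probability.
#'
#' @param n Number of gene families.
#' @return Integer count of distinct extremity pairs.
#' @export
count_possible_adjacencies <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  ends <- c(paste0(rep(seq_len(n), each = 2L), c("t", "h")), "o1", "o2")
  ncol(combn(ends, 2L))
}
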