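#' Pearson correlation with strict preconditions
#'
#' Sample Pearson correlation coefficient between two numeric vectors.
#' Unlike [stats::cor()], inputs of unequal length, length below 3, or with
#' zero variance are rejected with an error: every downstream consumer in
#' this package (module detection, edge screening) must filter degenerate
#' profiles *before* computing correlations, and a silent `NA` would defeat
#' that contract.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance and no missing values.
#' @return The correlation coefficient, a single number in \[-1, 1\].
#' @examples
#' pearson_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
pearson_cor <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("`x` and `y` must be numeric vectors.", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length (", length(x), " vs ",
         length(y), ").", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("Correlation requires at least 3 observations, got ", length(x),
         ".", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("`x` and `y` must not contain missing values.", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Correlation undefined: zero variance in ",
         if (stats::sd(x) == 0) "`x`" else "`y`",
         ". Filter constant profiles before correlating.", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Permutation-based empirical p-value for a Pearson correlation
#'
#' Shuffles `y` `n_perm` times and reports the two-sided empirical tail
#' probability of the observed correlation,
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1)`.
#' The +1 correction keeps the estimate strictly positive (the observed
#' statistic is counted as one permutation), so `p >= 1/(n_perm + 1)` by
#' construction. The test is two-sided on `|r|`; one-sided sign filters
#' (e.g. keeping only positive co-response edges) belong downstream.
#'
#' Permutations are drawn from a dedicated seeded stream, so the result for
#' a given `(x, y, n_perm, seed)` is reproducible and independent of any
#' surrounding RNG use or of the order in which pairs are processed.
#'
#' @param x,y Numeric vectors (see [pearson_cor()] for preconditions).
#' @param n_perm Number of permutations (default 1000, as used for module
#'   and edge screening).
#' @param seed Integer seed for the permutation stream.
#' @param id_a,id_b Optional identifiers carried into the result row.
#' @return A one-row tibble: `id_a`, `id_b`, `pcc`, `p_emp`, `n_perm`.
#' @examples
#' empirical_pcc_pvalue(1:5, c(2, 1, 4, 3, 5), n_perm = 199, seed = 1)
#' @export
empirical_pcc_pvalue <- function(x, y, n_perm = 1000, seed = 1L,
                                 id_a = NA_character_, id_b = NA_character_) {
  r_obs <- pearson_cor(x, y)
  if (n_perm < 1) stop("`n_perm` must be >= 1.", call. = FALSE)
  n <- length(y)
  xs <- (x - mean(x)) / stats::sd(x)
  perm_idx <- withr::with_seed(
    as.integer(seed),
    matrix(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)),
           nrow = n)
  )
  yp <- matrix(y[perm_idx], nrow = n)
  yp <- scale(yp)  # center + unit sd per column
  r_perm <- as.vector(crossprod(xs, yp)) / (n - 1)
  # tolerance catches ties at |r| = 1 that floating point would miss
  hits <- sum(abs(r_perm) >= abs(r_obs) - 1e-12)
  tibble::tibble(
    id_a = id_a, id_b = id_b,
    pcc = r_obs,
    p_emp = (1 + hits) / (n_perm + 1),
    n_perm = as.integer(n_perm)
  )
}

# Deterministic per-pair seed so edge screens are order-independent:
# a small polynomial string hash folded with the base seed, kept < 2^31.
pair_seed <- function(seed, id_a, id_b) {
  h <- 0
  for (ch in utf8ToInt(paste(id_a, id_b, sep = "\r"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` annotated members in a draw of `n` from a
#' background of `N` genes of which `K` are annotated. This is the
#' enrichment p-value used for promoter-element tests. Computed on the log
#' scale internally (via [stats::phyper()]) for numerical stability.
#'
#' @param k Observed hits in the set (0 <= k <= min(n, K)).
#' @param n Set (module) size.
#' @param K Hits in the background.
#' @param N Background size.
#' @return Upper-tail probability in (0, 1\].
#' @examples
#' hypergeometric_upper(4, 4, 5, 10)  # 5/210
#' @export
hypergeometric_upper <- function(k, n, K, N) {
  bad <- !(k >= 0 & k <= pmin(n, K) & n <= N & K <= N & K >= 0 & n >= 0)
  if (any(bad)) {
    stop("Invalid hypergeometric counts: need 0 <= k <= min(n, K), ",
         "n <= N, K <= N (first violation at position ", which(bad)[1], ").",
         call. = FALSE)
  }
  # P[X >= k] = 1 - P[X <= k-1]; phyper works in log space internally
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement between an inferred partition and a reference,
#' corrected for chance. Used to score planted-module recovery in
#' simulations. 1 means identical partitions; 0 is the expected value for
#' independent labelings.
#'
#' @param labels_a,labels_b Vectors of equal length (any atomic type);
#'   compared as partitions.
#' @return The adjusted Rand index, a single number <= 1.
#' @export
module_recovery_ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("Label vectors must have equal length.", call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
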