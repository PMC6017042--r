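#' Base frequencies at a locus
#'
#' Converts per-base read depths to per-base frequencies. Frequencies, not
#' absolute depths, feed the ED statistic so that sequencing-depth
#' differences between pools cancel out.
#'
#' @param depths A length-4 numeric vector of read counts in base order
#'   A, C, G, T, or an n x 4 matrix / data frame of such counts (one row per
#'   locus).
#' @return A vector (or matrix, matching the input shape) of frequencies
#'   summing to 1 per locus.
#' @details A locus with zero total depth has no defined frequency and is an
#'   error: the read-support filter must remove such loci before frequencies
#'   are taken.
#' @examples
#' base_frequencies(c(30, 10, 0, 0))
#' @export
base_frequencies <- function(depths) {
  vec <- is.null(dim(depths))
  m <- as_depth_matrix(depths)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    bad <- which(tot == 0)
    stop("zero total depth at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; frequencies are undefined (apply the read-support filter first)")
  }
  f <- m / tot
  if (vec) f[1L, ] else f
}

#' Euclidean distance between two base-frequency vectors
#'
#' The per-SNP association statistic of a bulked-segregant scan:
#' \deqn{ED = \sqrt{\sum_{b \in \{A,C,G,T\}} (f_{1,b} - f_{2,b})^2}}
#' where \eqn{f_{1}} and \eqn{f_{2}} are the base-frequency vectors of the
#' two bulks at the locus. ED is symmetric, zero iff the bulks carry
#' identical base compositions, and bounded above by \eqn{\sqrt 2} (opposite
#' fixed alleles).
#'
#' @param f1,f2 Length-4 frequency vectors, or n x 4 matrices (row-wise).
#' @return Numeric vector of distances, one per locus.
#' @examples
#' euclidean_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)) # sqrt(2)
#' @export
euclidean_distance <- function(f1, f2) {
  if (is.null(dim(f1))) f1 <- matrix(f1, nrow = 1L)
  if (is.null(dim(f2))) f2 <- matrix(f2, nrow = 1L)
  if (!all(dim(f1) == dim(f2)))
    stop("frequency arguments must have matching dimensions")
  if (ncol(f1) != 4L) stop("frequency vectors must have 4 entries")
  sqrt(rowSums((f1 - f2)^2))
}

#' Power transform of the ED statistic
#'
#' Raising ED to a power k >= 1 (default 5) suppresses the many small
#' background distances relative to large, trait-linked ones. The transform
#' is strictly monotone, so candidate rankings are unchanged.
#'
#' @param ed Non-negative ED value(s).
#' @param k Exponent, an integer or real >= 1.
#' @return `ed^k`.
#' @export
ed_power <- function(ed, k = 5) {
  if (length(k) != 1L || !is.finite(k) || k < 1)
    stop("k must be a single value >= 1")
  if (any(ed < 0)) stop("ed must be non-negative")
  ed^k
}

#' Classify candidate association loci
#'
#' A locus is a candidate association locus when its scan statistic reaches
#' the association threshold (default ED = 0.74 on the raw ED scale). The
#' comparison is inclusive (`>=`) so boundary values are not dropped by
#' floating-point rounding.
#'
#' @param ed Non-negative statistic value(s) (raw ED, or ED^k when the scan
#'   is configured to threshold the transformed value).
#' @param threshold Positive association threshold.
#' @return Logical vector, `TRUE` for candidate loci.
#' @export
classify_candidate <- function(ed, threshold = 0.74) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a single positive value")
  if (any(ed < 0)) stop("ed must be non-negative")
  ed >= threshold
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least `y_assoc` candidate association loci
#' among a unigene's `n_all` SNP loci when `k_assoc` of the `m_total`
#' genome-wide bulk-discrepant loci are candidates and loci are assigned at
#' random:
#' \deqn{P = 1 - \sum_{x=0}^{y-1} \binom{K}{x}\binom{M-K}{N-x} / \binom{M}{N}}
#'
#' The sum is evaluated directly over the upper tail in log space
#' (`lchoose` with log-sum-exp), which avoids the catastrophic cancellation
#' of literally subtracting the lower tail from 1 when P is small. Results
#' are clamped to `[.Machine$double.xmin, 1]`: an exact zero is never
#' returned, since the finite-population probability cannot be exactly zero
#' for an event that is merely unlikely, and underflowing values are
#' reported as the smallest representable positive number.
#'
#' @param n_all Number of SNP loci on the unigene (N). Vectorized.
#' @param y_assoc Number of candidate loci on the unigene (Y). Vectorized
#'   with `n_all`.
#' @param m_total Total bulk-discrepant SNP loci genome-wide (M).
#' @param k_assoc Total candidate association loci genome-wide (K).
#' @return Upper-tail probabilities in (0, 1].
#' @examples
#' hypergeom_tail(2, 2, m_total = 10, k_assoc = 5) # C(5,2)/C(10,2)
#' @export
hypergeom_tail <- function(n_all, y_assoc, m_total, k_assoc) {
  if (length(m_total) != 1L || length(k_assoc) != 1L)
    stop("m_total and k_assoc must be scalars")
  if (m_total < 0 || k_assoc < 0 || k_assoc > m_total)
    stop("need 0 <= k_assoc <= m_total")
  if (length(n_all) != length(y_assoc))
    stop("n_all and y_assoc must have equal length")
  if (any(y_assoc < 0) || any(y_assoc > n_all) || any(n_all > m_total))
    stop("need 0 <= y_assoc <= n_all <= m_total")
  vapply(seq_along(n_all), function(i) {
    hypergeom_tail_1(n_all[i], y_assoc[i], m_total, k_assoc)
  }, numeric(1L))
}

hypergeom_tail_1 <- function(n, y, m, k) {
  if (y == 0) return(1)
  xs <- seq.int(y, min(n, k))
  if (y > min(n, k)) return(.Machine$double.xmin)
  lt <- lchoose(k, xs) + lchoose(m - k, n - xs) - lchoose(m, n)
  lt <- lt[is.finite(lt)]
  if (!length(lt)) return(.Machine$double.xmin)
  lmax <- max(lt)
  p <- exp(lmax + log(sum(exp(lt - lmax))))
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: p-values are ranked ascending,
#' multiplied by m/rank, made monotone from the largest rank downward,
#' capped at 1 and returned in input order. Ties share their block's value.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (q-values) in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0L))
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop("p_values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Screen unigenes significant after FDR correction
#'
#' @param enrichments A data frame of per-unigene enrichment results with at
#'   least columns `unigene` and `fdr` (as produced by [run_bsr_scan()]).
#' @param fdr_cutoff Strict FDR cutoff; rows with `fdr < fdr_cutoff` are
#'   retained.
#' @return The significant subset, ordered by ascending FDR then unigene id.
#' @export
screen_significant <- function(enrichments, fdr_cutoff = 0.01) {
  if (!is.data.frame(enrichments) ||
      !all(c("unigene", "fdr") %in% names(enrichments)))
    stop("enrichments must be a data frame with columns 'unigene' and 'fdr'")
  if (anyNA(enrichments$fdr)) stop("fdr must be populated on every record")
  keep <- enrichments[enrichments$fdr < fdr_cutoff, , drop = FALSE]
  keep <- keep[order(keep$fdr, keep$unigene, method = "radix"), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
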