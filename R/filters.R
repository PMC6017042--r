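#' Observed-allele indicator matrix for one pool
#'
#' A base counts as "observed" in a pool when its frequency reaches the
#' minor-allele floor; the floor absorbs sequencing error without modelling
#' base quality. Pools with zero total depth observe no alleles.
#' @noRd
observed_alleles <- function(loci, pool, allele_floor = 0.1) {
  d <- pool_depths(loci, pool)
  tot <- rowSums(d)
  f <- d / ifelse(tot > 0, tot, 1)
  f >= allele_floor & tot > 0
}

#' Read-support filter
#'
#' Removes loci with insufficient read depth. By default every pool (both
#' parents and both bulks) must reach `min_support` total reads at the
#' locus: the ED statistic needs defined frequencies in both bulks, and the
#' parent-consistency filter needs parental calls. With
#' `scope = "bulks_only"` only the two bulk pools are required.
#'
#' @param loci A validated locus depth table (see [validate_loci()]).
#' @param min_support Minimum total reads per pool (inclusive), >= 1.
#' @param scope `"all_pools"` (default) or `"bulks_only"`.
#' @return A list with elements `kept` and `removed`, both locus tables.
#' @export
filter_read_support <- function(loci, min_support = 3,
                                scope = c("all_pools", "bulks_only")) {
  scope <- match.arg(scope)
  if (min_support < 1) stop("min_support must be >= 1")
  if (nrow(loci) == 0L) return(list(kept = loci, removed = loci))
  pools <- if (scope == "all_pools") POOLS else c("T03", "T04")
  tots <- matrix(unlist(lapply(pools, function(p)
    rowSums(pool_depths(loci, p)))), nrow = nrow(loci))
  ok <- rowSums(tots >= min_support) == length(pools)
  list(kept = loci[ok, , drop = FALSE], removed = loci[!ok, , drop = FALSE])
}

#' Parent-bulk Mendelian consistency filter
#'
#' Removes loci at which a bulk's observed allele set could not have been
#' inherited from the parents — alleles present in a bulk above the
#' minor-allele floor but absent from the parental allele set are Mendelian
#' impossibilities (sequencing/calling artefacts in a true F1 design).
#'
#' Pairings:
#' \describe{
#'   \item{`both_parents`}{(default) each bulk is checked against the union
#'     of both parents' alleles — the weakest assumption that is always
#'     valid for an F1, since every F1 allele is drawn from one of the two
#'     parents.}
#'   \item{`as_printed`}{early bulk T03 against parent T01, late bulk T04
#'     against parent T02.}
#'   \item{`phenotype_matched`}{T03 against T02, T04 against T01.}
#' }
#' Parents with zero depth contribute an empty allele set.
#'
#' @param loci A validated locus depth table.
#' @param pairing Which bulk-parent pairing to enforce.
#' @param allele_floor Minimum frequency for an allele to count as observed.
#' @return A list with elements `kept` and `removed`.
#' @export
filter_parent_discrepant <- function(loci,
                                     pairing = c("both_parents", "as_printed",
                                                 "phenotype_matched"),
                                     allele_floor = 0.1) {
  pairing <- match.arg(pairing)
  if (nrow(loci) == 0L) return(list(kept = loci, removed = loci))
  obs <- lapply(stats::setNames(POOLS, POOLS), observed_alleles,
                loci = loci, allele_floor = allele_floor)
  allowed <- switch(pairing,
    both_parents      = list(T03 = obs$T01 | obs$T02, T04 = obs$T01 | obs$T02),
    as_printed        = list(T03 = obs$T01, T04 = obs$T02),
    phenotype_matched = list(T03 = obs$T02, T04 = obs$T01))
  ok03 <- rowSums(obs$T03 & !allowed$T03) == 0L
  ok04 <- rowSums(obs$T04 & !allowed$T04) == 0L
  ok <- ok03 & ok04
  list(kept = loci[ok, , drop = FALSE], removed = loci[!ok, , drop = FALSE])
}

#' Bulk-consistency filter
#'
#' Removes consistent-type loci: sites where the two bulks carry identical
#' observed allele sets and an ED below the consistency epsilon. Such loci
#' hold no discrepancy between the bulks and cannot inform the scan. The
#' loci surviving this filter define M, the genome-wide total of
#' bulk-discrepant SNPs.
#'
#' @param loci A validated locus depth table in which both bulks have
#'   positive depth (guaranteed downstream of [filter_read_support()]).
#' @param consistency_eps ED below which equal-allele-set bulks count as
#'   consistent.
#' @param allele_floor Minimum frequency for an allele to count as observed.
#' @return A list with elements `kept` and `removed`.
#' @export
filter_bulk_consistent <- function(loci, consistency_eps = 1e-6,
                                   allele_floor = 0.1) {
  if (nrow(loci) == 0L) return(list(kept = loci, removed = loci))
  f3 <- base_frequencies(pool_depths(loci, "T03"))
  f4 <- base_frequencies(pool_depths(loci, "T04"))
  ed <- euclidean_distance(f3, f4)
  same_set <- rowSums(observed_alleles(loci, "T03", allele_floor) !=
                      observed_alleles(loci, "T04", allele_floor)) == 0L
  drop <- same_set & ed < consistency_eps
  list(kept = loci[!drop, , drop = FALSE],
       removed = loci[drop, , drop = FALSE])
}
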