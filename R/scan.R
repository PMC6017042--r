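#' Configuration for a BSR association scan
#'
#' @param min_support Minimum total reads per pool at a locus (read-support
#'   filter, inclusive).
#' @param support_scope Pools the support filter applies to: `"all_pools"`
#'   or `"bulks_only"`.
#' @param threshold Association threshold (default ED = 0.74).
#' @param threshold_on Scale on which the threshold is compared: raw `"ed"`
#'   (default; 0.74 lies inside the raw-ED range \[0, sqrt(2)\]) or
#'   `"ed_powered"`.
#' @param power Exponent k of the ED^k noise transform (default 5).
#' @param fdr_cutoff Strict FDR cutoff for the significance screen.
#' @param pairing Bulk-parent pairing of the Mendelian-consistency filter;
#'   see [filter_parent_discrepant()].
#' @param allele_floor Minor-allele frequency floor for "observed" alleles
#'   in the filters.
#' @param consistency_eps ED epsilon of the bulk-consistency filter.
#' @return A list of class `bsr_config`.
#' @export
bsr_config <- function(min_support = 3,
                       support_scope = c("all_pools", "bulks_only"),
                       threshold = 0.74,
                       threshold_on = c("ed", "ed_powered"),
                       power = 5,
                       fdr_cutoff = 0.01,
                       pairing = c("both_parents", "as_printed",
                                   "phenotype_matched"),
                       allele_floor = 0.1,
                       consistency_eps = 1e-6) {
  cfg <- list(min_support = min_support,
              support_scope = match.arg(support_scope),
              threshold = threshold,
              threshold_on = match.arg(threshold_on),
              power = power,
              fdr_cutoff = fdr_cutoff,
              pairing = match.arg(pairing),
              allele_floor = allele_floor,
              consistency_eps = consistency_eps)
  if (cfg$min_support < 1) stop("min_support must be >= 1")
  if (cfg$threshold <= 0) stop("threshold must be positive")
  if (cfg$power < 1) stop("power must be >= 1")
  if (cfg$fdr_cutoff <= 0 || cfg$fdr_cutoff > 1)
    stop("fdr_cutoff must be in (0, 1]")
  structure(cfg, class = "bsr_config")
}

#' Count all and candidate loci per unigene
#'
#' @param ed_records Data frame with columns `unigene` and `is_candidate`
#'   (one row per surviving locus).
#' @return Data frame with one row per unigene, ordered by unigene id:
#'   `unigene`, `n_all` (its SNP count), `y_assoc` (its candidate count).
#' @export
aggregate_unigenes <- function(ed_records) {
  if (nrow(ed_records) == 0L)
    return(data.frame(unigene = character(0L), n_all = integer(0L),
                      y_assoc = integer(0L)))
  u <- sort(unique(ed_records$unigene), method = "radix")
  idx <- factor(ed_records$unigene, levels = u)
  out <- data.frame(
    unigene = u,
    n_all   = as.integer(tabulate(idx, nbins = length(u))),
    y_assoc = as.integer(rowsum(as.numeric(ed_records$is_candidate), idx)[, 1L]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the full BSR association scan
#'
#' Applies the three filters in order (read support, parent-bulk Mendelian
#' consistency, bulk consistency), computes per-locus ED and ED^k between
#' the two bulks, classifies candidate loci against the association
#' threshold, and tests each unigene for candidate enrichment with the
#' upper-tail hypergeometric probability, Benjamini-Hochberg corrected
#' across unigenes.
#'
#' @param loci A locus depth table (see [read_depth_tsv()] for the layout).
#' @param config A [bsr_config()] object.
#' @return An object of class `bsr_scan`: a list with
#' \describe{
#'   \item{ed_records}{per-locus table: unigene, pos, per-pool depths, ed,
#'     ed_powered, is_candidate; canonical order (unigene, pos).}
#'   \item{params}{list with `m_total` (surviving loci, M) and `k_assoc`
#'     (candidate loci, K).}
#'   \item{unigene_table}{per-unigene table: unigene, n_all, y_assoc,
#'     p_value, fdr, significant.}
#'   \item{filter_report}{per-stage input/output counts and removed loci.}
#'   \item{config}{the configuration snapshot.}
#' }
#' @export
run_bsr_scan <- function(loci, config = bsr_config()) {
  if (!inherits(config, "bsr_config")) stop("config must be a bsr_config()")
  validate_loci(loci)

  s1 <- filter_read_support(loci, config$min_support, config$support_scope)
  s2 <- filter_parent_discrepant(s1$kept, config$pairing, config$allele_floor)
  s3 <- filter_bulk_consistent(s2$kept, config$consistency_eps,
                               config$allele_floor)
  report <- list(n_input            = nrow(loci),
                 n_after_support    = nrow(s1$kept),
                 n_after_discrepant = nrow(s2$kept),
                 n_after_consistent = nrow(s3$kept),
                 removed = list(support    = s1$removed,
                                discrepant = s2$removed,
                                consistent = s3$removed))
  stopifnot(report$n_input >= report$n_after_support,
            report$n_after_support >= report$n_after_discrepant,
            report$n_after_discrepant >= report$n_after_consistent)

  kept <- s3$kept
  if (nrow(kept) == 0L)
    stop("empty scan: no loci survive the filters")
  kept <- kept[order(kept$unigene, kept$pos, method = "radix"), , drop = FALSE]
  rownames(kept) <- NULL

  f3 <- base_frequencies(pool_depths(kept, "T03"))
  f4 <- base_frequencies(pool_depths(kept, "T04"))
  ed <- euclidean_distance(f3, f4)
  edk <- ed_power(ed, config$power)
  stat <- if (config$threshold_on == "ed") ed else edk
  cand <- classify_candidate(stat, config$threshold)

  ed_records <- cbind(kept,
                      data.frame(ed = ed, ed_powered = edk,
                                 is_candidate = cand))
  m_total <- nrow(ed_records)
  k_assoc <- sum(cand)

  uni <- aggregate_unigenes(ed_records)
  stopifnot(sum(uni$n_all) == m_total, sum(uni$y_assoc) == k_assoc)
  uni$p_value <- if (k_assoc == 0L) rep(1, nrow(uni)) else
    hypergeom_tail(uni$n_all, uni$y_assoc, m_total, k_assoc)
  uni$fdr <- bh_fdr(uni$p_value)
  uni$significant <- uni$fdr < config$fdr_cutoff

  structure(list(ed_records = ed_records,
                 params = list(m_total = m_total, k_assoc = k_assoc),
                 unigene_table = uni,
                 filter_report = report,
                 config = config),
            class = "bsr_scan")
}

#' @export
print.bsr_scan <- function(x, ...) {
  r <- x$filter_report
  cat("BSR association scan\n")
  cat(sprintf("  loci: %d input -> %d support -> %d Mendelian -> %d discrepant (M)\n",
              r$n_input, r$n_after_support, r$n_after_discrepant,
              r$n_after_consistent))
  cat(sprintf("  candidates (K): %d at %s >= %g (power %g)\n",
              x$params$k_assoc, x$config$threshold_on, x$config$threshold,
              x$config$power))
  cat(sprintf("  unigenes: %d tested, %d significant at FDR < %g\n",
              nrow(x$unigene_table), sum(x$unigene_table$significant),
              x$config$fdr_cutoff))
  invisible(x)
}
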