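#' FPKM expression value
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `count * 1e9 / (length * library_size)`. Normalises a fragment count for
#' both transcript length and sequencing depth so expression is comparable
#' across genes and libraries.
#'
#' @param fragment_count Non-negative fragment count(s) for the gene.
#' @param effective_length_bp Positive transcript (effective) length in bp.
#' @param library_fragments Positive total mapped fragments in the library.
#' @return FPKM value(s); 0 when the count is 0.
#' @examples
#' fpkm(1000, 1000, 1e6) # 1000
#' @export
fpkm <- function(fragment_count, effective_length_bp, library_fragments) {
  if (any(fragment_count < 0)) stop("fragment_count must be non-negative")
  if (any(effective_length_bp <= 0)) stop("effective_length_bp must be positive")
  if (any(library_fragments <= 0)) stop("library_fragments must be positive")
  fragment_count * 1e9 / (as.numeric(effective_length_bp) * library_fragments)
}

#' Screen differentially expressed genes by FDR and fold change
#'
#' Retains genes with `fdr < fdr_cutoff` and a fold change of at least
#' `fc_cutoff` in either direction, partitioned into up-regulated
#' (`fold_change >= fc_cutoff`) and down-regulated
#' (`fold_change <= 1/fc_cutoff`) sets. Fold change is the expression ratio
#' of the first-named group over the second, as supplied.
#'
#' @param records Data frame with columns `gene_id`, `fold_change`
#'   (positive ratio) and `fdr` (in \[0, 1\]).
#' @param fdr_cutoff Strict FDR cutoff (default 0.01).
#' @param fc_cutoff Fold-change cutoff >= 1 (default 2).
#' @return A list with data frames `up` and `down`.
#' @export
deg_screen <- function(records, fdr_cutoff = 0.01, fc_cutoff = 2) {
  need <- c("gene_id", "fold_change", "fdr")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (any(records$fold_change <= 0)) stop("fold_change must be positive")
  if (any(records$fdr < 0 | records$fdr > 1)) stop("fdr must be in [0, 1]")
  if (fdr_cutoff <= 0 || fc_cutoff < 1) stop("invalid cutoffs")
  sig <- records$fdr < fdr_cutoff &
    pmax(records$fold_change, 1 / records$fold_change) >= fc_cutoff
  up <- records[sig & records$fold_change >= fc_cutoff, , drop = FALSE]
  down <- records[sig & records$fold_change <= 1 / fc_cutoff, , drop = FALSE]
  rownames(up) <- rownames(down) <- NULL
  list(up = up, down = down)
}

#' Relative expression by the 2^-ddCt method
#'
#' Relative quantification of a target gene against a reference gene
#' (e.g. Actin) and a calibrator sample:
#' `2^-((Ct_target,sample - Ct_ref,sample) - (Ct_target,cal - Ct_ref,cal))`.
#' Technical-replicate Ct values are averaged before calling this.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and reference
#'   gene in the calibrator sample.
#' @return Positive relative expression; 1 means no change versus the
#'   calibrator.
#' @examples
#' ddct_relative_expression(20, 18, 22, 18) # 4
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator,
                                     ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (anyNA(cts) || any(!is.finite(cts))) stop("Ct values must be finite")
  if (any(cts <= 0 | cts >= 45))
    warning("Ct value(s) outside the typical (0, 45) range")
  dct_sample <- ct_target_sample - ct_ref_sample
  dct_cal <- ct_target_calibrator - ct_ref_calibrator
  2^(-(dct_sample - dct_cal))
}
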