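#' Read a per-pool base-depth TSV
#'
#' Reads the package's depth dialect: a tab-separated file with header
#' `unigene  pos  T01_A T01_C T01_G T01_T ... T04_T` (18 columns, UTF-8).
#' Lines starting with `#` are comments. Positions are 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return A validated locus depth table (data frame, 18 columns).
#' @details Malformed rows (wrong field count, non-integer or negative
#'   depths) and duplicate (unigene, pos) keys are hard errors reported
#'   with the offending file line numbers.
#' @export
read_depth_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  if (!length(lineno)) stop("no header found in ", path)
  header <- strsplit(lines[lineno[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("unigene", "pos", depth_cols())
  if (!identical(header, need))
    stop("bad header in ", path, "; expected columns: ",
         paste(need, collapse = ", "))
  body_ln <- lineno[-1L]
  if (!length(body_ln))
    return(validate_loci(empty_loci()))
  fields <- strsplit(lines[body_ln], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 18L))
    stop("wrong field count on line(s) ",
         paste(utils::head(body_ln[nf != 18L], 5L), collapse = ", "),
         " of ", path)
  mat <- matrix(unlist(fields), ncol = 18L, byrow = TRUE)
  num <- suppressWarnings(apply(mat[, -1L, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 17L)
  bad <- rowSums(is.na(num) | num < 0 | num != floor(num)) > 0L
  if (any(bad))
    stop("non-integer or negative value on line(s) ",
         paste(utils::head(body_ln[bad], 5L), collapse = ", "), " of ", path)
  loci <- data.frame(unigene = mat[, 1L], stringsAsFactors = FALSE)
  loci[need[-1L]] <- as.data.frame(matrix(as.integer(num), ncol = 17L))
  key <- paste(loci$unigene, loci$pos)
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    stop("duplicate (unigene, pos) on line(s) ",
         paste(utils::head(body_ln[dup], 5L), collapse = ", "), " of ", path)
  }
  validate_loci(loci)
  loci
}

empty_loci <- function() {
  out <- data.frame(unigene = character(0L))
  out[c("pos", depth_cols())] <- rep(list(integer(0L)), 17L)
  out
}

#' Read pooled allele depths from a VCF
#'
#' Builds a locus depth table from a VCF carrying per-sample allele depths
#' (the `AD` FORMAT subfield, as emitted by GATK). `CHROM` is taken as the
#' unigene id and `POS` as the 1-based position. Each sample's AD values
#' are distributed onto the four-base depth vector according to the REF and
#' ALT bases of the record.
#'
#' Records that are not simple SNPs (indels, multi-nucleotide or symbolic
#' alleles) are skipped, as are records with a missing AD in any mapped
#' sample; both are counted in the `skipped` attribute of the result.
#'
#' @param path Path to a VCF (4.x) file.
#' @param sample_map Named character vector mapping pool ids to VCF sample
#'   names, e.g. `c(T01 = "parentM", T02 = "parentF", T03 = "bulkE",
#'   T04 = "bulkL")`.
#' @return A validated locus depth table with attribute `skipped`, a named
#'   integer vector with counts `non_snp` and `missing_ad`.
#' @export
read_depth_vcf <- function(path, sample_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!all(POOLS %in% names(sample_map)))
    stop("sample_map must name all of ", paste(POOLS, collapse = ", "))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(vcf@gt)[-1L]
  missing <- setdiff(unname(sample_map[POOLS]), have)
  if (length(missing))
    stop("sample(s) not present in VCF header: ",
         paste(missing, collapse = ", "))
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(vcf)),
                dimnames = list(NULL, colnames(vcfR::getFIX(vcf))))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  n <- nrow(fix)
  skipped <- c(non_snp = 0L, missing_ad = 0L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    alleles <- c(ref, alts)
    if (!all(alleles %in% BASES)) {
      skipped["non_snp"] <- skipped["non_snp"] + 1L
      next
    }
    vals <- list()
    bad <- FALSE
    for (pool in POOLS) {
      adv <- ad[i, sample_map[[pool]]]
      if (is.na(adv) || adv %in% c(".", "")) { bad <- TRUE; break }
      counts <- suppressWarnings(as.integer(strsplit(adv, ",", fixed = TRUE)[[1L]]))
      if (anyNA(counts) || length(counts) != length(alleles)) { bad <- TRUE; break }
      v <- stats::setNames(integer(4L), BASES)
      for (j in seq_along(alleles)) v[alleles[j]] <- v[alleles[j]] + counts[j]
      vals[[pool]] <- v
    }
    if (bad) {
      skipped["missing_ad"] <- skipped["missing_ad"] + 1L
      next
    }
    vals$unigene <- fix[i, "CHROM"]
    vals$pos <- as.integer(fix[i, "POS"])
    rows[[i]] <- vals
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    out <- empty_loci()
  } else {
    out <- data.frame(
      unigene = vapply(rows, `[[`, character(1L), "unigene"),
      pos = vapply(rows, `[[`, integer(1L), "pos"),
      stringsAsFactors = FALSE)
    for (pool in POOLS) {
      m <- t(vapply(rows, `[[`, integer(4L), pool))
      out[pool_cols(pool)] <- as.data.frame(m)
    }
  }
  validate_loci(out)
  attr(out, "skipped") <- skipped
  out
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Write scan result files
#'
#' Writes three files into `out_dir`:
#' \describe{
#'   \item{loci.tsv}{per-locus table: unigene, pos, per-pool depths, ed,
#'     ed_powered, is_candidate.}
#'   \item{unigenes.tsv}{per-unigene table: unigene, all_count, asso_count,
#'     p_value, fdr, significant.}
#'   \item{run_metadata.txt}{configuration snapshot, filter report, M, K.}
#' }
#' Output is byte-stable: the same result and configuration always produce
#' identical files.
#'
#' @param result A `bsr_scan` object.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths of the files written.
#' @export
write_results <- function(result, out_dir) {
  if (!inherits(result, "bsr_scan")) stop("result must be a bsr_scan object")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  loci_path <- file.path(out_dir, "loci.tsv")
  uni_path <- file.path(out_dir, "unigenes.tsv")
  meta_path <- file.path(out_dir, "run_metadata.txt")

  er <- result$ed_records
  loci_out <- data.frame(er[c("unigene", "pos", depth_cols())],
                         ed = fmt_num(er$ed),
                         ed_powered = fmt_num(er$ed_powered),
                         is_candidate = er$is_candidate)
  utils::write.table(loci_out, loci_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  u <- result$unigene_table
  uni_out <- data.frame(unigene = u$unigene,
                        all_count = u$n_all,
                        asso_count = u$y_assoc,
                        p_value = fmt_num(u$p_value),
                        fdr = fmt_num(u$fdr),
                        significant = u$significant)
  utils::write.table(uni_out, uni_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  cfg <- result$config
  r <- result$filter_report
  meta <- c("bsr_scan run metadata",
            "coordinates: unigene positions are 1-based inclusive",
            sprintf("config: %s",
                    paste(sprintf("%s=%s", names(cfg),
                                  vapply(cfg, function(v) as.character(v),
                                         character(1L))),
                          collapse = " ")),
            sprintf("filter: input=%d after_support=%d after_discrepant=%d after_consistent=%d",
                    r$n_input, r$n_after_support, r$n_after_discrepant,
                    r$n_after_consistent),
            sprintf("M=%d K=%d", result$params$m_total, result$params$k_assoc),
            sprintf("significant_unigenes=%d",
                    sum(result$unigene_table$significant)))
  writeLines(meta, meta_path)
  invisible(c(loci_path, uni_path, meta_path))
}
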