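#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")
POOLS <- c("T01", "T02", "T03", "T04")

#' Column names holding the four base depths of one pool
#' @noRd
pool_cols <- function(pool) paste(pool, BASES, sep = "_")

depth_cols <- function() as.vector(vapply(POOLS, pool_cols, character(4)))

#' Extract the n x 4 depth matrix of one pool from a locus table
#' @noRd
pool_depths <- function(loci, pool) {
  m <- as.matrix(loci[, pool_cols(pool), drop = FALSE])
  storage.mode(m) <- "double"
  colnames(m) <- BASES
  m
}

#' Coerce a depth argument to an n x 4 numeric matrix
#'
#' Accepts a length-4 vector (A, C, G, T) or an n x 4 matrix / data frame.
#' @noRd
as_depth_matrix <- function(depths, what = "depths") {
  if (is.data.frame(depths)) depths <- as.matrix(depths)
  if (is.null(dim(depths))) {
    if (length(depths) != 4L)
      stop(what, " must have 4 entries (A, C, G, T), got ", length(depths))
    depths <- matrix(depths, nrow = 1L)
  }
  if (ncol(depths) != 4L)
    stop(what, " must have 4 columns (A, C, G, T), got ", ncol(depths))
  storage.mode(depths) <- "double"
  if (anyNA(depths) || any(!is.finite(depths)))
    stop(what, " contains missing or non-finite values")
  if (any(depths < 0))
    stop(what, " contains negative values")
  colnames(depths) <- BASES
  depths
}

#' Validate a per-locus depth table
#'
#' Checks that a data frame carries the 18-column per-pool base-depth layout
#' used throughout the package: `unigene`, `pos`, then `T01_A` ... `T04_T`.
#' Depths must be non-negative and finite, positions >= 1, and the
#' (unigene, pos) key unique.
#'
#' @param loci A data frame of SNP loci.
#' @return `loci`, invisibly, after validation.
#' @export
validate_loci <- function(loci) {
  if (!is.data.frame(loci)) stop("loci must be a data frame")
  need <- c("unigene", "pos", depth_cols())
  miss <- setdiff(need, names(loci))
  if (length(miss))
    stop("loci is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(loci) == 0L) return(invisible(loci))
  if (anyNA(loci$pos) || any(loci$pos < 1) || any(loci$pos != floor(loci$pos)))
    stop("pos must be a 1-based integer position")
  d <- as.matrix(loci[, depth_cols()])
  storage.mode(d) <- "double"
  if (anyNA(d) || any(!is.finite(d)) || any(d < 0) || any(d != floor(d)))
    stop("depth columns must be non-negative integers")
  key <- paste(loci$unigene, loci$pos)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicated (unigene, pos) key(s): ",
         paste(utils::head(dup, 5L), collapse = "; "))
  }
  invisible(loci)
}
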