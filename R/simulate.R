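#' Configuration for the bulked-pool simulator
#'
#' Defines the study design the simulator emulates: an F1 pseudo-testcross
#' population from two heterozygous parents, with two phenotypically
#' contrasting bulks of `bulk_size` individuals each (the parents are
#' sequenced as the other two pools). Informative SNPs are heterozygous in
#' one parent and homozygous in the other, so the Mendelian expectation of
#' the alternate-allele frequency in an unselected bulk is 0.25.
#'
#' @param n_unigenes Number of unigenes.
#' @param loci_per_unigene SNP loci per unigene: a single integer or a
#'   length-2 range sampled uniformly per unigene.
#' @param n_causal Number of causal unigenes (trait-linked).
#' @param causal_divergence Difference in alternate-allele frequency between
#'   the two bulks at causal loci, in \[0, 1\]; applied symmetrically
#'   (+/- d/2 around the Mendelian expectation, clipped to \[0, 1\]).
#' @param bulk_size Individuals per bulk (default 20).
#' @param mean_depth Mean sequencing depth per pool per locus (Poisson).
#' @param error_rate Per-read base miscall probability, to a uniform other
#'   base, in \[0, 1).
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_unigenes = 1000, loci_per_unigene = 5,
                       n_causal = 1, causal_divergence = 0.5,
                       bulk_size = 20, mean_depth = 50,
                       error_rate = 0.01, seed = 1) {
  cfg <- list(n_unigenes = as.integer(n_unigenes),
              loci_per_unigene = as.integer(loci_per_unigene),
              n_causal = as.integer(n_causal),
              causal_divergence = causal_divergence,
              bulk_size = as.integer(bulk_size),
              mean_depth = mean_depth,
              error_rate = error_rate,
              seed = as.integer(seed))
  if (cfg$n_unigenes < 1) stop("n_unigenes must be >= 1")
  if (!length(cfg$loci_per_unigene) %in% 1:2 || any(cfg$loci_per_unigene < 1))
    stop("loci_per_unigene must be a positive integer or length-2 range")
  if (cfg$n_causal < 0 || cfg$n_causal > cfg$n_unigenes)
    stop("need 0 <= n_causal <= n_unigenes")
  if (cfg$causal_divergence < 0 || cfg$causal_divergence > 1)
    stop("causal_divergence must be in [0, 1]")
  if (cfg$bulk_size < 1) stop("bulk_size must be >= 1")
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Multinomial base-call sampling, one probability row per locus
#' @noRd
rmultinom_rows <- function(size, prob) {
  n <- length(size)
  out <- matrix(0L, n, 4L)
  remaining <- as.integer(size)
  pleft <- rep(1, n)
  for (j in 1:3) {
    pj <- prob[, j] / pleft
    pj[!is.finite(pj)] <- 0
    pj <- pmin(pmax(pj, 0), 1)
    out[, j] <- stats::rbinom(n, remaining, pj)
    remaining <- remaining - out[, j]
    pleft <- pleft - prob[, j]
  }
  out[, 4L] <- remaining
  out
}

#' Biallelic base probabilities with uniform miscall error
#' @noRd
base_probs <- function(ref_idx, alt_idx, p_alt, error_rate) {
  n <- length(ref_idx)
  q <- matrix(0, n, 4L)
  q[cbind(seq_len(n), ref_idx)] <- 1 - p_alt
  q[cbind(seq_len(n), alt_idx)] <- q[cbind(seq_len(n), alt_idx)] + p_alt
  q * (1 - error_rate) + (1 - q) * error_rate / 3
}

#' Simulate a bulked-pool SNP depth dataset with known truth
#'
#' Generates per-locus, per-pool base depths for the four-pool design
#' (two parents T01/T02, early bulk T03, late bulk T04):
#' \enumerate{
#'   \item each locus is an informative pseudo-testcross SNP — one parent
#'     heterozygous ref/alt, the other homozygous ref (which parent is
#'     heterozygous is random per locus);
#'   \item bulk alternate-allele frequencies are binomial draws of
#'     `2 * bulk_size` allele copies around the Mendelian expectation 0.25;
#'     at causal loci the early/late expectations are shifted apart by
#'     `causal_divergence` (+/- d/2, clipped to \[0, 1\]);
#'   \item per-pool read depths are Poisson(`mean_depth`), base calls
#'     multinomial on the true base frequencies perturbed by a uniform
#'     miscall `error_rate`.
#' }
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#' \describe{
#'   \item{loci}{a locus depth table in the package's 18-column layout.}
#'   \item{truth}{a list with `causal_unigenes` (character vector) and
#'     `loci` — a per-locus data frame with ref/alt bases, the causal flag,
#'     the true alternate-allele frequency of every pool (for the bulks,
#'     the realised frequency after binomial bulk sampling), and a class
#'     label `discrepant`/`consistent` (consistent = the two bulks realised
#'     identical allele frequencies).}
#' }
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config()")
  set.seed(config$seed)
  nu <- config$n_unigenes
  lpu <- config$loci_per_unigene
  uni_ids <- sprintf("UN%05d", seq_len(nu))
  nloc_per <- if (length(lpu) == 1L) rep(lpu, nu) else
    sample(lpu[1L]:lpu[2L], nu, replace = TRUE)
  unigene <- rep(uni_ids, nloc_per)
  n <- length(unigene)
  pos <- unlist(lapply(nloc_per, function(k) sort(sample.int(10000L, k))),
                use.names = FALSE)

  causal_ids <- sort(sample(uni_ids, config$n_causal))
  causal <- unigene %in% causal_ids

  ref_idx <- sample.int(4L, n, replace = TRUE)
  alt_idx <- 1L + (ref_idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L
  het_parent <- sample(c("T01", "T02"), n, replace = TRUE)

  p <- list(T01 = ifelse(het_parent == "T01", 0.5, 0),
            T02 = ifelse(het_parent == "T02", 0.5, 0))
  d2 <- config$causal_divergence / 2
  exp_early <- pmin(pmax(0.25 + ifelse(causal, d2, 0), 0), 1)
  exp_late  <- pmin(pmax(0.25 - ifelse(causal, d2, 0), 0), 1)
  nchrom <- 2L * config$bulk_size
  p$T03 <- stats::rbinom(n, nchrom, exp_early) / nchrom
  p$T04 <- stats::rbinom(n, nchrom, exp_late) / nchrom

  loci <- data.frame(unigene = unigene, pos = pos, stringsAsFactors = FALSE)
  for (pool in POOLS) {
    depth <- stats::rpois(n, config$mean_depth)
    q <- base_probs(ref_idx, alt_idx, p[[pool]], config$error_rate)
    loci[pool_cols(pool)] <- as.data.frame(rmultinom_rows(depth, q))
  }
  validate_loci(loci)

  truth_loci <- data.frame(
    unigene = unigene, pos = pos,
    ref = BASES[ref_idx], alt = BASES[alt_idx],
    het_parent = het_parent, causal = causal,
    p_t01 = p$T01, p_t02 = p$T02, p_t03 = p$T03, p_t04 = p$T04,
    class = ifelse(p$T03 == p$T04, "consistent", "discrepant"),
    stringsAsFactors = FALSE)

  list(loci = loci,
       truth = list(causal_unigenes = causal_ids, loci = truth_loci))
}

#' Inject filter test loci into a simulated dataset
#'
#' Replaces stated fractions of loci with the three artefact classes the
#' pipeline's filters are designed to remove, and relabels them in the
#' truth table so filter recall and precision are computable:
#' \describe{
#'   \item{low_support}{one random pool's depth is reduced below the
#'     read-support threshold (2 reads of the reference base).}
#'   \item{mendelian_impossible}{both parents are set homozygous reference
#'     while the bulks carry a third base absent from either parent.}
#'   \item{bulk_identical}{the late bulk's depth vector is made an exact
#'     copy of the early bulk's, yielding ED = 0 and identical allele
#'     sets.}
#' }
#'
#' @param loci,truth A dataset as returned by [simulate_dataset()].
#' @param fractions Named numeric vector with any of `low_support`,
#'   `mendelian_impossible`, `bulk_identical`; each in \[0, 1\], summing to
#'   at most 1. Counts are `round(fraction * n)` on disjoint random loci.
#' @return A list with modified `loci` and `truth`.
#' @export
inject_filter_fodder <- function(loci, truth,
                                 fractions = c(low_support = 0,
                                               mendelian_impossible = 0,
                                               bulk_identical = 0)) {
  classes <- c("low_support", "mendelian_impossible", "bulk_identical")
  fr <- stats::setNames(rep(0, 3L), classes)
  if (length(fractions)) {
    if (is.null(names(fractions)) || !all(names(fractions) %in% classes))
      stop("fractions must be named among: ", paste(classes, collapse = ", "))
    fr[names(fractions)] <- fractions
  }
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("fractions must be in [0, 1] and sum to at most 1")
  n <- nrow(loci)
  counts <- round(fr * n)
  total <- sum(counts)
  if (total == 0L) return(list(loci = loci, truth = truth))
  idx <- sample.int(n, total)
  take <- split(idx, rep(classes, counts))

  for (i in take$low_support) {
    pool <- sample(POOLS, 1L)
    ref <- truth$loci$ref[i]
    loci[i, pool_cols(pool)] <- 0L
    loci[i, paste(pool, ref, sep = "_")] <- 2L
    truth$loci$class[i] <- "low_support"
  }
  for (i in take$mendelian_impossible) {
    ref <- truth$loci$ref[i]
    alt <- truth$loci$alt[i]
    other <- setdiff(BASES, c(ref, alt))[1L]
    for (pool in c("T01", "T02")) {
      loci[i, pool_cols(pool)] <- 0L
      loci[i, paste(pool, ref, sep = "_")] <- 50L
    }
    loci[i, pool_cols("T03")] <- 0L
    loci[i, paste("T03", ref, sep = "_")] <- 25L
    loci[i, paste("T03", other, sep = "_")] <- 25L
    loci[i, pool_cols("T04")] <- 0L
    loci[i, paste("T04", ref, sep = "_")] <- 30L
    loci[i, paste("T04", other, sep = "_")] <- 20L
    truth$loci$class[i] <- "mendelian_impossible"
  }
  for (i in take$bulk_identical) {
    if (sum(loci[i, pool_cols("T03")]) < 3L) {
      ref <- truth$loci$ref[i]
      loci[i, pool_cols("T03")] <- 0L
      loci[i, paste("T03", ref, sep = "_")] <- 50L
    }
    loci[i, pool_cols("T04")] <- loci[i, pool_cols("T03")]
    truth$loci$class[i] <- "bulk_identical"
  }
  list(loci = loci, truth = truth)
}

#' Write a simulated dataset to TSV files
#'
#' Emits `depths.tsv` in the pipeline's depth dialect (round-trips
#' losslessly through [read_depth_tsv()]) and `truth.tsv` with the
#' per-locus ground truth.
#'
#' @param loci,truth A dataset as returned by [simulate_dataset()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_sim_tsv <- function(loci, truth, out_dir) {
  validate_loci(loci)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  depths_path <- file.path(out_dir, "depths.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(loci, depths_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  tl <- truth$loci
  tl_out <- cbind(tl[c("unigene", "pos", "ref", "alt", "het_parent",
                       "causal")],
                  data.frame(p_t01 = fmt_num(tl$p_t01),
                             p_t02 = fmt_num(tl$p_t02),
                             p_t03 = fmt_num(tl$p_t03),
                             p_t04 = fmt_num(tl$p_t04),
                             class = tl$class))
  utils::write.table(tl_out, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(c(depths_path, truth_path))
}
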