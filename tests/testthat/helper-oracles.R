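# Independent oracles and small fixture builders used across the suite.

# Exact hypergeometric PMF over x = 0..n by direct binomial-coefficient
# products; independent of the package's log-space implementation.
oracle_hyper_pmf <- function(m, k, n) {
  xs <- 0:n
  choose(k, xs) * choose(m - k, n - xs) / choose(m, n)
}

oracle_hyper_tail <- function(m, k, n, y) {
  pmf <- oracle_hyper_pmf(m, k, n)
  sum(pmf[(0:n) >= y])
}

# Literal Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hand-built locus table: one row per locus, depths supplied as a named list
# of length-4 vectors (A, C, G, T) per pool.
make_locus <- function(unigene, pos, T01, T02, T03, T04) {
  row <- data.frame(unigene = unigene, pos = as.integer(pos),
                    stringsAsFactors = FALSE)
  for (pool in c("T01", "T02", "T03", "T04")) {
    v <- as.integer(get(pool))
    row[paste(pool, c("A", "C", "G", "T"), sep = "_")] <- as.list(v)
  }
  row
}

make_loci <- function(...) do.call(rbind, list(...))

# Random valid depth tables for property-style checks.
random_depths <- function(n, max_depth = 60) {
  matrix(sample.int(max_depth, 4L * n, replace = TRUE), ncol = 4L)
}

locus_key <- function(loci) paste(loci$unigene, loci$pos)
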