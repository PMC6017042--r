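Package: bsrscan
Title: Bulked-Segregant RNA-Seq Association Scanning with the
    Euclidean-Distance Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reference-free bulked-segregant RNA-seq (BSR-seq) association
    analysis on transcriptome unigene coordinates. Computes a per-SNP
    Euclidean-distance (ED) statistic between the four-base frequency
    vectors of two phenotypically contrasting bulks, applies the ED^k noise
    transform, classifies candidate association loci against a fixed ED
    threshold, and tests each unigene for enrichment of candidate loci with
    an upper-tail hypergeometric probability corrected by the
    Benjamini-Hochberg false discovery rate. Includes the three-stage SNP
    filtering used upstream of the scan (read support, parent-bulk
    Mendelian consistency, bulk discrepancy), readers for per-pool base
    depth tables (TSV) and VCF allele depths, a synthetic pooled-depth data
    generator with ground truth for an F1 pseudo-testcross bulked design,
    and small expression utilities (FPKM, fold-change/FDR screening,
    2^-ddCt relative expression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
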