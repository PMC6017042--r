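test_that("simulator honours the counting contract and is reproducible", {
  cfg <- sim_config(n_unigenes = 10, loci_per_unigene = 3, n_causal = 2,
                    seed = 61)
  sim <- simulate_dataset(cfg)
  expect_identical(nrow(sim$loci), 30L)
  expect_identical(length(unique(sim$loci$unigene)), 10L)
  expect_identical(length(sim$truth$causal_unigenes), 2L)
  expect_true(all(sim$truth$causal_unigenes %in% sim$loci$unigene))
  expect_identical(nrow(sim$truth$loci), nrow(sim$loci))
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim, sim2)
  # a different seed changes the data
  expect_false(identical(sim$loci,
                         simulate_dataset(sim_config(n_unigenes = 10,
                                                     loci_per_unigene = 3,
                                                     n_causal = 2,
                                                     seed = 62))$loci))
  # ranged loci-per-unigene stays within the range
  simr <- simulate_dataset(sim_config(n_unigenes = 20,
                                      loci_per_unigene = c(2, 6), seed = 61))
  per <- table(simr$loci$unigene)
  expect_true(all(per >= 2 & per <= 6))
  expect_error(sim_config(n_causal = 5, n_unigenes = 2), "n_causal")
  expect_error(sim_config(causal_divergence = 1.5), "causal_divergence")
  expect_error(sim_config(error_rate = 1), "error_rate")
})

test_that("deep error-free pools reproduce the configured frequencies", {
  sim <- simulate_dataset(sim_config(n_unigenes = 250, loci_per_unigene = 4,
                                     n_causal = 0, mean_depth = 500,
                                     error_rate = 0, seed = 63))
  tr <- sim$truth$loci
  for (pool in c("T01", "T02", "T03", "T04")) {
    d <- as.matrix(sim$loci[paste(pool, c("A", "C", "G", "T"), sep = "_")])
    alt_emp <- d[cbind(seq_len(nrow(d)), match(tr$alt, c("A", "C", "G", "T")))] /
      rowSums(d)
    p_true <- tr[[paste0("p_", tolower(pool))]]
    # generator calibration: pooled mean per true-frequency class
    for (cls in unique(round(p_true, 6))) {
      sel <- round(p_true, 6) == cls
      if (sum(sel) < 10) next
      expect_lt(abs(mean(alt_emp[sel]) - mean(p_true[sel])), 0.05)
    }
    # read sampling alone at depth 500 keeps every locus close to truth
    expect_lt(stats::quantile(abs(alt_emp - p_true), 0.99), 0.08)
  }
})

test_that("causal divergence separates ED; zero divergence does not", {
  ed_gap <- function(divergence, seeds) {
    vapply(seeds, function(s) {
      sim <- simulate_dataset(sim_config(n_unigenes = 20, loci_per_unigene = 2,
                                         n_causal = 5,
                                         causal_divergence = divergence,
                                         error_rate = 0, seed = s))
      res <- run_bsr_scan(sim$loci, bsr_config())
      er <- res$ed_records
      causal <- er$unigene %in% sim$truth$causal_unigenes
      mean(er$ed[causal]) - mean(er$ed[!causal])
    }, numeric(1))
  }
  gaps <- ed_gap(0.5, 1:200)
  expect_lt(stats::t.test(gaps, alternative = "greater")$p.value, 0.01)
  gaps0 <- ed_gap(0, 201:400)
  expect_lt(abs(mean(gaps0)), 0.05)
})

test_that("injected fodder is counted exactly and removed with full recall", {
  sim <- simulate_dataset(sim_config(n_unigenes = 50, loci_per_unigene = 4,
                                     error_rate = 0, seed = 64))
  set.seed(64)
  inj <- inject_filter_fodder(sim$loci, sim$truth,
                              c(low_support = 0.1,
                                mendelian_impossible = 0.1,
                                bulk_identical = 0.1))
  cls <- inj$truth$loci$class
  expect_identical(sum(cls == "low_support"), 20L)
  expect_identical(sum(cls == "mendelian_impossible"), 20L)
  expect_identical(sum(cls == "bulk_identical"), 20L)

  key <- locus_key(inj$loci)
  tkey <- locus_key(inj$truth$loci)
  s1 <- filter_read_support(inj$loci)
  expect_true(all(tkey[cls == "low_support"] %in% locus_key(s1$removed)))
  s2 <- filter_parent_discrepant(s1$kept, pairing = "both_parents")
  expect_true(all(tkey[cls == "mendelian_impossible"] %in%
                  locus_key(s2$removed)))
  s3 <- filter_bulk_consistent(s2$kept)
  expect_true(all(tkey[cls == "bulk_identical"] %in% locus_key(s3$removed)))

  # identity when nothing is injected; validation of bad fractions
  same <- inject_filter_fodder(sim$loci, sim$truth)
  expect_identical(same$loci, sim$loci)
  expect_error(inject_filter_fodder(sim$loci, sim$truth,
                                    c(low_support = 0.8,
                                      bulk_identical = 0.4)), "sum")
  expect_error(inject_filter_fodder(sim$loci, sim$truth, c(oops = 0.1)),
               "named")
})
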