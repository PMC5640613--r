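test_that("CCF-adjusted counts sum CCF by class and reduce to raw counts at CCF 1", {
  mut <- make_mut(gene = "G1", patient = c("P1", "P2", "P3"),
                  classification = c("missense", "indel", "silent"),
                  ccf = c(1.0, 0.5, 0.2), damage = 0.5)
  counts <- ccf_adjusted_counts(mut, genes = c("G1", "G2"))
  expect_equal(counts$n_a_ccf, c(1.5, 0))
  expect_equal(counts$n_s_ccf, c(0.2, 0))

  # all CCF = 1: the adjusted counts are the plain mutation counts
  mut$ccf <- 1
  counts1 <- ccf_adjusted_counts(mut)
  expect_equal(counts1$n_a_ccf, 2)
  expect_equal(counts1$n_s_ccf, 1)
})

test_that("silent-count correction floors at the neutral single-mutation value", {
  expect_equal(correct_silent_counts(0, 100, 50), 0.5)
  expect_equal(correct_silent_counts(3, 100, 50), 3)
  expect_equal(correct_silent_counts(0.5, 100, 50), 0.5)  # boundary unchanged
  expect_error(correct_silent_counts(1, 0, 50), "positive")
})

test_that("Ka/Ks and ncmr expected counts follow the neutral arithmetic", {
  expect_equal(expected_nonsilent_kaks(2, 100, 50), 4)
  expect_equal(expected_nonsilent_kaks(0.5, 100, 50), 1)
  expect_equal(expected_nonsilent_kaks(2, 200, 50),
               2 * expected_nonsilent_kaks(2, 100, 50))

  # ncmr * length = 3, N_s/N_a = 0.5 -> 2
  expect_equal(expected_nonsilent_ncmr(0.002, 1500, 100, 50), 2)
  expect_equal(expected_nonsilent_ncmr(0, 1500, 100, 50), 0)
  # all-sites-nonsynonymous limit: expected tends to the total
  expect_equal(expected_nonsilent_ncmr(0.002, 1500, 1e9, 1), 3,
               tolerance = 1e-8)
})

test_that("clonal rate averages per-patient clonal nonsilent SNV counts", {
  mut <- make_mut(gene = "G1",
                  patient = c("P1", "P1", "P2", "P2", "P2", "P2", "P2", "P2"),
                  classification = "missense",
                  ccf = c(0.9, 0.95, 0.9, 0.9, 0.86, 0.99, 0.3, 0.2),
                  damage = 0.5)
  expect_equal(clonal_mutation_rate(mut), 3)  # counts {2, 4}

  # CCF exactly at the threshold counts as clonal
  m2 <- make_mut(ccf = 0.85, damage = 0.5)
  expect_equal(clonal_mutation_rate(m2), 1)

  # indels are excluded unless asked for
  m3 <- make_mut(classification = c("indel", "missense"),
                 patient = c("P1", "P1"), ccf = c(0.9, 0.9), damage = 0.5)
  expect_equal(clonal_mutation_rate(m3), 1)
  expect_equal(clonal_mutation_rate(m3, include_indels = TRUE), 2)

  # cohort with no clonal mutations: r = 0 and bmp = 0 everywhere
  m4 <- make_mut(ccf = 0.2, damage = 0.5)
  expect_equal(clonal_mutation_rate(m4), 0)
  expect_equal(background_probability(c(1, 3), 0), c(0, 0))
})

test_that("background probability matches the binomial zero-class complement", {
  expect_equal(background_probability(c(0.5, 0.5), 1), c(0.5, 0.5))
  expect_equal(background_probability(c(1, 1), 2), c(0.75, 0.75))
  expect_error(background_probability(c(0, 0), 2), "zero")

  # brute-force binomial oracle: P(X >= 1) = sum_{k>=1} C(r,k) p^k (1-p)^(r-k)
  set.seed(10)
  for (i in 1:50) {
    p <- runif(1, 0.001, 0.999)
    r <- sample(1:40, 1)
    oracle <- sum(stats::dbinom(1:r, r, p))
    expect_equal(background_probability(c(p, 1 - p), r)[1], oracle,
                 tolerance = 1e-12)
  }
})

test_that("bmp is monotone in the expected count and in r", {
  expected <- c(1, 2, 3, 4)
  bmp1 <- background_probability(expected, 3)
  expect_true(all(diff(bmp1) > 0))
  bmp2 <- background_probability(expected, 6)
  expect_true(all(bmp2 > bmp1))
})

test_that("combining bmps averages per gene and validates gene sets", {
  expect_equal(combine_bmp(0.2, 0.4), 0.3)
  expect_equal(combine_bmp(c(a = 0.3), c(a = 0.3)), c(a = 0.3))
  x <- c(0.1, 0.9); y <- c(0.5, 0.2)
  z <- combine_bmp(x, y)
  expect_true(all(z >= pmin(x, y) & z <= pmax(x, y)))
  expect_error(combine_bmp(c(a = 0.1), c(b = 0.1)), "gene sets")
  expect_error(combine_bmp(c(0.1, 0.2), 0.1), "gene sets")
})

test_that("full background model normalises success probabilities to 1", {
  sim <- simulate_cohort(simulation_config(n_genes = 50, n_patients = 20,
                                           driver_genes = 2,
                                           mut_per_patient = 10), seed = 5)
  bg <- compute_background(sim$mutations, sim$gene_context)
  g <- tidy(bg)
  expect_equal(sum(g$expected_nonsilent_kaks /
                     sum(g$expected_nonsilent_kaks)), 1, tolerance = 1e-12)
  expect_equal(sum(g$expected_nonsilent_ncmr /
                     sum(g$expected_nonsilent_ncmr)), 1, tolerance = 1e-12)
  expect_true(all(g$bmp >= 0 & g$bmp <= 1))
  expect_true(all(g$n_s_corrected >= g$n_s_ccf))
  expect_gte(bg$r, 0)
})

test_that("mutations in genes without context are dropped with a warning", {
  mut <- add_damage(add_ccf(make_mut(gene = c("TP53", "NOTINCTX"),
                                     patient = c("P1", "P2"),
                                     vaf = c(0.4, 0.4))))
  expect_warning(bg <- compute_background(mut, make_context()),
                 "absent from the gene-context")
  expect_false("NOTINCTX" %in% tidy(bg)$gene)
})
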