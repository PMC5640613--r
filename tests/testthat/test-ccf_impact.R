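test_that("damage transform hits its midpoint, saturates and matches the logistic", {
  expect_equal(damage_score(15), 0.5)
  expect_gt(damage_score(1000), 0.999)
  # frozen from evaluating 1/(1 + exp(-1)) at high precision
  expect_equal(damage_score(17), 0.731058578630005, tolerance = 1e-12)
  expect_error(impact_params(scale = -1), "positive")
})

test_that("damage transform is monotone nondecreasing", {
  set.seed(1)
  for (i in 1:20) {
    x <- sort(runif(50, 0, 60))
    d <- damage_score(x)
    expect_true(all(diff(d) >= 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("CCF estimation matches the diploid formula and clips to [0, 1]", {
  expect_equal(estimate_ccf(0.5, purity = 1, copy_number = 2), 1)
  expect_equal(estimate_ccf(0, purity = 0.3), 0)
  expect_equal(estimate_ccf(0.25, purity = 0.5, copy_number = 2), 1)
  expect_equal(estimate_ccf(0.2, purity = 0.8), 0.5)
  expect_error(estimate_ccf(0.5, purity = 0), "purity")
  expect_error(estimate_ccf(1.5), "vaf")
})

test_that("CCF uses the CCF-weighted effective copy number when a CNV overlaps", {
  # cnv_ccf = 1: all cancer cells carry the CNV, copy number used as-is
  expect_equal(estimate_ccf(0.1, purity = 1, copy_number = 4, cnv_ccf = 1),
               0.4)
  # cnv_ccf = 0.5: effective copy number 2*(1-0.5) + 4*0.5 = 3
  expect_equal(estimate_ccf(0.1, purity = 1, copy_number = 4, cnv_ccf = 0.5),
               0.3)
})

test_that("CCF estimation is monotone in vaf and antitone in purity", {
  set.seed(2)
  for (i in 1:20) {
    vaf <- sort(runif(30, 0, 0.5))
    pur <- runif(1, 0.2, 1)
    ccf <- estimate_ccf(vaf, purity = pur)
    expect_true(all(diff(ccf) >= 0))
    purs <- sort(runif(30, 0.2, 1))
    ccf2 <- estimate_ccf(0.15, purity = purs)
    expect_true(all(diff(ccf2) <= 0))
    expect_true(all(c(ccf, ccf2) >= 0 & c(ccf, ccf2) <= 1))
  }
})

test_that("per-patient collapse keeps the highest-CCF mutation", {
  mut <- make_mut(gene = "G1", patient = "P1", vaf = c(0.15, 0.45),
                  impact_raw = c(30, 10))
  mut <- add_damage(add_ccf(mut))
  kept <- collapse_per_patient(mut)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$ccf, 0.9)

  single <- add_damage(add_ccf(make_mut()))
  expect_equal(collapse_per_patient(single)$vaf, 0.4)
})

test_that("collapse ties on CCF break by damage, exhaustively over both orders", {
  base <- make_mut(gene = "G1", patient = "P1", vaf = c(0.25, 0.25),
                   ccf = c(0.5, 0.5), damage = c(0.2, 0.9))
  for (perm in list(1:2, 2:1)) {
    kept <- collapse_per_patient(base[perm, ])
    expect_equal(kept$damage, 0.9)
  }
})

test_that("collapse drops silent mutations and counts distinct mutated patients", {
  set.seed(3)
  n <- 200
  mut <- make_mut(
    gene = sample(c("G1", "G2", "G3"), n, replace = TRUE),
    patient = sample(sprintf("P%02d", 1:20), n, replace = TRUE),
    classification = sample(c("missense", "silent"), n, replace = TRUE),
    vaf = runif(n, 0, 0.5), impact_raw = runif(n, 0, 40))
  mut <- add_damage(add_ccf(mut))
  kept <- collapse_per_patient(mut)
  expect_false(any(kept$classification == "silent"))
  nonsil <- dplyr::filter(mut, classification != "silent")
  expect_equal(nrow(kept),
               nrow(dplyr::distinct(nonsil, gene, patient)))
})

test_that("clonal drivers separate from subclonal groups in the CCF comparison", {
  set.seed(4)
  n <- 1000
  mk <- function(gene, class, ccf) {
    make_mut(gene = gene, patient = sprintf("P%04d", seq_along(ccf)),
             classification = class, vaf = ccf / 2, ccf = ccf, damage = 0.5)
  }
  mut <- dplyr::bind_rows(
    mk("DRV", "missense", rbeta(n, 30, 2)),
    mk("PSG", "missense", rbeta(n, 2, 5)),
    mk("DRV", "silent", rbeta(n, 2, 5)),
    mk("PSG", "silent", rbeta(n, 2, 5)))
  cmp <- ccf_group_comparison(mut, driver_genes = "DRV")
  med <- setNames(cmp$groups$median_ccf, cmp$groups$group)
  expect_true(all(med["nonsilent_driver"] > med[-1]))
  drv_pairs <- dplyr::filter(cmp$pairs,
                             group1 == "nonsilent_driver" |
                               group2 == "nonsilent_driver")
  expect_true(all(drv_pairs$p_value < 0.01))
})

test_that("CCF comparison is calibrated under the null", {
  # all four groups i.i.d. from one distribution: p-values roughly uniform
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    mut <- make_mut(gene = rep(c("DRV", "PSG"), each = 60),
                    patient = sprintf("P%03d", 1:120),
                    classification = rep(c("missense", "silent"), times = 60),
                    vaf = 0.1, ccf = runif(120), damage = 0.5)
    cmp <- ccf_group_comparison(mut, driver_genes = "DRV")
    median(cmp$pairs$p_value)
  }, numeric(1))
  expect_gt(median(ps), 0.3)
  expect_lt(median(ps), 0.7)
})

test_that("degenerate CCF groups are handled without errors", {
  # two identical constant-valued groups: no separation
  mut <- make_mut(gene = rep(c("DRV", "PSG"), each = 10),
                  patient = sprintf("P%02d", 1:20),
                  classification = "missense", vaf = 0.25, ccf = 0.5,
                  damage = 0.5)
  cmp <- ccf_group_comparison(mut, driver_genes = "DRV")
  p <- dplyr::filter(cmp$pairs, group1 == "nonsilent_driver",
                     group2 == "nonsilent_passenger")$p_value
  expect_equal(p, 1)
  # groups with < 2 mutations give NA p-values, not an exception
  expect_true(all(is.na(dplyr::filter(cmp$pairs,
                                      group1 == "silent_driver")$p_value)))
})
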