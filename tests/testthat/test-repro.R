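# Coefficient-of-variation engine and the summary layers.

test_that("cv matches its definition and hand-computed examples", {
  expect_equal(cv(c(5, 5, 5, 5)), 0)
  # values {44, 48, 50, 52}: mean 48.5, sample SD sqrt(35/3) = 3.4157
  expect_equal(cv(c(44, 48, 50, 52)), 100 * sqrt(35 / 3) / 48.5)
  expect_equal(round(cv(c(44, 48, 50, 52)), 2), 7.04)
  expect_equal(cv(c(44, 48, 50, 52) * 10), cv(c(44, 48, 50, 52)))
  expect_error(cv(5), "insufficient")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("cv_from_summary reproduces printed-table rows", {
  expect_equal(round(cv_from_summary(48.5, 4.8), 1), 9.9)
  expect_equal(round(cv_from_summary(262844, 25930), 1), 9.9)
  expect_equal(cv_from_summary(100, 0), 0)
  expect_error(cv_from_summary(0, 1), "zero mean")
  expect_error(cv_from_summary(1, -1), "negative SD")
})

test_that("repro table satisfies its internal identities", {
  panel <- gen_multisite_panel(toy_panel_spec(inter = 3, intra = 1,
                                              n_scanners = 4, n_sessions = 5,
                                              seed = 2))
  tab <- build_repro_table(panel)
  # cv = 100 sd / mean on every row, full precision
  expect_equal(tab$inter$cv_pct, 100 * tab$inter$sd / tab$inter$mean)
  expect_equal(tab$intra$cv_pct, 100 * tab$intra$sd / tab$intra$mean)
  expect_equal(tab$vendor$cv_pct, 100 * tab$vendor$sd / tab$vendor$mean)
  expect_true(all(tab$inter$cv_pct >= 0))
  # mean_intra is the unweighted mean over scanners
  for (lab in tab$inter$label) {
    ic <- tab$intra[tab$intra$label == lab, ]
    expect_equal(tab$inter$mean_intra_cv_pct[tab$inter$label == lab],
                 mean(ic$cv_pct))
  }
  # ratio = inter / mean-intra at full precision
  expect_equal(tab$inter$ratio_inter_to_mean_intra,
               tab$inter$cv_pct / tab$inter$mean_intra_cv_pct)
})

test_that("constant panels give zero CVs and undefined ratios", {
  panel <- gen_multisite_panel(toy_panel_spec(inter = 0, intra = 0,
                                              n_scanners = 3, n_sessions = 3))
  tab <- build_repro_table(panel)
  expect_true(all(tab$inter$cv_pct == 0))
  expect_true(all(tab$intra$cv_pct == 0))
  expect_true(all(is.na(tab$inter$ratio_inter_to_mean_intra)))
  expect_error(ratio_summary(tab), "no defined ratios")
})

test_that("scanners with fewer than two scans contribute no intra row", {
  spec <- toy_panel_spec(n_scanners = 2, n_sessions = 3, seed = 4)
  spec$sessions_per_scanner[["B"]] <- 1L
  tab <- build_repro_table(gen_multisite_panel(spec))
  expect_false("B" %in% tab$intra$scanner_id)
  expect_true("A" %in% tab$intra$scanner_id)
})

test_that("single-scanner vendor CV equals that scanner's intra CV", {
  spec <- toy_panel_spec(n_scanners = 3, n_sessions = 4, seed = 5)
  spec$vendor_of <- c(A = "V1", B = "V1", C = "solo")
  tab <- build_repro_table(gen_multisite_panel(spec))
  solo_cv <- tab$vendor$cv_pct[tab$vendor$vendor == "solo"]
  c_cv <- tab$intra$cv_pct[tab$intra$scanner_id == "C"]
  expect_equal(sort(solo_cv), sort(c_cv))
})

test_that("variance components are recovered from synthetic panels", {
  # intra 1%, between-scanner effect 3% -> inter CV ~ sqrt(10) ~ 3.16%.
  # A single 7-scanner panel estimates the between-scanner SD with only 6
  # degrees of freedom (chi-square SE ~ cv / sqrt(2*6) ~ 0.9), so the check
  # averages 20 independent panels; SE of the mean ~ 0.21.
  inters <- vapply(1:20, function(s) {
    tab <- build_repro_table(gen_multisite_panel(
      toy_panel_spec(inter = sqrt(10), intra = 1, seed = 100 + s)))
    mean(tab$inter$cv_pct)
  }, numeric(1))
  se_single <- sqrt(10) / sqrt(2 * 6)
  expect_lt(abs(mean(inters) - sqrt(10)), 3 * se_single / sqrt(20))
  # mean intra CV from one panel: 7 x 20 sessions, SE ~ 0.06
  tab <- build_repro_table(gen_multisite_panel(
    toy_panel_spec(inter = sqrt(10), intra = 1, seed = 77)))
  expect_lt(abs(mean(tab$inter$mean_intra_cv_pct) - 1), 0.2)
})

test_that("inter CV exceeds intra CV in expectation when scanners differ", {
  # 3-SE margin over 200 small replicate panels
  diffs <- vapply(1:200, function(s) {
    tab <- build_repro_table(gen_multisite_panel(
      toy_panel_spec(inter = 4, intra = 1, n_scanners = 3, n_sessions = 3,
                     seed = 1000 + s, labels = c(x = 100))))
    tab$inter$cv_pct - mean(tab$intra$cv_pct)
  }, numeric(1))
  expect_gt(mean(diffs), 3 * stats::sd(diffs) / sqrt(200))
})

test_that("across-label summaries follow their scope definitions", {
  panel <- gen_multisite_panel(toy_panel_spec(n_scanners = 3, n_sessions = 4,
                                              seed = 8))
  tab <- build_repro_table(panel)
  s_inter <- summarize_across_labels(tab, "inter")
  expect_equal(s_inter$mean_cv_pct, mean(tab$inter$cv_pct))
  expect_equal(s_inter$sd_cv_pct, stats::sd(tab$inter$cv_pct))
  s_sc <- summarize_across_labels(tab, "per-scanner")
  expect_equal(nrow(s_sc), 3)
  a_rows <- tab$intra[tab$intra$scanner_id == "A", ]
  expect_equal(s_sc$mean_cv_pct[s_sc$group == "A"], mean(a_rows$cv_pct))
  # the mean-intra headline averages per-scanner means across scanners
  s_mi <- summarize_across_labels(tab, "mean-intra")
  expect_equal(s_mi$mean_cv_pct, mean(s_sc$mean_cv_pct))
  expect_equal(s_mi$sd_cv_pct, stats::sd(s_sc$mean_cv_pct))
  # single label: mean equals the label's CV, SD is NA
  one <- build_repro_table(gen_multisite_panel(
    toy_panel_spec(n_scanners = 3, n_sessions = 3, seed = 9,
                   labels = c(only = 50))))
  s1 <- summarize_across_labels(one, "inter")
  expect_equal(s1$mean_cv_pct, one$inter$cv_pct)
  expect_true(is.na(s1$sd_cv_pct))
})

test_that("ratio summary reports mean, extremes and their labels", {
  df <- data.frame(label = c("a", "b", "c"),
                   ratio_inter_to_mean_intra = c(2, 4, 3))
  rs <- ratio_summary(df)
  expect_equal(rs$mean_ratio, 3)
  expect_equal(rs$min_label, "a")
  expect_equal(rs$max_label, "b")
  same <- data.frame(label = c("a", "b"),
                     ratio_inter_to_mean_intra = c(2.5, 2.5))
  rs2 <- ratio_summary(same)
  expect_equal(rs2$mean_ratio, rs2$min_ratio)
  expect_equal(rs2$mean_ratio, rs2$max_ratio)
})
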