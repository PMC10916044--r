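test_that("beta, M and WGBS transforms match their closed forms", {
  expect_equal(beta_from_intensities(0, 0), 0)
  expect_equal(beta_from_intensities(100, 100), 1 / 3)
  expect_equal(beta_from_intensities(900, 0), 0.9)
  expect_error(beta_from_intensities(-1, 0), "negative")

  expect_equal(m_from_beta(0.5), 0)
  expect_equal(m_from_beta(0.8), 2)
  b <- c(0.1, 0.25, 0.4)
  expect_equal(m_from_beta(1 - b), -m_from_beta(b))
  expect_equal(beta_from_m(m_from_beta(b)), b)
  expect_error(m_from_beta(1.2), "outside")
  expect_error(m_from_beta(0), "clipping")
  expect_equal(m_from_beta(0, clip = 1e-6), log2(1e-6 / (1 - 1e-6)))

  expect_equal(wgbs_logit(5, 5), 0)
  expect_equal(wgbs_logit(3, 0), log2(7))
  expect_equal(wgbs_logit(0, 3), -log2(7))
  expect_equal(wgbs_logit(7, 2), -wgbs_logit(2, 7))
  expect_error(wgbs_logit(-1, 2), "negative")
})

test_that("rmse and paired Cohen's d follow their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(rmse(x, y), rmse(y, x))
  expect_equal(rmse(c(x, NA), c(y, 1)), rmse(x, y))  # pairwise complete
  expect_error(rmse(NA_real_, 1), "complete")

  expect_equal(paired_cohens_d(c(2, 4, 6), c(1, 2, 3)), 2)
  set.seed(2)
  noise <- rnorm(30)
  y <- rnorm(30)
  expect_equal(paired_cohens_d(y + 3 + noise, y),
               mean(3 + noise) / sd(noise))
  expect_error(paired_cohens_d(y, y), "zero sd")
})

test_that("row-linear fit reproduces the closed-form worked example", {
  matched <- tibble::tibble(
    site = "s1",
    platform = rep(c("P1", "P2"), each = 3),
    sample = rep(c("a", "b", "c"), 2),
    m = c(0, 1, 2, 0, 2, 4))
  fit <- rowlinear_fit(matched)
  # consensus (0, 1.5, 3): slopes 2/3 and 4/3 with zero residual
  expect_equal(fit$sensitivity, c(2 / 3, 4 / 3))
  expect_equal(fit$precision, c(0, 0))
  expect_equal(fit$n_samples, c(3L, 3L))
  # platform slopes average to 1 when all platforms feed the consensus
  expect_equal(mean(fit$sensitivity), 1)
  # Mandel centring changes alpha only
  fitc <- rowlinear_fit(matched, center = TRUE)
  expect_equal(fitc$sensitivity, fit$sensitivity)
  expect_equal(fitc$precision, fit$precision)
  expect_false(isTRUE(all.equal(fitc$alpha, fit$alpha)))

  # identical platforms: slopes 1, precisions 0
  same <- dplyr::mutate(matched, m = rep(c(0, 1, 2), 2))
  fit1 <- rowlinear_fit(same)
  expect_equal(fit1$sensitivity, c(1, 1))
  expect_equal(fit1$precision, c(0, 0))

  # zero consensus variance is a degenerate fit
  flat <- dplyr::mutate(matched, m = 1)
  expect_error(rowlinear_fit(flat), "degenerate")
})

test_that("row-linear slope means average to one across many sites", {
  cfg <- sim_config(seed = 33, n_samples = 12,
                    platform_slope = c(EPICv1 = 0.9, EPICv2 = 1.1),
                    platform_sigma = c(EPICv1 = 0.2, EPICv2 = 0.2),
                    detection_fail_rate = 0, zero_coverage_rate = 0)
  sim <- simulate_methylation_dataset(cfg, sites = 60)
  matched <- match_cross_platform(sim$tables)
  fit <- rowlinear_fit(matched)
  per_site <- dplyr::summarise(dplyr::group_by(fit, site),
                               ms = mean(sensitivity))
  expect_true(all(abs(per_site$ms - 1) < 1e-9))
})

test_that("cross-platform matching drops failures and resolves duplicates", {
  cfg <- sim_config(seed = 5, n_samples = 6,
                    detection_fail_rate = 0, zero_coverage_rate = 0)
  sim <- simulate_methylation_dataset(cfg, sites = 20)
  tables <- sim$tables
  # no dropouts: full block
  matched <- match_cross_platform(tables)
  expect_equal(dplyr::n_distinct(matched$site), 20L)
  expect_equal(nrow(matched), 20L * 6L * 3L)
  expect_equal(nrow(attr(matched, "exclusions")), 0L)

  # plant one detection failure on EPICv2 and a zero-coverage WGBS cell
  t2 <- tables
  t2$EPICv2$qc[t2$EPICv2$site == "site_0003"][2] <- 0.2
  t2$WGBS$qc[t2$WGBS$site == "site_0007"][4] <- 0
  t2$WGBS$value[t2$WGBS$site == "site_0007"][4] <- NA
  matched2 <- match_cross_platform(t2)
  expect_equal(dplyr::n_distinct(matched2$site), 18L)
  excl <- attr(matched2, "exclusions")
  expect_setequal(excl$site, c("site_0003", "site_0007"))
  expect_setequal(excl$reason, c("detection_p_failure", "zero_coverage"))

  expect_error(match_cross_platform(list(
    methyl_table(tibble::tibble(site = "s", sample = "x", value = 1,
                                qc = 0.01), "A"),
    methyl_table(tibble::tibble(site = "s", sample = "y", value = 1,
                                qc = 0.01), "B"))), "shared samples")
})

test_that("duplicate-location probes resolve to the first manifest row", {
  g <- fixture_genome()
  mf <- design_manifest(g, n_probes = 6, seed = 12, n_location = 1)
  pair <- attr(mf, "replicate_truth")$location[[1]]
  samples <- sprintf("S%02d", 1:5)
  mk_tbl <- function(platform) {
    methyl_table(tidyr::crossing(site = mf$ilmn_id, sample = samples) |>
                   dplyr::mutate(value = rnorm(dplyr::n()), qc = 0.001),
                 platform, space = "M", qc_type = "detection_p")
  }
  set.seed(1)
  tables <- list(EPICv1 = mk_tbl("EPICv1"), EPICv2 = mk_tbl("EPICv2"))
  matched <- match_cross_platform(tables, manifest = mf)
  excl <- attr(matched, "exclusions")
  # the later manifest row of the co-located pair is dropped, and sites
  # are re-keyed by coordinate
  first_of_pair <- pair[which.min(match(pair, mf$ilmn_id))]
  later <- setdiff(pair, first_of_pair)
  expect_true(later %in%
                excl$site[excl$reason ==
                            "duplicate_location_later_in_manifest"])
  coord <- paste(mf$chrom[mf$ilmn_id == first_of_pair],
                 mf$mapinfo[mf$ilmn_id == first_of_pair], sep = ":")
  expect_true(coord %in% matched$site)
})

test_that("WGBS evidence flags probes tracking an off-target CpG", {
  set.seed(7)
  n <- 18
  samples <- sprintf("S%02d", 1:n)
  on_wgbs <- tibble::tibble(sample = samples, value = rnorm(n, 0, 2))
  off_wgbs <- tidyr::crossing(coord = c("chr1:500", "chr1:900"),
                              sample = samples) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 0, 2))
  planted <- off_wgbs$value[off_wgbs$coord == "chr1:900"]

  # probe tracks the off-target at chr1:900
  probe_off <- tibble::tibble(sample = samples,
                              m = planted + rnorm(n, 0, 0.1))
  ev <- crosshyb_wgbs_evidence(probe_off, on_wgbs, off_wgbs)
  expect_equal(ev$flag, "Y")
  expect_equal(ev$best_off_coordinate, "chr1:900")
  expect_equal(ev$num_offtargets, 2L)
  expect_lt(ev$best_off_rmse, ev$rmse_on_target)

  # probe tracks its own target
  probe_on <- tibble::tibble(sample = samples,
                             m = on_wgbs$value + rnorm(n, 0, 0.1))
  expect_equal(crosshyb_wgbs_evidence(probe_on, on_wgbs, off_wgbs)$flag,
               "N")

  # no CpG off-target, or too few matched pairs: not evaluated
  expect_equal(crosshyb_wgbs_evidence(probe_on, on_wgbs,
                                      off_wgbs[0, ])$flag,
               "not_evaluated")
  sparse <- dplyr::mutate(probe_on,
                          m = ifelse(dplyr::row_number() <= 8, m, NA))
  expect_equal(crosshyb_wgbs_evidence(sparse, on_wgbs, off_wgbs)$flag,
               "not_evaluated")
})

test_that("replicate verdict rules adjudicate constructed sets", {
  rs <- simulate_replicate_set(101, slopes = c(1, 0.6, 0.6),
                               sigmas = c(0.05, 1, 1))
  v <- evaluate_replicate_set(rs$members, epicv1 = rs$epicv1,
                              wgbs = rs$wgbs)
  expect_equal(v$label[v$probe_id == "P1"], "superior")
  # superior is unique and beats every member and the set mean
  expect_equal(sum(v$label == "superior", na.rm = TRUE), 1L)
  i <- which(v$probe_id == "P1")
  expect_true(all(v$sensitivity[i] >= v$sensitivity[-i]))
  expect_true(all(v$precision[i] <= v$precision[-i]))
  expect_gt(v$sensitivity[i], v$mean_sensitivity[1])
  expect_lt(v$precision[i], v$mean_precision[1])

  # split axes: best sensitivity and best precision in different members
  rs2 <- simulate_replicate_set(11, slopes = c(1.3, 0.7),
                                sigmas = c(0.6, 0.05))
  v2 <- evaluate_replicate_set(rs2$members, epicv1 = rs2$epicv1,
                               wgbs = rs2$wgbs)
  expect_setequal(v2$label, c("best_sensitivity", "best_precision"))

  # insufficient matched values
  rs3 <- simulate_replicate_set(12)
  rs3$members <- purrr::map(rs3$members, function(m) {
    m$m[1:10] <- NA
    m
  })
  v3 <- evaluate_replicate_set(rs3$members, epicv1 = rs3$epicv1,
                               wgbs = rs3$wgbs)
  expect_true(all(v3$label == "insufficient"))

  expect_error(evaluate_replicate_set(rs3$members[1]), "size")
})

test_that("verdicts agree with a brute-force re-evaluation of the rule table", {
  for (seed in 1:20) {
    rs <- simulate_replicate_set(
      200 + seed,
      slopes = runif(3, 0.4, 1.3),
      sigmas = runif(3, 0.05, 0.9))
    v <- evaluate_replicate_set(rs$members, epicv1 = rs$epicv1,
                                wgbs = rs$wgbs)
    s <- v$sensitivity; p <- v$precision
    ms <- v$mean_sensitivity[1]; mp <- v$mean_precision[1]
    ib <- which.max(s); ip <- which.min(p)
    expected <- rep(NA_character_, 3)
    if (ib == ip && s[ib] > max(s[-ib]) && s[ib] > ms &&
        p[ip] < min(p[-ip]) && p[ip] < mp) {
      expected[ib] <- "superior"
      iw <- which.min(s)
      if (iw != ib && s[iw] < min(s[-iw]) && p[iw] > max(p[-iw]) &&
          s[iw] < ms && p[iw] > mp && which.max(p) == iw) {
        expected[iw] <- "inferior"
      }
    } else if (mp < min(p)) {
      expected[] <- "best_precision_by_group_mean"
      expected[ib] <- "best_sensitivity"
    } else {
      expected[ib] <- "best_sensitivity"
      if (ip != ib) expected[ip] <- "best_precision"
    }
    expect_equal(v$label, expected)
    # set-mean sensitivity is intermediate of the member extremes
    expect_gte(ms, min(s) - 1e-9)
    expect_lte(ms, max(s) + 1e-9)
  }
})

test_that("WGBS-only route ranks by RMSE with group-mean upgrade", {
  rs <- simulate_replicate_set(55, slopes = c(1, 1, 1),
                               sigmas = c(0.05, 1.2, 1.2))
  v <- evaluate_replicate_set(rs$members, epicv1 = NULL, wgbs = rs$wgbs)
  expect_equal(v$label[v$probe_id == "P1"], "superior_by_WGBS")
  expect_true(all(v$label[v$probe_id != "P1"] == "inferior_by_WGBS"))

  # equal-noise members: averaging beats each individual
  rs2 <- simulate_replicate_set(56, slopes = c(1, 1, 1),
                                sigmas = c(0.8, 0.8, 0.8))
  v2 <- evaluate_replicate_set(rs2$members, epicv1 = NULL,
                               wgbs = rs2$wgbs)
  if (v2$mean_rmse_wgbs[1] < min(v2$rmse_wgbs)) {
    expect_true(all(v2$label == "superior_group_mean_WGBS"))
  } else {
    expect_equal(sum(v2$label == "superior_by_WGBS"), 1L)
  }
})

test_that("RLM deviations subtract the per-site median", {
  m <- tibble::tibble(site = rep(c("s1", "s2"), each = 3),
                      sample = rep(c("a", "b", "c"), 2),
                      m = c(1, 2, 9, 5, 5, 5))
  d <- rlm_deviations(m)
  expect_equal(d$deviation, c(-1, 0, 7, 0, 0, 0))
  # matrix input and constant matrix -> all zeros
  mat <- matrix(3, 4, 3, dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  expect_true(all(rlm_deviations(mat)$deviation == 0))
  # shifting a sample that is already extremal leaves the per-site
  # median, and hence every other sample's deviations, untouched
  m2 <- tidyr::crossing(site = paste0("s", 1:30),
                        sample = c("a", "b", "c", "d"))
  set.seed(4)
  m2$m <- rnorm(nrow(m2)) + ifelse(m2$sample == "a", 100, 0)
  base <- rlm_deviations(m2)
  shifted <- dplyr::mutate(m2, m = m + ifelse(sample == "a", 10, 0))
  d2 <- rlm_deviations(shifted)
  expect_equal(d2$deviation[d2$sample != "a"],
               base$deviation[base$sample != "a"])
  expect_equal(d2$deviation[d2$sample == "a"],
               base$deviation[base$sample == "a"] + 10)
})

test_that("the cleanest technical replicate is selected by failed-probe count", {
  tbl <- methyl_table(
    tibble::tibble(site = rep(paste0("s", 1:10), 3),
                   sample = rep(c("r1", "r2", "r3"), each = 10),
                   value = 0,
                   qc = c(rep(0.01, 10),
                          c(rep(0.2, 3), rep(0.01, 7)),
                          c(rep(0.2, 1), rep(0.01, 9)))),
    "EPICv2")
  expect_equal(select_technical_replicate(tbl, c("r1", "r2", "r3")), "r1")
  expect_equal(select_technical_replicate(tbl, c("r2", "r3")), "r3")
})
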