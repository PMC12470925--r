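test_that("total effect and relative risk recover the published margins", {
  counts <- published_counts()
  te <- total_effect(counts, n_draws = 1e4, seed = 31)
  rr <- relative_risk(counts, n_draws = 1e4, seed = 31)
  expect_equal(summarize_draws(te)$median, 0.0044, tolerance = 0.01)
  expect_equal(summarize_draws(rr)$median, 2.00, tolerance = 0.005)
  # symmetry: identical race counts give a null disparity
  n <- pomediate:::empty_count_array("five_by_five")
  r <- n
  n[, "NBW", "TD"] <- 1000L
  r[, "NBW", "TD"] <- 10L
  sym <- strata_counts(n, r)
  expect_equal(summarize_draws(total_effect(sym, n_draws = 2e4,
                                            seed = 1))$median,
               0, tolerance = 2e-3)
  expect_equal(summarize_draws(relative_risk(sym, n_draws = 2e4,
                                             seed = 1))$median,
               1, tolerance = 0.2)
  # doubling the Black deaths approximately doubles the relative risk
  r2 <- r
  r2["Black", "NBW", "TD"] <- 20L
  rr2 <- summarize_draws(relative_risk(strata_counts(n, r2), n_draws = 2e4,
                                       seed = 2))$median
  expect_equal(rr2, 2, tolerance = 0.25)
  # a race without births is an error
  n0 <- n; n0["Black", , ] <- 0L
  expect_error(total_effect(strata_counts(n0, pomediate:::
                                            empty_count_array("five_by_five"))),
               "at least one birth")
})

test_that("counterfactual propagation reproduces the published worked example", {
  counts <- published_counts()
  res <- mediate_control(counts, control_strategy(c("ELBW", "EPTD")),
                         n_draws = 1e4, seed = 11,
                         s_r_fixed = published_s_r(c("ELBW", "EPTD")))
  # p.r is exact integer arithmetic once s.r is fixed
  expect_equal(res$p_r$Black$median, 21881 - (10729 - 73))
  expect_equal(res$p_r$nonBlack$median, 101641 - (36779 - 148))
  expect_equal(res$new_po$Black$median, 11225 / 2475161, tolerance = 1e-10)
  expect_equal(res$cde$median, 11225 / 2475161 - 65010 / 22973056,
               tolerance = 1e-10)
  expect_equal(res$pa$median, 61.4, tolerance = 0.005)
  expect_equal(res$pa$lo2_5, 60.3, tolerance = 0.01)
  expect_equal(res$pa$hi97_5, 62.4, tolerance = 0.01)

  res2 <- mediate_control(counts, control_strategy(c("LBW", "PTD")),
                          n_draws = 1e4, seed = 12,
                          s_r_fixed = published_s_r(c("LBW", "PTD")))
  expect_equal(res2$cde$median, 0.0042, tolerance = 0.02)
  expect_equal(res2$pa$median, 4.0, tolerance = 0.05)
})

test_that("drawwise identities hold exactly", {
  # published strata plus a populated reference cell (rates as implied by
  # the published controlled counts) so the reference posterior is
  # data-dominated
  counts <- published_counts()
  n <- counts$n; r <- counts$r
  n["Black", "NBW", "TD"] <- 1500000L; r["Black", "NBW", "TD"] <- 4185L
  n["nonBlack", "NBW", "TD"] <- 18000000L
  r["nonBlack", "NBW", "TD"] <- 30218L
  counts <- strata_counts(n, r, counts$n_race, counts$r_race)
  res <- mediate_control(counts, control_strategy(c("ELBW", "EPTD")),
                         n_draws = 2000, seed = 3)
  d <- res$draws
  expect_equal(d$pa, 100 * (d$te - d$cde) / d$te, tolerance = 1e-12)
  expect_equal(d$cde, d$new_po$Black - d$new_po$nonBlack, tolerance = 1e-12)
  # mediated effect + CDE = TE per draw by construction
  expect_equal(res$mediated_effect$median,
               summarize_draws(d$te - d$cde)$median, tolerance = 1e-12)
  expect_true(all(d$p_r$Black >= 0) && all(d$p_r$nonBlack >= 0))
  # with reference rates below the targeted plug-in rate, the
  # counterfactual count cannot exceed the observed total
  expect_true(all(d$p_r$Black <= counts$r_race["Black"]))
  expect_true(all(d$p_r$nonBlack <= counts$r_race["nonBlack"]))
})

test_that("degenerate control strategies behave as identities", {
  counts <- published_counts()
  # controlling to the stratum's own observed deaths leaves the totals alone
  tg <- c("LBW", "PTD")
  res <- mediate_control(counts, control_strategy(tg), n_draws = 2000,
                         seed = 8,
                         s_r_fixed = c(
                           Black = counts$r["Black", tg[1], tg[2]],
                           nonBlack = counts$r["nonBlack", tg[1], tg[2]]))
  expect_equal(res$p_r$Black$median, unname(counts$r_race["Black"]))
  expect_equal(res$p_r$nonBlack$median, unname(counts$r_race["nonBlack"]))
  # CDE then equals the plug-in total effect, so PA is centred at zero
  expect_lt(abs(res$pa$median), 1)
  expect_true(res$pa$lo2_5 < 0 && res$pa$hi97_5 > 0)
  # controlling a stratum that already sits at the reference rate removes
  # nothing: PA centred at zero
  n <- counts$n; r <- counts$r
  n["Black", "NBW", "TD"] <- 1000000L; r["Black", "NBW", "TD"] <- 2790L
  n["nonBlack", "NBW", "TD"] <- 10000000L
  r["nonBlack", "NBW", "TD"] <- 16790L
  n["Black", "LBW", "TD"] <- 100000L; r["Black", "LBW", "TD"] <- 279L
  n["nonBlack", "LBW", "TD"] <- 1000000L
  r["nonBlack", "LBW", "TD"] <- 1679L
  aug <- strata_counts(n, r, counts$n_race, counts$r_race)
  res2 <- mediate_control(aug, control_strategy(c("LBW", "TD")),
                          n_draws = 4000, seed = 9)
  expect_lt(abs(res2$pa$median), 1)
  expect_true(res2$pa$lo2_5 < 0 && res2$pa$hi97_5 > 0)
  # the reference cell cannot be targeted
  expect_error(control_strategy(c("NBW", "TD")), "reference cell")
})

test_that("brute-force sampler agrees with the propagation on tiny counts", {
  counts <- tiny_counts()
  cell <- c("ELBW", "VPTD")
  n_impl <- 1e5
  res <- mediate_control(counts, control_strategy(cell), n_draws = n_impl,
                         seed = 17)
  # independent oracle: raw rbeta + arithmetic, nothing from the package
  set.seed(1234)
  k <- 1e6
  a <- 1; b <- 10
  rb <- counts$r_race["Black"]; nb <- counts$n_race["Black"]
  rn <- counts$r_race["nonBlack"]; nn <- counts$n_race["nonBlack"]
  te_o <- rbeta(k, a + rb, b + nb - rb) - rbeta(k, a + rn, b + nn - rn)
  ref_b <- rbeta(k, a + counts$r["Black", "NBW", "TD"],
                 b + counts$n["Black", "NBW", "TD"] -
                   counts$r["Black", "NBW", "TD"])
  ref_n <- rbeta(k, a + counts$r["nonBlack", "NBW", "TD"],
                 b + counts$n["nonBlack", "NBW", "TD"] -
                   counts$r["nonBlack", "NBW", "TD"])
  pr_b <- rb - (counts$r["Black", cell[1], cell[2]] -
                  counts$n["Black", cell[1], cell[2]] * ref_b)
  pr_n <- rn - (counts$r["nonBlack", cell[1], cell[2]] -
                  counts$n["nonBlack", cell[1], cell[2]] * ref_n)
  cde_o <- pr_b / nb - pr_n / nn
  pa_o <- 100 * (te_o - cde_o) / te_o
  se <- 1.2533 * stats::sd(pa_o) * sqrt(1 / k + 1 / n_impl)
  expect_lt(abs(res$pa$median - stats::median(pa_o)), 3 * se)
})

test_that("binary joint control equals the all-cell five-level control", {
  spec <- default_spec(5e4)
  cohort <- generate_records(spec, seed = 21)
  counts5 <- aggregate_strata(cohort$records, "five_by_five")
  counts2 <- aggregate_strata(cohort$records, "binary")
  res5 <- mediate_control(counts5,
                          control_strategy("abnormal_both", "five_by_five"),
                          n_draws = 4000, seed = 9)
  res2 <- mediate_control(counts2,
                          control_strategy("abnormal_both", "binary"),
                          n_draws = 4000, seed = 9)
  # same records, same seed: identical marginals and reference cell, and
  # the summed counterfactual deficit is identical, so the draws coincide
  expect_equal(res5$draws$pa, res2$draws$pa, tolerance = 1e-10)
  expect_equal(res5$cde$median, res2$cde$median, tolerance = 1e-10)
})

test_that("model 1 reports the three strategies coherently", {
  spec <- default_spec(5e4)
  counts2 <- collapse_binary(generate_counts(spec, seed = 33)$counts)
  tab <- run_model1(counts2, n_draws = 4000, seed = 13)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$mediator[3], "Birthweight and length of gestation")
  # mediated effect + CDE = TE for every strategy (medians differ from the
  # drawwise identity only by percentile non-additivity)
  te <- attr(tab, "te")$median
  expect_true(all(abs(tab$cde_median + tab$mediated_median - te) < 1e-3))
  # no-disparity population: null effects and an uninformative attribution
  # (PA is a ratio with a zero-centred denominator, so only TE and CDE are
  # interpretable there)
  n <- pomediate:::empty_count_array("binary")
  r <- n
  n[, , ] <- 5000L
  r[, , ] <- 50L
  flat <- run_model1(strata_counts(n, r), n_draws = 4000, seed = 14)
  te_flat <- attr(flat, "te")
  expect_true(te_flat$lo2_5 < 0 && te_flat$hi97_5 > 0)
  expect_true(all(flat$cde_lo2_5 < 0 & flat$cde_hi97_5 > 0))
  expect_true(all(flat$pa_hi97_5 - flat$pa_lo2_5 > 100))
})

test_that("incidence and conditional relative risks match plug-in oracles", {
  counts <- published_counts()
  irr <- summarize_draws(incidence_relative_risk(counts, "ELBW", "EPTD",
                                                 n_draws = 1e4, seed = 19))
  expect_equal(irr$median, (26163 / 2475161) / (88158 / 22973056),
               tolerance = 0.005)
  crr <- summarize_draws(conditional_rate_ratio(counts, "ELBW", "EPTD",
                                                n_draws = 1e4, seed = 19))
  expect_equal(crr$median, (10729 / 26163) / (36779 / 88158),
               tolerance = 0.01)
  # equal incidence and mortality give unit ratios
  n <- pomediate:::empty_count_array("five_by_five")
  r <- n
  n[, "NBW", "TD"] <- 10000L; n[, "LBW", "PTD"] <- 500L
  r[, "NBW", "TD"] <- 30L; r[, "LBW", "PTD"] <- 10L
  eq <- strata_counts(n, r)
  expect_equal(summarize_draws(incidence_relative_risk(
    eq, "LBW", "PTD", n_draws = 2e4, seed = 2))$median, 1, tolerance = 0.05)
  expect_equal(summarize_draws(conditional_rate_ratio(
    eq, "LBW", "PTD", n_draws = 2e4, seed = 2))$median, 1, tolerance = 0.15)
  # unobserved-in-one-race cells carry the instability flag
  expect_true(attr(incidence_relative_risk(published_counts(), "VLBW",
                                           "PostTD", n_draws = 100,
                                           seed = 1), "unstable"))
})

test_that("the five-by-five model table flags and estimates correctly", {
  counts <- published_counts()
  tab <- run_model2(counts, n_draws = 4000, seed = 23)
  expect_equal(nrow(tab), 25)
  ee <- tab[tab$bw_cat == "ELBW" & tab$lg_cat == "EPTD", ]
  expect_equal(ee$po_black_median, 0.410, tolerance = 0.005)
  expect_equal(ee$po_nonblack_median, 0.417, tolerance = 0.005)
  expect_equal(ee$inc_rr_median, 2.75, tolerance = 0.01)
  # the reference cell has no attribution of its own
  ref <- tab[tab$bw_cat == "NBW" & tab$lg_cat == "TD", ]
  expect_equal(ref$status, "reference")
  expect_true(is.na(ref$pa_median))
  # strata without observations are reported as such, not estimated
  mac <- tab[tab$bw_cat == "MAC" & tab$lg_cat %in% c("EPTD", "VPTD"), ]
  expect_true(all(mac$status == "not_observed"))
  expect_true(all(is.na(mac$po_black_median)))
  # a no-disparity synthetic population: PA ~ 0 and ratios ~ 1 everywhere
  n <- pomediate:::empty_count_array("five_by_five")
  r <- n
  n[, "NBW", "TD"] <- 50000L; r[, "NBW", "TD"] <- 100L
  n[, "ELBW", "EPTD"] <- 1000L; r[, "ELBW", "EPTD"] <- 400L
  n[, "LBW", "PTD"] <- 3000L; r[, "LBW", "PTD"] <- 45L
  flat <- run_model2(strata_counts(n, r), n_draws = 4000, seed = 29)
  obs <- flat[flat$status == "observed", ]
  te_flat <- attr(flat, "te")
  expect_true(te_flat$lo2_5 < 0 && te_flat$hi97_5 > 0)
  expect_true(all(abs(obs$inc_rr_median - 1) < 0.1))
  expect_true(all(abs(obs$cond_rr_median - 1) < 0.3))
  # attribution is uninformative without a disparity to attribute: interval
  # widths are tens of percentage points, versus ~1 point when a genuine
  # disparity anchors the denominator
  expect_true(all(obs$pa_hi97_5 - obs$pa_lo2_5 > 10))
})
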