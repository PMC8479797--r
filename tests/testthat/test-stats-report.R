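test_that("identical samples give t = 0, p = 1; degenerate pairs are handled", {
  a <- rp_set(c(0.2, 0.3, 0.4), condition = "a")
  b <- rp_set(c(0.2, 0.3, 0.4), condition = "b")
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)

  flat1 <- rp_set(rep(0.5, 4), condition = "f1")
  flat2 <- rp_set(rep(0.5, 4), condition = "f2")
  cmp0 <- compare_conditions(flat1, flat2)
  expect_equal(cmp0$p, 1)
  expect_error(compare_conditions(rp_set(0.1), flat1), "at least 2")
})

test_that("pooled t matches the textbook formula on a small fixture", {
  a <- rp_set(c(1, 2, 3), condition = "a")
  b <- rp_set(c(2, 3, 4), condition = "b")
  cmp <- compare_conditions(a, b)
  # hand-computed pooled-variance oracle
  sp2 <- (2 * 1 + 2 * 1) / 4           # both sample variances are 1
  t_oracle <- (2 - 3) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * stats::pt(t_oracle, df = 4)
  expect_equal(cmp$t, t_oracle, tolerance = 1e-12)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, p_oracle, tolerance = 1e-12)

  # swapping groups negates t, preserves p
  rev <- compare_conditions(b, a)
  expect_equal(rev$t, -cmp$t)
  expect_equal(rev$p, cmp$p)
})

test_that("t and p are invariant under rescaling both samples", {
  set.seed(9)
  a <- rp_set(stats::rnorm(20, 0.2, 0.05), condition = "a")
  b <- rp_set(stats::rnorm(20, 0.25, 0.05), condition = "b")
  sa <- rp_set(a$rp * 3.7, condition = "a")
  sb <- rp_set(b$rp * 3.7, condition = "b")
  expect_equal(compare_conditions(sa, sb)$t, compare_conditions(a, b)$t,
               tolerance = 1e-12)
  expect_equal(compare_conditions(sa, sb)$p, compare_conditions(a, b)$p,
               tolerance = 1e-12)
})

test_that("paper-scale synthetic conditions separate at p < 1e-4 with small percent errors", {
  pr <- actuation_protocol()
  me3 <- rp_from_tracks(simulate_condition("dido1_h3k4me3", protocol = pr,
                                           seed = 101), pr)
  me1 <- rp_from_tracks(simulate_condition("dido1_h3k4me1", protocol = pr,
                                           seed = 102), pr)
  cmp <- compare_conditions(me3, me1)
  expect_equal(cmp$n_a, 360)
  expect_lt(cmp$p, 1e-4)
  expect_lt(cmp$percent_error_a, 5)
  expect_lt(cmp$percent_error_b, 5)
  # the conservative roller-level test still separates these conditions
  expect_lt(compare_conditions(me3, me1, unit = "roller")$p, 0.01)
})

test_that("min-max normalisation maps extremes to 0 and 1", {
  expect_equal(minmax_normalize_array(c(10, 20, 30)), c(0, 0.5, 1))
  set.seed(3)
  v <- stats::rnorm(17)
  s <- minmax_normalize_array(v)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  expect_equal(order(s), order(v))
  expect_error(minmax_normalize_array(rep(2, 5)), "constant array")
})

test_that("replicates are averaged before scaling and arrays combine rank-consistently", {
  arr1 <- matrix(c(10, 10, 10, 20, 20, 20, 30, 30, 30), nrow = 3,
                 byrow = TRUE, dimnames = list(c("p1", "p2", "p3"), NULL))
  expect_equal(unname(minmax_normalize_array(arr1)), c(0, 0.5, 1))
  # a second array with the same rank order but different gains
  arr2 <- arr1 * 5 + 100
  comb <- minmax_normalize_array(list(arr1, arr2))
  expect_equal(comb$peptide, c("p1", "p2", "p3"))
  expect_equal(order(comb$mean), 1:3)
  expect_equal(comb$sd, rep(0, 3))  # identical after per-array scaling
})

test_that("reports carry one complete row per condition", {
  pr <- short_protocol(3)
  sets <- list(
    dido1_h3k4me3 = rp_from_tracks(simulate_condition("dido1_h3k4me3",
                                                      n_rollers = 4,
                                                      protocol = pr,
                                                      seed = 111), pr),
    dido1_h3k4me2 = rp_from_tracks(simulate_condition("dido1_h3k4me2",
                                                      n_rollers = 4,
                                                      protocol = pr,
                                                      seed = 112), pr),
    dido1_h3k4me1 = rp_from_tracks(simulate_condition("dido1_h3k4me1",
                                                      n_rollers = 4,
                                                      protocol = pr,
                                                      seed = 113), pr))
  model <- fit_calibration(rbind(
    anchor_points(family = "dido1"),
    calibration_points("mid", rp = 0.3, kd = 1e-8, family = "dido1")))
  rep <- build_report(sets, model, reference = "dido1_h3k4me3")
  expect_equal(nrow(rep), 3)
  expect_false(any(is.na(rep$kd)))
  expect_false(any(is.na(rep$kd_lower)))
  ref_row <- rep[rep$condition == "dido1_h3k4me3", ]
  expect_equal(ref_row$fold_change, 1)
  expect_equal(ref_row$ddg_kcal_mol, 0)
  # weaker rolling => weaker calibrated affinity => positive ddG vs reference
  expect_gt(rep$ddg_kcal_mol[rep$condition == "dido1_h3k4me1"], 0)

  expect_error(build_report(sets, model, reference = "nope"),
               "not among")
  expect_error(build_report(sets, model, reference = "dido1_h3k4me3",
                            published = c(orphan = 1e-6)), "orphan")
})

test_that("constant published/calibrated ratios are reproduced exactly by scaling", {
  pr <- short_protocol(2)
  sets <- list(
    a = rp_from_tracks(simulate_condition("orc1_h4k20me2", n_rollers = 3,
                                          protocol = pr, seed = 121), pr),
    b = rp_from_tracks(simulate_condition("orc1_h4k20me1", n_rollers = 3,
                                          protocol = pr, seed = 122), pr),
    c = rp_from_tracks(simulate_condition("orc1_h4", n_rollers = 3,
                                          protocol = pr, seed = 123), pr))
  model <- fit_calibration(rbind(
    anchor_points(family = "orc1"),
    calibration_points("mid", rp = 0.3, kd = 1e-8, family = "orc1")))
  plain <- build_report(sets, model, reference = "a")
  published <- stats::setNames(plain$kd[1:2] * 4.5, plain$condition[1:2])
  rep <- build_report(sets, model, reference = "a", published = published)
  expect_equal(attr(rep, "scaling_factor"), 4.5, tolerance = 1e-12)
  expect_equal(rep$scaled_kd[1:2], unname(published), tolerance = 1e-12)
  # scaling never changes within-family ddG
  expect_equal(delta_delta_g(rep$scaled_kd[2], rep$scaled_kd[1]),
               rep$ddg_kcal_mol[2], tolerance = 1e-12)
})

test_that("report files are written as CSV and JSON", {
  pr <- short_protocol(1)
  sets <- list(x = rp_from_tracks(simulate_condition("ube2d1_ubiquitin",
                                                     n_rollers = 2,
                                                     protocol = pr,
                                                     seed = 131), pr))
  model <- fit_calibration(rbind(anchor_points(),
                                 calibration_points("m", 0.3, 1e-8)))
  rep <- build_report(sets, model, reference = "x")
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.csv")))
  back <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$rows$mean_rp, rep$mean_rp, tolerance = 1e-12)
})
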