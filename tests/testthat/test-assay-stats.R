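test_that("delta-delta-Ct recovers planted folds and normalizes the control to 1", {
  # identical Ct everywhere: all folds are exactly 1
  flat <- tidyr::expand_grid(sample = paste0("s", 1:4), gene = c("t", "r"),
                             replicate = 1:2) |>
    dplyr::mutate(group = rep(c("control", "trt"), each = 8), ct = 20)
  dd <- delta_delta_ct(flat, "control", reference_gene = "r", target_gene = "t")
  expect_equal(dd$rel_expr, rep(1, 4))
  # worked duplicate example: ddCt = -2 => fold 4
  ct <- tibble::tibble(
    sample = rep(c("c1", "t1"), each = 2),
    group = rep(c("control", "treated"), each = 2),
    gene = rep(c("Hamp", "Atp5b"), 2), replicate = 1L,
    ct = c(22, 18, 20, 18))
  dd <- delta_delta_ct(ct, "control", reference_gene = "Atp5b")
  expect_equal(dd$delta_delta_ct[dd$group == "treated"], -2)
  expect_equal(dd$rel_expr[dd$group == "treated"], 4)
  # generator round trip at zero noise recovers 3.6 exactly
  cfg0 <- sim_config(seed = 6, ct_noise_sd = 0)
  sim <- simulate_ct_table(tibble::tibble(group = c("control", "high_iron"),
                                          fold_change = c(1, 3.6)),
                           cfg0, control_group = "control")
  dd <- delta_delta_ct(sim, "control", reference_gene = "reference",
                       target_gene = "target")
  expect_equal(unique(dd$rel_expr[dd$group == "high_iron"]), 3.6)
  # control-group geometric mean is exactly 1 even with noise
  cfgN <- sim_config(seed = 7, ct_noise_sd = 0.4)
  simN <- simulate_ct_table(tibble::tibble(group = c("control", "x"),
                                           fold_change = c(1, 2)),
                            cfgN, control_group = "control")
  ddN <- delta_delta_ct(simN, "control", reference_gene = "reference",
                        target_gene = "target")
  ctrl <- ddN$rel_expr[ddN$group == "control"]
  expect_equal(exp(mean(log(ctrl))), 1, tolerance = 1e-12)
})

test_that("delta-delta-Ct validates inputs and honors the efficiency base", {
  ct <- tibble::tibble(sample = c("a", "a", "b"), group = "g",
                       gene = c("t", "r", "t"), replicate = 1L, ct = 20)
  expect_error(delta_delta_ct(ct, "g", reference_gene = "r", target_gene = "t"),
               regexp = "b", class = "strainase_validation_error")
  expect_error(delta_delta_ct(ct, "nope", reference_gene = "r"),
               class = "strainase_param_error")
  # shifting every reference Ct by a constant rescales all folds equally
  ct2 <- tibble::tibble(
    sample = rep(c("c1", "t1"), each = 2),
    group = rep(c("control", "treated"), each = 2),
    gene = rep(c("t", "r"), 2), replicate = 1L, ct = c(22, 18, 20, 18))
  base <- delta_delta_ct(ct2, "control", reference_gene = "r", target_gene = "t")
  shifted <- dplyr::mutate(ct2, ct = ifelse(gene == "r", ct + 1, ct))
  dd2 <- delta_delta_ct(shifted, "control", reference_gene = "r",
                        target_gene = "t")
  expect_equal(dd2$rel_expr, base$rel_expr)  # common shift cancels in ddCt
  # efficiency 1.9 instead of 2
  dd19 <- delta_delta_ct(ct2, "control", reference_gene = "r",
                         target_gene = "t", efficiency = 1.9)
  expect_equal(dd19$rel_expr[dd19$group == "treated"], 1.9^2)
})

test_that("GTT AUC matches closed-form trapezoids and is partition-additive", {
  # constant curve: rectangle, and zero incremental area
  const <- tibble::tibble(animal = "m", time = c(0, 15, 30, 60, 120),
                          glucose = 100)
  a <- gtt_auc(const)
  expect_equal(a$auc_total, 12000)
  expect_equal(a$auc_incremental, 0)
  # worked example: 2250 + 3000 + 5250 + 7500
  curve <- tibble::tibble(animal = "m", time = c(0, 15, 30, 60, 120),
                          glucose = c(100, 200, 200, 150, 100))
  expect_equal(gtt_auc(curve)$auc_total, 18000)
  # inserting a collinear midpoint changes nothing
  mid <- tibble::tibble(animal = "m", time = 45, glucose = 175)
  curve2 <- dplyr::arrange(dplyr::bind_rows(curve, mid), time)
  expect_equal(gtt_auc(curve2)$auc_total, 18000)
  # additivity over a partition of the time axis
  left <- dplyr::filter(curve, time <= 30)
  right <- dplyr::filter(curve, time >= 30)
  expect_equal(gtt_auc(left)$auc_total + gtt_auc(right)$auc_total, 18000)
  expect_error(gtt_auc(tibble::tibble(animal = "m", time = c(0, 30, 15),
                                      glucose = 100)),
               class = "strainase_validation_error")
})

test_that("Grubbs screen flags a gross outlier and respects its guards", {
  gr <- grubbs_screen(c(1.0, 1.1, 0.9, 1.05, 8.0), alpha = 0.05)
  expect_equal(gr$outlier_indices, 5L)
  # independent oracle for the critical value at n = 5, alpha = .05
  t5 <- qt(1 - 0.05 / 10, df = 3)
  crit5 <- (4 / sqrt(5)) * sqrt(t5^2 / (3 + t5^2))
  expect_equal(gr$critical_value[1], crit5, tolerance = 1e-12)
  # degenerate inputs: no removal, marked not applicable
  expect_false(grubbs_screen(c(2, 2, 2, 2))$applicable)
  expect_false(grubbs_screen(c(1, 2))$applicable)
  expect_equal(grubbs_screen(c(2, 2, 2, 2))$outlier_indices, integer(0))
  # single-pass default removes at most one value even with two outliers
  two <- c(rnorm(10), 50, -60)
  expect_lte(length(grubbs_screen(two)$outlier_indices), 1L)
  expect_gte(length(grubbs_screen(two, max_outliers = 5)$outlier_indices), 2L)
})

test_that("Grubbs type-I error sits near alpha under the null", {
  withr::with_seed(91, {
    n <- 15; reps <- 4000
    x <- matrix(rnorm(n * reps), nrow = reps)
    g <- apply(x, 1, function(r) max(abs(r - mean(r))) / sd(r))
    crit <- strainase:::grubbs_critical(n, 0.05)
    rate <- mean(g > crit)
    # 3 * MC sd at p=.05, reps=4000 is ~0.010
    expect_lt(abs(rate - 0.05), 0.011)
  })
})

test_that("log10 policy transforms only on normality rejection", {
  withr::with_seed(19, {
    normal <- rnorm(50)
    ln <- exp(rnorm(50, sd = 1))
    res_n <- log10_policy(normal)
    expect_false(res_n$transformed)
    expect_identical(res_n$values, normal)
    res_l <- log10_policy(ln)
    expect_true(res_l$transformed)
    expect_equal(res_l$values, log10(ln))
    # a log-normal sample shifted below zero errors instead of silently offsetting
    expect_error(log10_policy(ln - min(ln) - 1), class = "strainase_param_error")
    # power: transform triggered in >= 90% of log-normal samples
    hits <- vapply(1:200, function(i) log10_policy(exp(rnorm(50)))$transformed,
                   logical(1))
    expect_gte(mean(hits), 0.9)
  })
})
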