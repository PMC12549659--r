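test_that("noiseless fixed-timing walks echo their parameters into truth", {
  cfg <- gait_sim_config(noise_sd = 0, stride_time_cycle_sd = 0,
                         stance_fraction_cycle_sd = 0,
                         stride_time_subject_sd = 0,
                         stance_fraction_subject_sd = 0,
                         speed_subject_sd = 0,
                         stance_asym_sd = 0,
                         stride_time_base = 1.0,
                         stance_fraction_base = 0.6)
  sim <- simulate_walk(cfg, "HC", seed = 1)
  cyc <- sim$truth$cycles
  expect_gt(nrow(cyc), 40)
  expect_equal(unique(round(cyc$stride_time, 9)), 1.0)
  expect_equal(unique(round(cyc$stance_time, 9)), 0.6)
  expect_equal(unique(round(cyc$swing_time, 9)), 0.4)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- gait_sim_config(seed = 9)
  a <- simulate_walk(cfg, "PD", stage = 2, seed = 5)
  b <- simulate_walk(cfg, "PD", stage = 2, seed = 5)
  expect_identical(a$recording$total_left, b$recording$total_left)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("truth events alternate HS < TO < next HS with feet offset by ~half a stride", {
  sim <- simulate_walk(gait_sim_config(seed = 3), "HC", seed = 3)
  for (foot in c("left", "right")) {
    ev <- sim$truth$events[[foot]]
    expect_true(all(ev$to > ev$hs))
    expect_true(all(ev$to[-nrow(ev)] < ev$hs[-1]))
  }
  l <- sim$truth$events$left$hs
  r <- sim$truth$events$right$hs
  interior <- l[l > min(r) & l < max(r)]
  offsets <- vapply(interior, function(t) min(abs(r - t)), numeric(1))
  stride <- mean(diff(l))
  expect_true(all(offsets > 0.25 * stride & offsets < 0.75 * stride))
})

test_that("default PD walks are slower than HC walks in the aggregate", {
  cfg <- gait_sim_config(n_per_class = 8, seed = 21)
  co <- simulate_cohort(cfg, "binary")
  stride_by_group <- vapply(names(co$truth), function(k) {
    mean(co$truth[[k]]$cycles$stride_time)
  }, numeric(1))
  grp <- co$demographics$group[match(sub("_\\d+$", "", names(co$truth)),
                                     co$demographics$subject_id)]
  expect_gt(mean(stride_by_group[grp == "PD"]),
            mean(stride_by_group[grp == "HC"]))
  # cadence = 120/stride, so the order reverses
  expect_lt(mean(120 / stride_by_group[grp == "PD"]),
            mean(120 / stride_by_group[grp == "HC"]))
})

test_that("cohort counting, imbalance knob, and severity labels behave", {
  co <- simulate_cohort(gait_sim_config(n_per_class = 5, seed = 2),
                        "binary")
  expect_equal(nrow(co$demographics), 10)
  expect_equal(sum(co$demographics$group == "PD"), 5)
  expect_length(co$records, 10)

  co2 <- simulate_cohort(
    gait_sim_config(n_per_class = c(`1` = 8, `2` = 4, `3` = 2), seed = 2),
    "severity")
  expect_equal(as.integer(table(co2$demographics$hoehn_yahr)[c("1", "2", "3")]),
               c(8L, 4L, 2L))
  counts <- tapply(
    vapply(co2$truth, function(t) nrow(t$cycles), numeric(1)),
    co2$demographics$hoehn_yahr[match(
      sub("_\\d+$", "", names(co2$truth)), co2$demographics$subject_id)],
    sum)
  # cycle counts follow the subject imbalance approximately (4:2:1)
  expect_gt(counts[["1"]] / counts[["2"]], 1.5)
  expect_gt(counts[["2"]] / counts[["3"]], 1.5)

  expect_error(simulate_cohort(gait_sim_config(n_per_class = 1), "binary"),
               class = "crisp_config_error")
})

test_that("a null severity gradient removes between-stage separation", {
  co <- simulate_cohort(gait_sim_config(n_per_class = 6, seed = 8,
                                        severity_gradient = 0),
                        "severity")
  stage <- co$demographics$hoehn_yahr[match(
    sub("_\\d+$", "", names(co$truth)), co$demographics$subject_id)]
  # subject-level means: cycles within a subject are correlated, so the
  # null comparison must be between subjects
  subj_mean <- vapply(co$truth, function(t) mean(t$cycles$stride_time),
                      numeric(1))
  p <- t.test(subj_mean[stage == 1], subj_mean[stage == 3])$p.value
  expect_gt(p, 0.01)
})

test_that("a larger severity gradient widens stage separation of stride time", {
  sep <- vapply(c(0.5, 2), function(g) {
    co <- simulate_cohort(gait_sim_config(n_per_class = 6, seed = 8,
                                          severity_gradient = g),
                          "severity")
    stage <- co$demographics$hoehn_yahr[match(
      sub("_\\d+$", "", names(co$truth)), co$demographics$subject_id)]
    m <- tapply(vapply(co$truth, function(t) mean(t$cycles$stride_time),
                       numeric(1)), stage, mean)
    m[["3"]] - m[["1"]]
  }, numeric(1))
  expect_gt(sep[2], sep[1])
})

test_that("invalid simulator configurations are rejected", {
  expect_error(gait_sim_config(stance_fraction_base = 1.2),
               class = "crisp_config_error")
  expect_error(gait_sim_config(walk_duration = 30),
               class = "crisp_config_error")
})
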