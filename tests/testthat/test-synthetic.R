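test_that("a fixed seed reproduces the whole scenario exactly", {
  cfg <- scenario_config(duration_s = 200)
  a <- generate_scenario(cfg, seed = 77)
  b <- generate_scenario(cfg, seed = 77)
  expect_identical(a$microclimate, b$microclimate)
  expect_identical(a$states, b$states)
  expect_identical(a$detections, b$detections)
  c <- generate_scenario(cfg, seed = 78)
  expect_false(identical(a$detections, c$detections))
})

test_that("synthetic microclimate hits the regime means with a mid-afternoon peak", {
  flat <- climate_params("cooled")
  flat$t_amp <- 0; flat$t_sd <- 0
  const <- generate_microclimate("cooled", seed = 1, params = flat)
  expect_true(all(const$t_air == 22.59))

  cooled <- generate_microclimate("cooled", n_days = 92, seed = 2)
  expect_lt(abs(mean(cooled$t_air) - 22.59), 0.3)
  expect_lt(abs(mean(cooled$rh) - 81.99), 1.5)
  uncooled <- generate_microclimate("uncooled", n_days = 92, seed = 2)
  expect_lt(abs(mean(uncooled$t_air) - 30.43), 0.3)
  expect_lt(abs(mean(uncooled$rh) - 54.62), 1.5)
  expect_true(all(cooled$rh >= 0 & cooled$rh <= 100))
  # humidity in anti-phase with temperature
  expect_lt(cor(cooled$t_air, cooled$rh), -0.8)
  # warmest record of every day falls in the afternoon
  day <- as.Date(cooled$timestamp)
  hour <- as.numeric(format(cooled$timestamp, "%H"))
  peak <- tapply(seq_len(nrow(cooled)), day,
                 function(i) hour[i[which.max(cooled$t_air[i])]])
  expect_true(all(peak >= 12 & peak <= 16))
  expect_error(generate_microclimate("cooled", n_days = 0), "n_days")
})

test_that("synthetic BGHI reproduces the observed stall means", {
  for (case in list(list(r = "cooled", m = 71.45),
                    list(r = "uncooled", m = 79.82))) {
    micro <- generate_microclimate(case$r, n_days = 30, seed = 4)
    idx <- bghi(micro$t_globe, dew_point(micro$t_air, micro$rh))
    expect_lt(abs(mean(idx) - case$m), 0.4)
  }
})

test_that("physiology generator exercises both comfort classes", {
  cooled <- generate_microclimate("cooled", seed = 6)
  pc <- generate_physiology(cooled, seed = 6)
  st <- classify_physiology(pc$rt, pc$rr)
  expect_gt(mean(st == "normal"), 0.5)
  uncooled <- generate_microclimate("uncooled", seed = 6)
  pu <- generate_physiology(uncooled, seed = 6)
  hr <- as.numeric(format(pu$timestamp, "%H"))
  expect_true(all(classify_physiology(pu$rt[hr == 12], pu$rr[hr == 12]) ==
                    "heat_stress"))
})

test_that("behavior chains converge to the calibrated stationary budgets", {
  pi_c <- behavior_stationary(transition_matrix_comfort())
  expect_equal(unname(pi_c),
               c(.680, .200, .115, .004) / sum(c(.680, .200, .115, .004)),
               tolerance = 1e-4)
  pi_h <- behavior_stationary(transition_matrix_heat())
  expect_equal(unname(pi_h), c(.697, .168, .123, .012), tolerance = 1e-4)

  # three chains over three days: bout durations (minutes-long lying
  # bouts) leave ~1 pp of sampling noise at this horizon
  st <- generate_behavior_states(3 * 86400, n_pigs = 3, seed = 8)
  emp <- prop.table(table(factor(st, levels = behaviors())))
  expect_true(all(abs(emp - pi_c) < 0.02))  # within 2 percentage points

  absorbing <- diag(4)
  dimnames(absorbing) <- list(behaviors(), behaviors())
  st2 <- generate_behavior_states(100, P = absorbing, n_pigs = 2, seed = 8,
                                  init = c(1, 0, 0, 0))
  expect_true(all(st2 == "lying"))

  expect_identical(generate_behavior_states(500, seed = 9),
                   generate_behavior_states(500, seed = 9))
  bad <- transition_matrix_comfort(); bad[1, 1] <- 0.5
  expect_error(generate_behavior_states(10, P = bad), "stochastic")
})

test_that("eating states are confined to feeding windows", {
  sched <- feeding_schedule(start = 100, end = 200)
  st <- generate_behavior_states(400, n_pigs = 3, seed = 10,
                                 schedule = sched, t0 = 0)
  t <- seq_len(400) - 1
  outside <- st[t < 100 | t >= 200, ]
  expect_false(any(outside == "eating"))
})

test_that("a noiseless detector channel is the identity", {
  cfg <- scenario_config(duration_s = 300, noise = zero_noise())
  sc <- generate_scenario(cfg, seed = 11)
  expect_equal(nrow(sc$detections), nrow(sc$truth))
  expect_true(all(sc$detections$conf == 1))
  expect_equal(sc$detections$x0, sc$truth$x0)
  expect_equal(sc$truth_budget_hours, sc$truth_pig_hours)
})

test_that("miss probability alone degrades recall binomially", {
  cfg <- scenario_config(duration_s = 2000,
                         noise = detector_noise(p_miss = 0.05, jitter_sd = 0,
                                                p_fp = 0, conf_shapes = NULL))
  sc <- generate_scenario(cfg, seed = 12)
  m <- match_detections(sc$detections, sc$truth)
  r <- with(list(p = m$per_class), sum(p$tp) / (sum(p$tp) + sum(p$fn)))
  n <- nrow(sc$truth)
  expect_lt(abs(r - 0.95), 4 * sqrt(0.05 * 0.95 / n))
})

test_that("false positives at the unused feeder inflate standing but never eating", {
  cfg <- scenario_config(duration_s = 1000,
                         noise = detector_noise(p_miss = 0, jitter_sd = 0,
                                                p_fp = 0.3, conf_shapes = NULL),
                         schedule = feeding_schedule(numeric(0), numeric(0)))
  sc <- generate_scenario(cfg, seed = 13)
  rep <- run_pipeline(sc, evaluate = FALSE)
  truth_standing <- sum(sc$truth$behavior != "lying")
  expect_gt(rep$totals[["standing"]], truth_standing * 0.9)
  expect_gt(nrow(sc$detections), nrow(sc$truth))
  expect_equal(rep$totals[["eating"]], 0)
})

test_that("heat stress shifts the expected budget: less eating time detected, more drinking", {
  # expectation-level check: stationary fraction x detectability; single
  # 16-h realizations cannot resolve the eating gap (run-to-run sd of
  # eating hours is several times the expected difference)
  pi_c <- behavior_stationary(transition_matrix_comfort())
  pi_h <- behavior_stationary(transition_matrix_heat())
  keep_c <- 1 - scenario_config("cooled")$noise$p_miss
  keep_h <- 1 - scenario_config("uncooled")$noise$p_miss
  expect_lt(pi_h[["eating"]] * keep_h, pi_c[["eating"]] * keep_c)
  expect_gt(pi_h[["drinking"]] * keep_h, pi_c[["drinking"]] * keep_c)
  # drinking is resolvable end-to-end over a full 12-h observation day
  cg <- run_pipeline(generate_scenario(
    scenario_config("cooled", duration_s = 43200), seed = 14),
    evaluate = FALSE)$budget
  ug <- run_pipeline(generate_scenario(
    scenario_config("uncooled", duration_s = 43200), seed = 15),
    evaluate = FALSE)$budget
  expect_gt(ug$hours[ug$behavior == "drinking"],
            cg$hours[cg$behavior == "drinking"])
})
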