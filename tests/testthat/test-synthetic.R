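test_that("trace scenarios validate their physical constraints", {
  expect_s3_class(trace_scenario(0.5), "trace_scenario")
  expect_error(trace_scenario(0.5, sampling_rate = 15, shedding_frequency = 10),
               "twice the shedding frequency")
  expect_error(trace_scenario(-1), "mean_velocity")
  expect_error(trace_scenario(0.5, turbulence_sd = -1), "turbulence_sd")
  expect_error(trace_scenario(0.5, duration = 0), "duration")
  expect_error(generate_llp_trace(list()), "trace_scenario")
})

test_that("noise-free traces obey the dynamic-pressure closed form", {
  sc <- trace_scenario(mean_velocity = 0.5, turbulence_sd = 0,
                       vortex_amplitude = 0, duration = 1, seed = 1)
  tr <- generate_llp_trace(sc)
  expect_equal(mean_front_pressure(tr), 125)  # 0.5 * 1000 * 0.5^2
  # lateral channels identically zero; asymmetry gets no pair contribution
  expect_true(all(tr$pressure[, 3:6] == 0))
  expect_equal(mean_pressure_asymmetry(tr, "pairmean")$raw, 0)
  # absolute channel is the hydrostatic constant
  expect_equal(unique(tr$p_abs), 1000 * 9.81 * sc$depth)
})

test_that("the in-phase front oscillation never leaks into asymmetry", {
  sc <- trace_scenario(mean_velocity = 0.3, turbulence_sd = 0,
                       vortex_amplitude = 5, shedding_frequency = 8,
                       duration = 2, seed = 4)
  tr <- generate_llp_trace(sc)
  # front pair difference is exactly zero; lateral pairs carry 2A sin
  expect_equal(tr$pressure[, 1], tr$pressure[, 2])
  expect_equal(tr$pressure[, 3], -tr$pressure[, 4])
  got <- mean_pressure_asymmetry(tr, "pairmean")$raw
  expect_equal(got, 2 * (2 * 5^2) / 3, tolerance = 0.01)  # both lateral pairs
})

test_that("seeded generation is bit-reproducible and leaves the RNG alone", {
  sc <- trace_scenario(0.4, turbulence_sd = 3, vortex_amplitude = 2, seed = 42,
                       duration = 2)
  t1 <- generate_llp_trace(sc)
  set.seed(777)
  expected_next <- rnorm(1)
  set.seed(777)
  t2 <- generate_llp_trace(sc)
  expect_identical(t1$pressure, t2$pressure)
  expect_identical(t1$p_abs, t2$p_abs)
  expect_equal(rnorm(1), expected_next)  # global RNG stream undisturbed
})

test_that("mean front pressure recovers the dynamic pressure relation", {
  v <- seq(0.1, 1, by = 0.1)
  q <- 0.5 * 1000 * v^2
  p12 <- vapply(seq_along(v), function(i) {
    sc <- trace_scenario(v[i], turbulence_sd = 5, duration = 20,
                         seed = 100 + i)
    mean_front_pressure(generate_llp_trace(sc))
  }, numeric(1))
  slope <- coef(lm(p12 ~ q))[["q"]]
  expect_gt(slope, 0.98)
  expect_lt(slope, 1.02)
})

test_that("asymmetry increases strictly along a vortex-amplitude ladder", {
  amps <- c(0.5, 1, 2, 4, 8)
  asym <- vapply(amps, function(a) {
    sc <- trace_scenario(0.3, turbulence_sd = 2, vortex_amplitude = a,
                         duration = 5, seed = 9)
    mean_pressure_asymmetry(generate_llp_trace(sc), "pairmean")$raw
  }, numeric(1))
  expect_true(all(diff(asym) > 0))
})

test_that("field scenarios encode the expected spatial structure", {
  layout0 <- build_grid("R0", n_rows = 6, n_cols = 3)
  tr0 <- generate_field_scenario(layout0, "R0HP", seed = 5, duration = 2)
  m0 <- summarize_field(tr0, layout0)
  # homogeneous field: between-cell spread is noise-level only
  expect_lt(sd(m0$p_front_mean) / mean(m0$p_front_mean), 0.01)

  layout1 <- build_grid("R1", n_rows = 15, n_cols = 3)
  trHP <- generate_field_scenario(layout1, "R1HP", seed = 5, duration = 2)
  trBF <- generate_field_scenario(layout1, "R1BF", seed = 5, duration = 2)
  mHP <- summarize_field(trHP, layout1)
  mBF <- summarize_field(trBF, layout1)

  # wake cells are calmer than the rest of the flume
  wake <- mBF$area_class == "structure_wake"
  expect_lt(min(mBF$p_front_mean[wake]), mean(mBF$p_front_mean[!wake]))
  # hydropeaking raises front pressure in every cell
  expect_true(all(mHP$p_front_mean > mBF$p_front_mean))
  # wake vortex shedding raises asymmetry above the open flume
  expect_gt(min(mBF$p_asym[wake]), max(mBF$p_asym[!wake]))

  expect_error(generate_field_scenario(layout1, "R9HP", seed = 1),
               "unknown treatment")
  expect_error(generate_field_scenario(layout1, "R2HP", seed = 1),
               "does not match")
})

test_that("behaviour counts follow the effect spec and its absences", {
  design <- experiment_design()
  eff <- effect_spec()
  counts <- generate_behaviour_counts(design, eff, seed = 21)
  expect_equal(nrow(counts), 10 * 5 * 5)
  sets <- behaviour_metric_sets()
  absent <- counts$treatment == "R0HP" & counts$metric %in% sets$structure
  expect_true(all(is.na(counts$count[absent])))
  expect_true(all(!is.na(counts$count[!absent])))
  expect_true(all(counts$count[!absent] >= 0))

  # zero means give zero counts
  eff0 <- effect_spec(behaviour_means = eff$behaviour_means * 0)
  c0 <- generate_behaviour_counts(design, eff0, seed = 2)
  expect_true(all(c0$count[!is.na(c0$count)] == 0))

  # reproducibility
  expect_identical(counts, generate_behaviour_counts(design, eff, seed = 21))
})

test_that("infinite dispersion collapses to Poisson", {
  design <- experiment_design(replicates = 2000L)  # 10k draws per cell
  means <- default_behaviour_means()
  eff <- effect_spec(behaviour_means = means, dispersion = Inf)
  counts <- generate_behaviour_counts(design, eff, seed = 8)
  x <- counts$count[counts$metric == "Isprint" & counts$treatment == "R0HP"]
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
  # and the default dispersion is visibly overdispersed
  eff5 <- effect_spec(behaviour_means = means, dispersion = 5)
  c5 <- generate_behaviour_counts(design, eff5, seed = 8)
  x5 <- c5$count[c5$metric == "Isprint" & c5$treatment == "R0HP"]
  expect_gt(var(x5) / mean(x5), 2)
})

test_that("physiology samples hit their calibration and degenerate limits", {
  design <- experiment_design()
  eff <- effect_spec()
  phys <- generate_physiology(design, eff, seed = 31)
  expect_equal(nrow(phys), 125)
  expect_false(anyDuplicated(phys$fish_id) > 0)
  expect_true(all(phys$glucose > 0 & phys$lactate > 0))

  # R2HP lactate calibrated at 5.06 +/- 0.49 mM: sample mean within 3 SE
  r2 <- phys$lactate[phys$treatment == "R2HP"]
  expect_length(r2, 25)
  expect_lt(abs(mean(r2) - 5.06), 3 * 0.49 / sqrt(25))

  # vanishing SD pins every fish at the treatment mean
  tiny <- default_physiology_effects()
  tiny$glucose_sd[] <- 1e-9; tiny$lactate_sd[] <- 1e-9
  p0 <- generate_physiology(design, effect_spec(physiology = tiny), seed = 1)
  expect_equal(p0$lactate[p0$treatment == "R2HP"], rep(5.06, 25),
               tolerance = 1e-6)

  expect_identical(phys, generate_physiology(design, eff, seed = 31))
})

test_that("null physiology keeps the downstream test at its nominal level", {
  design <- experiment_design()
  flat <- default_physiology_effects()
  flat$glucose_mean[] <- 45; flat$lactate_mean[] <- 4
  flat$glucose_sd[] <- 8; flat$lactate_sd[] <- 0.8
  eff <- effect_spec(physiology = flat)
  reject <- 0
  nsim <- 500
  for (s in seq_len(nsim)) {
    phys <- generate_physiology(design, eff, seed = 5000 + s)
    if (kruskal_wallis(phys$glucose, phys$treatment)$p_value < 0.05)
      reject <- reject + 1
  }
  expect_gt(reject / nsim, 0.03)
  expect_lt(reject / nsim, 0.07)
})

test_that("an injected two-fold count shift is detectable with power > 0.5", {
  design <- experiment_design()
  means <- default_behaviour_means()
  # one metric, base mean for BF treatments, doubled under HP
  means["Isprint", ] <- c(R0HP = 20, R1HP = 20, R1BF = 10, R2HP = 20, R2BF = 10)
  eff <- effect_spec(behaviour_means = means, dispersion = 5)
  hits <- 0
  nsim <- 500
  for (s in seq_len(nsim)) {
    counts <- generate_behaviour_counts(design, eff, seed = 9000 + s)
    x <- counts[counts$metric == "Isprint", ]
    if (kruskal_wallis(x$count, x$treatment)$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / nsim, 0.5)
})
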