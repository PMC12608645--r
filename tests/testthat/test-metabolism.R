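params <- metabolic_parameters()

test_that("parameter table loads strictly and fails fast on mismatch", {
  expect_s3_class(params, "msx_params")
  expect_true(all(is.finite(params)))
  tmp <- tempfile(fileext = ".csv")
  tab <- read.csv(system.file("extdata", "metabolic_parameters.csv",
                              package = "metaspheroid"))
  write.csv(tab[-3, ], tmp, row.names = FALSE)
  expect_error(metabolic_parameters(tmp), "missing")
  tab2 <- rbind(tab, data.frame(reaction = "rX", name = "vmax_bogus",
                                value = 1, units = "", note = ""))
  write.csv(tab2, tmp, row.names = FALSE)
  expect_error(metabolic_parameters(tmp), "unknown")
})

test_that("init_state is deterministic, complete and non-negative", {
  s1 <- init_state(gamma = 1.3, rng_seed = 7)
  s2 <- init_state(gamma = 1.3, rng_seed = 7)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_equal(attr(s1, "gamma"), 1.3)
  expect_length(s1, 53)
  expect_true(all(s1 >= 0))
  expect_true(all(c("glucose_i", "pyruvate", "lactate_i", "proton_i", "atp",
                    "LDH", "PDH", "HIF1A") %in% names(s1)))
  expect_error(init_state(gamma = -1))
})

test_that("reaction rates respect substrate limitation and directionality", {
  s <- init_state()
  # zero oxygen silences the oxygen-dependent mitochondrial rates
  r0 <- reaction_rates(s, local_environment(oxygen_mM = 0))
  expect_identical(unname(r0[c("r22", "r24")]), c(0, 0))
  # no pyruvate + internal lactate drives LDH backward (lactate -> pyruvate)
  s2 <- s
  s2["pyruvate"] <- 0
  s2["lactate_i"] <- 5
  r2 <- reaction_rates(s2, basal_env())
  expect_lt(r2[["r12"]], 0)
  # at the basal state in a rich aerobic environment respiration dominates
  rb <- reaction_rates(s, basal_env())
  expect_gt(rb[["r18"]], rb[["r12"]])
  expect_gte(rb[["r18"]], 0)
})

test_that("MCT symport follows the lactate-proton product gradient", {
  # equilibrium of the product driving force
  expect_equal(mct_flux(2, 1e-4, 4, 5e-5), 0)
  # downhill export at equal pH
  expect_gt(mct_flux(10, 1e-4, 0.1, 1e-4), 0)
  # import from an acidic, lactate-rich exterior
  expect_lt(mct_flux(0.5, 6e-5, 10, 1e-3), 0)
  # antisymmetric under swapping the compartments
  f1 <- mct_flux(3, 2e-4, 1, 1e-4)
  f2 <- mct_flux(1, 1e-4, 3, 2e-4)
  expect_equal(f1, -f2)
})

test_that("pH modulation is anchored, monotone and bounded", {
  expect_equal(ph_inhibition_factor(7.4), 1)
  expect_equal(ph_inhibition_factor(8.5), 1)  # no boost above physiological
  grid <- seq(3.2, 8.8, by = 0.1)
  f <- vapply(grid, ph_inhibition_factor, numeric(1))
  expect_true(all(diff(f) >= -1e-12))
  expect_true(all(f >= 0 & f <= 1))
  expect_lte(ph_inhibition_factor(5.3), ph_inhibition_factor(6.0))
  expect_equal(glycolysis_ph_modulation(2, 7.4, 7.4), 2)
  expect_error(glycolysis_ph_modulation(1, 2.5, 7.4), "range")
})

test_that("gene regulation is a fixed point at steady state and lactate
           induces HIF-1a and LDH", {
  s <- init_state()
  # noise-free stepping at the basal environment stays at the fixed point
  st <- s
  for (k in 1:50) st <- gene_regulation_step(st, basal_env(), dt_s = 1.2)
  genes <- c("HIF1A", "LDH", "PDH", "PDK", "GLUT", "MCT", "HK", "PFK",
             "MYC", "AMPK")
  expect_equal(as.numeric(st[genes]), as.numeric(s[genes]),
               tolerance = 1e-3)
  # raising extracellular lactate at high oxygen raises HIF1A and LDH
  env_lac <- local_environment(oxygen_mmHg = 38, glucose_mM = 6,
                               lactate_mM = 10, pH = 7.4)
  res <- simulate_cell(s, env_lac, hours = 48)
  expect_gt(res$state[["HIF1A"]], s[["HIF1A"]] * 1.2)
  expect_gt(res$state[["LDH"]], s[["LDH"]] * 1.2)
  # same seed, same trajectory (with noise on)
  a <- step_metabolism(s, basal_env(), noise_amp = 0.05, seed = 11,
                       cell_id = 3, step_index = 9)
  b <- step_metabolism(s, basal_env(), noise_amp = 0.05, seed = 11,
                       cell_id = 3, step_index = 9)
  expect_identical(as.numeric(a$state), as.numeric(b$state))
  # different cell id, different noise realization
  c <- step_metabolism(s, basal_env(), noise_amp = 0.05, seed = 11,
                       cell_id = 4, step_index = 9)
  expect_false(identical(as.numeric(a$state), as.numeric(c$state)))
})

test_that("interval-average fluxes reproduce the published flux regimes", {
  s <- init_state()
  # anoxia with glucose: fermentation with lactate export
  res <- simulate_cell(s, hypoxic_lactate_env(), hours = 24)
  n <- length(res$time_h)
  expect_gt(res$r12[n], 0)
  expect_gt(res$r21[n], 0)
  # oxygen without glucose, ample lactate: import feeds respiration
  env <- local_environment(oxygen_mmHg = 38, glucose_mM = 0, lactate_mM = 5,
                           pH = 7.4)
  res2 <- simulate_cell(s, env, hours = 24)
  n2 <- length(res2$time_h)
  expect_lt(res2$r21[n2], 0)
  expect_gt(res2$r18[n2], 0)
})

test_that("closed-cell carbon bookkeeping: glycolytic carbon leaves only
           through PDH", {
  # all transport capacities zero: total glucose-equivalent carbon in
  # {stores, glycolytic intermediates, pyruvate, lactate} declines only
  # via the PDH drain (r18), to RK4 accuracy
  p2 <- params
  p2[c("vmax_glut", "vmax_mct")] <- 0
  s <- init_state()
  env <- basal_env()
  # glucose-equivalents: hexoses and glycogen count 1, trioses 1/2
  hexose <- c("glucose_i", "g6p", "f6p", "f16bp", "glycogen")
  triose <- c("dhap", "gap", "bpg13", "pg3", "pg2", "pep", "pyruvate",
              "lactate_i")
  carbon <- function(x) sum(x[hexose]) + 0.5 * sum(x[triose])
  st <- as.numeric(s); names(st) <- names(s)
  drained <- 0
  for (k in 1:200) {
    out <- step_metabolism(st, env, dt_s = 1.2, params = p2)
    drained <- drained + 0.5 * out$fluxes[["r18"]] * 1.2 / 60
    st <- out$state
  }
  expect_equal(carbon(st), carbon(s) - drained, tolerance = 1e-6)
})

test_that("acid exposure inhibits steady-state glycolysis", {
  s <- init_state()
  env74 <- basal_env()
  env60 <- local_environment(oxygen_mmHg = 38, glucose_mM = 6,
                             lactate_mM = 0.1, pH = 6.0)
  r74 <- simulate_cell(s, env74, hours = 36)
  r60 <- simulate_cell(s, env60, hours = 36)
  n <- length(r74$time_h)
  expect_lt(r60$glucose_uptake[length(r60$time_h)], r74$glucose_uptake[n])
})

test_that("positivity is preserved over many random small steps", {
  s <- init_state()
  envs <- list(basal_env(), hypoxic_lactate_env(),
               local_environment(oxygen_mmHg = 2, glucose_mM = 0.1,
                                 lactate_mM = 0.1, pH = 6.5))
  for (e in seq_along(envs)) {
    st <- s
    for (k in 1:2000) {
      out <- step_metabolism(st, envs[[e]], dt_s = 1.2, noise_amp = 0.05,
                             seed = 5, cell_id = e, step_index = k)
      st <- out$state
    }
    expect_true(all(st >= 0))
    expect_true(all(is.finite(st)))
  }
})

test_that("steady states separate into oxidative and glycolytic basins", {
  s <- init_state()
  coords <- t(vapply(0:7, function(i) {
    f <- i / 7
    env <- local_environment(oxygen_mM = o2_mmHg_to_mM(38) * (1 - f) +
                               o2_mmHg_to_mM(0.5) * f,
                             glucose_mM = 6,
                             lactate_mM = 0.1 * (1 - f) + 8 * f, pH = 7.4)
    res <- simulate_cell(s, env, hours = 40)
    c(res$state[["LDH"]], res$state[["PDH"]])
  }, numeric(2)))
  km <- kmeans(coords, centers = 2, nstart = 5)
  lo <- which.min(km$centers[, 1])
  hi <- 3 - lo
  # oxidative basin: low LDH / high PDH; glycolytic: high LDH / low PDH
  expect_gt(km$centers[hi, 1], km$centers[lo, 1] + 1.5)
  expect_lt(km$centers[hi, 2], km$centers[lo, 2] - 0.3)
})
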