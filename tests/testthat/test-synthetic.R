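test_that("toy molecules are deterministic and satisfy all invariants", {
  m1 <- gen_toy_molecule(123)
  m2 <- gen_toy_molecule(123)
  expect_identical(m1, m2)
  for (seed in c(1, 2, 3, 4, 5)) {
    m <- gen_toy_molecule(seed)
    expect_silent(validate_molecule(m))
    d <- dist(m$coords)
    expect_gte(min(d), 0.5)
    ts <- attr(m, "torsion")
    expect_equal(measure_dihedral(m, ts$a, ts$b, ts$c, ts$d), 180,
                 tolerance = 1e-6)
  }
  expect_error(gen_toy_molecule(1, n_heavy = 8), "at least 12")
  expect_error(gen_toy_molecule(1, elements = c("C", "Zz")), "unsupported")
})

test_that("requested elements appear, so element-pair descriptors fire", {
  m <- gen_toy_molecule(9, elements = c("C", "S", "Cl"))
  expect_true(all(c("S", "Cl") %in% m$elements))
  expect_gt(geom_pair_sum(m, "S", "Cl"), 0)
})

test_that("isomer series mirror the 29-species study design", {
  series <- gen_isomer_series(77)
  expect_length(series, 29L)
  tags <- table(vapply(series, function(m) m$isomer, ""))
  expect_equal(unname(tags[["trans"]]), 15L)
  expect_equal(unname(tags[["cis"]]), 14L)
  ids4 <- vapply(series, function(m) m$id, "") == "4"
  expect_equal(vapply(series[ids4], function(m) m$isomer, ""), "trans")
  expect_error(gen_isomer_series(1, n_compounds = 3, drop_cis_for = 9),
               "out of range")
})

test_that("each isomer pair shares topology but not geometry", {
  series <- gen_isomer_series(88, n_compounds = 4, drop_cis_for = NULL)
  for (i in seq(1, 8, 2)) {
    tr <- series[[i]]; ci <- series[[i + 1]]
    expect_identical(tr$id, ci$id)
    expect_identical(topological_distances(tr), topological_distances(ci))
    expect_identical(cats2d(tr), cats2d(ci))
    expect_gt(max(abs(geometric_distances(tr) - geometric_distances(ci))),
              1e-3)
  }
})

test_that("noiseless simulated log kw is recovered exactly by OLS", {
  series <- gen_isomer_series(11, n_compounds = 4, drop_cis_for = NULL)
  tab <- compute_descriptor_table(series)
  beta <- c(0.05, -0.02)
  names(beta) <- c("H3e", "G(S..Cl)")
  sim <- simulate_logkw(tab, beta, sigma = 0, seed = 5)
  m <- fit_ols(tab[, names(beta)], sim$logkw)
  expect_equal(unname(m$coefficients), unname(beta), tolerance = 1e-10)
  expect_equal(m$intercept, 3.5, tolerance = 1e-10)
  sim2 <- simulate_logkw(tab, beta, sigma = 0.036, seed = 5)
  sim3 <- simulate_logkw(tab, beta, sigma = 0.036, seed = 5)
  expect_identical(sim2$logkw, sim3$logkw)
  expect_error(simulate_logkw(tab, c(ZZ = 1), seed = 1), "not in")
})

test_that("the fitted residual scale tracks the simulated noise", {
  series <- gen_isomer_series(13)
  tab <- compute_descriptor_table(series)
  beta <- setNames(c(0.05, -0.02, 0.03, 0.02) /
                     vapply(c("H2e", "H5e", "R3e+", "G(S..Cl)"),
                            function(cn) sd(tab[[cn]]), 0),
                   c("H2e", "H5e", "R3e+", "G(S..Cl)"))
  inside <- 0L
  for (s in 1:100) {
    sim <- simulate_logkw(tab, beta, sigma = 0.036, seed = 1000 + s)
    m <- fit_ols(tab[, names(beta)], sim$logkw)
    inside <- inside + (m$stats$s >= 0.5 * 0.036 && m$stats$s <= 1.5 * 0.036)
  }
  expect_gte(inside, 90L)
})

test_that("retention simulation inverts exactly without noise", {
  inst <- instrument_params(2.2, 3.7)
  params <- list(`1-trans` = lss_params(3.60, 4.64),
                 `1-cis` = lss_params(3.52, 5.00),
                 `2-trans` = lss_params(3.39, 4.04))
  sim <- simulate_retention_table(params, inst = inst, tr_noise_sd = 0,
                                  seed = 3)
  expect_equal(sim$table$compound, c("1", "1", "2"))
  expect_equal(sim$table$isomer, c("trans", "cis", "trans"))
  fit <- build_retention_table(sim$table, inst)
  expect_equal(fit$logkw, vapply(params, `[[`, 0, "logkw"),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(fit$s_value, vapply(params, `[[`, 0, "S"),
               tolerance = 1e-4, ignore_attr = TRUE)
  sim2 <- simulate_retention_table(params, inst = inst, tr_noise_sd = 0.05,
                                   seed = 3)
  sim3 <- simulate_retention_table(params, inst = inst, tr_noise_sd = 0.05,
                                   seed = 3)
  expect_identical(sim2$table, sim3$table)
})

test_that("retention-time noise propagates into log kw as the LSS
          sensitivities predict", {
  # the two-run fit interpolates the (tr30, tr60) pair exactly, so
  # Gaussian retention noise maps to log kw errors with SD
  # tr_noise_sd * ||d logkw / d(tr30, tr60)||; check the simulated
  # errors against that first-order propagation (2 sigma ~ 95% nominal)
  inst <- instrument_params(2.2, 3.7)
  g30 <- gradient_program(30); g60 <- gradient_program(60)
  t2 <- load_fixture("table2")
  params <- lapply(seq_len(nrow(t2)), function(r)
    lss_params(t2$logkw[r], t2$s_value[r]))
  names(params) <- t2$species
  base <- simulate_retention_table(params, inst = inst, tr_noise_sd = 0,
                                   seed = 1)$table
  eps <- 0.01
  sd_pred <- vapply(seq_len(nrow(base)), function(r) {
    j30 <- (fit_lss_two_runs(base$tr_30[r] + eps, g30, base$tr_60[r], g60,
                             inst)$logkw - t2$logkw[r]) / eps
    j60 <- (fit_lss_two_runs(base$tr_30[r], g30, base$tr_60[r] + eps, g60,
                             inst)$logkw - t2$logkw[r]) / eps
    0.05 * sqrt(j30^2 + j60^2)
  }, 0)
  ok <- 0L; total <- 0L
  for (s in 1:3) {
    sim <- simulate_retention_table(params, inst = inst,
                                    tr_noise_sd = 0.05, seed = s)
    fit <- build_retention_table(sim$table, inst)
    ok <- ok + sum(abs(fit$logkw - t2$logkw) <= 2 * sd_pred, na.rm = TRUE)
    total <- total + nrow(t2)
  }
  expect_gte(ok / total, 0.9)
})

test_that("ground truth sidecars serialize losslessly enough to recompute", {
  series <- gen_isomer_series(17, n_compounds = 3, drop_cis_for = NULL)
  tab <- compute_descriptor_table(series)
  beta <- setNames(0.05, "H4e")
  sim <- simulate_logkw(tab, beta, sigma = 0.01, seed = 9)
  path <- tempfile(fileext = ".json")
  write_ground_truth(sim$ground_truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$beta[["H4e"]], unname(beta), tolerance = 1e-12)
  expect_equal(back$sigma, 0.01)
  expect_equal(back$seed, 9)
})
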