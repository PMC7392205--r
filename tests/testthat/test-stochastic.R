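test_that("the zero-noise Euler path converges to the ODE solution as the
           step shrinks", {
  ode <- integrate_ode(system_state(1, 1, 0, 0), par_quiet, 2e6, t_max = 48)
  errs <- vapply(c(0.05, 0.01), function(dt) {
    sde <- simulate_sde(system_state(1, 1, 0, 0), par_quiet, 2e6,
                        t_max = 48, dt = dt, seed = 1,
                        record_every = round(1 / dt))
    max(abs(sde$states - ode$states) / (1 + abs(ode$states)))
  }, numeric(1))
  expect_lt(errs[2], 0.02)        # dt = 0.01 h tracks the ODE closely
  expect_lt(errs[2], errs[1])     # refinement reduces the error
})

test_that("identical seeds give identical paths and ensembles", {
  a <- simulate_sde(system_state(1, 1, 0, 0), par_default, 2e6,
                    t_max = 24, seed = 77)
  b <- simulate_sde(system_state(1, 1, 0, 0), par_default, 2e6,
                    t_max = 24, seed = 77)
  expect_identical(a$states, b$states)
  c <- simulate_sde(system_state(1, 1, 0, 0), par_default, 2e6,
                    t_max = 24, seed = 78)
  expect_false(identical(a$states, c$states))
  e1 <- run_ensemble(5, system_state(1, 1, 0, 0), par_default, 2e6,
                     t_max = 12, master_seed = 5)
  e2 <- run_ensemble(5, system_state(1, 1, 0, 0), par_default, 2e6,
                     t_max = 12, master_seed = 5)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$seeds, e2$seeds)
  expect_equal(length(unique(e1$seeds)), 5)
  ## a one-path ensemble reduces to simulate_sde under the derived seed
  single <- run_ensemble(1, system_state(1, 1, 0, 0), par_default, 2e6,
                         t_max = 12, master_seed = 5)
  direct <- simulate_sde(system_state(1, 1, 0, 0), par_default, 2e6,
                         t_max = 12, seed = single$seeds[1])
  expect_identical(single$states[, , 1], direct$states)
})

test_that("stochastic paths stay non-negative and large steps are rejected", {
  par_loud <- model_parameters(n_TF1 = 0.8, n_TF2 = 0.8, n_CY1 = 0.8,
                               n_CY2 = 0.8)
  tr <- simulate_sde(system_state(1, 1, 0, 0), par_loud, 1e9, t_max = 48,
                     seed = 3)
  expect_true(all(tr$states >= 0))
  expect_error(simulate_sde(system_state(1, 1, 0, 0), par_default, 2e6,
                            t_max = 24, dt = 0, seed = 1), "dt")
})

test_that("long-run molecular expression shows the positive skew of
           lognormal-type fluctuations", {
  par_n <- model_parameters(n_TF1 = 0.2, n_TF2 = 0.2, n_CY1 = 0.2,
                            n_CY2 = 0.2)
  ens <- run_ensemble(150, system_state(1, 1, 0, 0), par_n, 2e6,
                      t_max = 240, master_seed = 9, record_every = 2400)
  x <- ens$states[dim(ens$states)[1], 1, ]
  expect_gt(sample_skewness(x), 0.5)
})

test_that("balance distributions are summarized and labelled by the
           documented shape rule", {
  ens <- run_ensemble(40, system_state(5, 5, 0, 0), par_quiet, 2e6,
                      t_max = 4, master_seed = 1)
  d <- balance_distribution(ens, 4)
  expect_equal(sum(d$counts), 40)
  expect_true(all(d$theta == 0.5))
  expect_equal(d$shape, "unimodal-central")
  expect_error(balance_distribution(ens, 3.21), "not on the ensemble")
  ## synthetic extreme bimodality labels as U-shaped
  fake <- ens
  fake$states[dim(fake$states)[1], 1, ] <- rep(c(0, 10), 20)
  fake$states[dim(fake$states)[1], 2, ] <- rep(c(10, 0), 20)
  expect_equal(balance_distribution(fake, 4)$shape, "U-shaped")
})

test_that("ensemble summaries reduce correctly in degenerate cases", {
  ens <- run_ensemble(6, system_state(1, 1, 0, 0), par_quiet, 2e6,
                      t_max = 24, master_seed = 2)
  s <- ensemble_summary(ens)
  ## all zero-noise paths coincide, so mean = median and IQR collapses
  expect_equal(s$TF1_mean, s$TF1_median, tolerance = 1e-12)
  expect_equal(s$TF1_q25, s$TF1_q75, tolerance = 1e-12)
  ode <- integrate_ode(system_state(1, 1, 0, 0), par_quiet, 2e6, t_max = 24)
  expect_equal(s$TF1_mean, unname(ode$states[, 1]), tolerance = 0.02)
})

test_that("ensembles round-trip through the long-format CSV writer", {
  ens <- run_ensemble(3, system_state(1, 1, 0, 0), par_default, 2e6,
                      t_max = 6, master_seed = 4)
  csv <- tempfile(fileext = ".csv")
  sumcsv <- tempfile(fileext = ".csv")
  write_ensemble(ens, csv, summary_path = sumcsv)
  long <- utils::read.csv(csv)
  expect_equal(nrow(long), 3 * length(ens$time))
  expect_equal(long$TF1[long$path_id == 2],
               unname(ens$states[, 1, 2]), tolerance = 1e-9)
  expect_equal(utils::read.csv(sumcsv)$TF1_mean,
               ensemble_summary(ens)$TF1_mean, tolerance = 1e-9)
})
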