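test_that("a trajectory started at a stable equilibrium stays there", {
  eq <- find_equilibria(par_default, 2e6)
  st <- eq$states[eq$stable & eq$label == "mixed", , drop = FALSE][1, ]
  tr <- integrate_ode(st, par_default, 2e6, t_max = 200, t_step = 50)
  expect_lt(max(abs(tr$states[nrow(tr$states), ] - st)), 1e-4)
})

test_that("symmetric initial conditions stay on the symmetric manifold", {
  tr <- integrate_ode(system_state(2, 2, 1, 1), par_default, 2e6,
                      t_max = 200)
  expect_lt(max(abs(tr$states[, 1] - tr$states[, 2])), 1e-6)
  expect_lt(max(abs(tr$states[, 3] - tr$states[, 4])), 1e-6)
})

test_that("in-vitro dynamics approach the mixed state slowly: the one-week
           transient still differs from the long-run asymptote", {
  ## exogenously biased start (Th1-skewed cytokine stimulation)
  tr <- integrate_ode(system_state(1, 1, 4, 0), par_default, 2e6,
                      t_max = 24 * 70, t_step = 24)
  ctx <- apply_density(par_default, 2e6)
  mixed <- thquorum:::mixed_equilibrium(par_default, ctx)
  day1 <- tr$states[tr$time == 24, ]
  wk1 <- tr$states[tr$time == 168, ]
  wk10 <- tr$states[nrow(tr$states), ]
  ## early culture is clearly biased by the stimulation ...
  expect_gt(abs(balance_index(day1[1], day1[2]) - 0.5), 0.02)
  ## ... the one-week state still measurably differs from the asymptote ...
  expect_gt(max(abs(wk1 - mixed) / (1 + mixed)), 1e-4)
  ## ... and by ten weeks it has converged on the common mixed state
  expect_lt(max(abs(wk10 - mixed) / (1 + mixed)), 1e-5)
})

test_that("every reported equilibrium satisfies the residual bound and the
           stability label matches the leading eigenvalue", {
  for (rho in c(2e6, 1e9)) {
    eq <- find_equilibria(par_default, rho)
    ctx <- apply_density(par_default, rho)
    for (i in seq_len(length(eq))) {
      x <- eq$states[i, ]
      f <- drift(x, ctx, par_default)
      expect_lt(max(abs(f)) / (1 + max(abs(x))), 1e-8)
      lam <- max(Re(eigen(model_jacobian(x, ctx, par_default),
                          only.values = TRUE)$values))
      expect_equal(eq$stable[i], lam < 0)
      expect_equal(eq$lambda_max[i], lam, tolerance = 1e-6)
    }
  }
})

test_that("equilibrium sets are closed under the index swap for symmetric
           parameters", {
  for (sc in c(1, 0)) {
    eq <- find_equilibria(par_default, 2e6, secretion_scale = sc)
    for (i in seq_len(length(eq))) {
      x_sw <- swap_state(eq$states[i, ])
      d <- apply(abs(eq$states - rep(x_sw, each = length(eq))), 1, max)
      expect_lt(min(d / (1 + max(abs(x_sw)))), 1e-6)
    }
  }
})

test_that("the secretion bifurcation scan brackets the loss of mixed-branch
           stability with opposite eigenvalue signs", {
  scan <- secretion_bifurcation_scan(par_default, 2e6,
                                     scales = seq(1, 0, by = -0.25))
  expect_true(is.finite(scan$critical_scale))
  expect_gt(scan$critical_scale, 0)
  expect_lt(scan$critical_scale, 1)
  ctx <- apply_density(par_default, 2e6)
  lam <- function(s, guess) {
    st <- thquorum:::mixed_equilibrium(par_default, ctx,
                                       secretion_scale = s, guess = guess)
    max(Re(eigen(model_jacobian(st, ctx, par_default,
                                secretion_scale = s),
                 only.values = TRUE)$values))
  }
  mixed1 <- thquorum:::mixed_equilibrium(par_default, ctx)
  expect_lt(lam(scan$bracket[2], mixed1), 0)
  expect_gt(lam(scan$bracket[1], mixed1), 0)
})

test_that("quorum density separates opposite stability verdicts", {
  qd <- quorum_density(par_default)
  expect_gt(qd$rho_crit, 1e6)
  expect_lt(qd$rho_crit, 1e9)
  for (f in c(0.9, 1.1)) {
    ctx <- apply_density(par_default, qd$rho_crit * f)
    st <- thquorum:::mixed_equilibrium(par_default, ctx, guess = qd$state)
    lam <- max(Re(eigen(model_jacobian(st, ctx, par_default),
                        only.values = TRUE)$values))
    expect_equal(lam < 0, f < 1)
  }
  ## the reported production:removal ratio is the closed-form density ratio
  ctx_c <- apply_density(par_default, qd$rho_crit)
  expect_equal(qd$production_removal_ratio, ctx_c$ratio1, tolerance = 1e-12)
  expect_error(quorum_density(par_default, bracket = c(1e8, 1e9)),
               "bracket")
})

test_that("scale decomposition rejects non-equilibria and loses its
           cross-scale coupling when the scales are uncoupled", {
  ctx <- apply_density(par_default, 2e6)
  expect_error(scale_decomposition(par_default, ctx,
                                   system_state(1, 1, 1, 1)),
               "not an equilibrium")
  ## no TF<->CY coupling: secretion off and no cytokine-driven induction
  par_dec <- model_parameters(s1 = 1e-12, s2 = 1e-12)
  eq <- find_equilibria(par_dec, 2e6, secretion_scale = 0)
  st <- eq$states[eq$label == "mixed", , drop = FALSE][1, ]
  dec <- scale_decomposition(par_dec, apply_density(par_dec, 2e6), st,
                             secretion_scale = 0, tol = 1e-4)
  expect_lt(abs(dec$M[1, 2]), 1e-9)
  expect_lt(abs(dec$M[2, 1]), 1e-9)
})

test_that("trajectory and equilibrium writers round-trip", {
  tr <- integrate_ode(system_state(1, 1, 0, 0), par_default, 2e6,
                      t_max = 10)
  csv <- tempfile(fileext = ".csv")
  write_trajectory(tr, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$TF1, unname(tr$states[, 1]), tolerance = 1e-9)
  meta <- jsonlite::read_json(paste0(csv, ".json"), simplifyVector = TRUE)
  expect_equal(meta$rho, 2e6)
  eq <- find_equilibria(par_default, 2e6)
  csv2 <- tempfile(fileext = ".csv")
  write_equilibria(eq, csv2)
  back2 <- utils::read.csv(csv2)
  expect_equal(nrow(back2), length(eq))
  expect_named(back2, c("TF1", "TF2", "CY1", "CY2", "lambda_max",
                        "stable", "theta", "label"))
})
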