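test_that("parameter validation enforces the model's invariants", {
  expect_s3_class(par_default, "th_params")
  expect_true(is_symmetric(par_default))
  expect_false(is_symmetric(par_asym))
  expect_error(model_parameters(b = -1), "strictly positive")
  expect_error(model_parameters(hp = 0.5), "Hill exponent")
  expect_error(model_parameters(n_TF1 = -0.1), "noise magnitude")
  expect_error(model_parameters(rho_ref = 0), "strictly positive")
})

test_that("parameter files round-trip through JSON and report bad keys", {
  path <- tempfile(fileext = ".json")
  write_parameters(par_asym, path)
  back <- read_parameters(path)
  expect_equal(unclass(back), unclass(par_asym), tolerance = 1e-12)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(b = 1, nonsense = 2), bad, auto_unbox = TRUE)
  expect_error(read_parameters(bad), "nonsense")
  incomplete <- tempfile(fileext = ".json")
  jsonlite::write_json(list(b = 1), incomplete, auto_unbox = TRUE)
  expect_error(read_parameters(incomplete), "missing parameter")
})

test_that("density scaling is the identity at the reference density and
           monotone in the production:removal ratio", {
  ctx_ref <- apply_density(par_default, par_default$rho_ref)
  expect_equal(ctx_ref$a1, par_default$a1_base)
  expect_equal(ctx_ref$dCY1,
               par_default$dCY_consume + par_default$dCY_free)
  ## ratio strictly increasing over a wide density grid
  rhos <- 10^seq(4, 10, length.out = 25)
  ratios <- vapply(rhos, function(r) apply_density(par_default, r)$ratio1,
                   numeric(1))
  expect_true(all(diff(ratios) > 0))
  ## in-vivo density has a strictly larger ratio than in-vitro
  expect_gt(apply_density(par_default, 1e9)$ratio1,
            apply_density(par_default, 1e6)$ratio1)
  ## vanishing-density limit: production -> 0, removal -> free decay
  ctx0 <- apply_density(par_default, 1e-6)
  expect_lt(ctx0$a1, 1e-10)
  expect_equal(ctx0$dCY1, par_default$dCY_free, tolerance = 1e-9)
  expect_error(apply_density(par_default, 0), "strictly positive")
  expect_error(apply_density(par_default, -5), "strictly positive")
})

test_that("drift matches its closed-form values at reference states", {
  ctx <- apply_density(par_default, 2e6)
  ## all-zero state: only basal TF production remains
  f0 <- drift(system_state(), ctx, par_default)
  expect_equal(unname(f0), c(par_default$b, par_default$b, 0, 0))
  ## saturating Th1-side APC instruction at the origin:
  ## dTF1 = b + s1 * APC1^hs / (S1^hs + APC1^hs)
  apc <- apc_instruction(APC1 = 50, APC2 = 0)
  f_apc <- drift(system_state(), ctx, par_default, apc = apc)
  expect_equal(f_apc[["TF1"]],
               par_default$b + par_default$s1 * 50^2 / (0.5^2 + 50^2),
               tolerance = 1e-12)
  expect_equal(f_apc[["TF2"]], par_default$b, tolerance = 1e-6)
  expect_error(drift(c(-1, 0, 0, 0), ctx, par_default), "non-negative")
  expect_error(drift(system_state(1, 1, 0, 0), ctx, par_default,
                     secretion_scale = 1.5), "secretion_scale")
})

test_that("secretion_scale = 0 reduces the cytokine equations to pure decay", {
  ctx <- apply_density(par_default, 2e6)
  for (x in asplit(random_states(20), 1)) {
    f <- drift(x, ctx, par_default, secretion_scale = 0)
    expect_equal(unname(f[3:4]),
                 c(-ctx$dCY1 * x[3], -ctx$dCY2 * x[4]), tolerance = 1e-12)
  }
})

test_that("the vector field preserves positivity at the boundary", {
  ctx <- apply_density(par_default, 1e9)
  states <- random_states(30, seed = 4)
  for (i in seq_len(nrow(states))) {
    x <- states[i, ]
    k <- (i %% 4) + 1
    x[k] <- 0
    f <- drift(x, ctx, par_default)
    expect_gte(f[[k]], 0)
  }
})

test_that("drift and diffusion commute with the Th1/Th2 index swap under
           symmetric parameters", {
  ctx <- apply_density(par_default, 2e6)
  for (x in asplit(random_states(20, seed = 2), 1)) {
    f <- drift(x, ctx, par_default)
    f_sw <- drift(swap_state(x), ctx, par_default)
    expect_equal(unname(f_sw), swap_state(f), tolerance = 1e-12)
    g <- diffusion(x, par_default)
    g_sw <- diffusion(swap_state(x), par_default)
    expect_equal(unname(g_sw), swap_state(g), tolerance = 1e-12)
  }
})

test_that("diffusion amplitudes are proportional to the state", {
  expect_equal(unname(diffusion(system_state(), par_default)), rep(0, 4))
  par_n <- model_parameters(n_CY1 = 0.5)
  expect_equal(diffusion(system_state(0, 3, 10, 2), par_n)[["CY1"]], 5)
  expect_equal(diffusion(system_state(0, 3, 10, 2), par_n)[["TF1"]], 0)
  expect_equal(unname(diffusion(system_state(1, 1, 1, 1), par_quiet)),
               rep(0, 4))
})

test_that("compiled and interpreted drift agree", {
  ctx <- apply_density(par_asym, 3e7)
  apc <- apc_instruction(0.4, 1.2)
  pv <- thquorum:::as_param_vector(par_asym)
  for (x in asplit(random_states(25, seed = 3), 1)) {
    f_r <- drift(x, ctx, par_asym, apc = apc, secretion_scale = 0.7)
    f_c <- thquorum:::drift_cpp(x, pv, ctx$a1, ctx$a2, ctx$dCY1, ctx$dCY2,
                                apc$APC1, apc$APC2, 0.7)
    expect_equal(unname(f_r), as.numeric(f_c), tolerance = 1e-12)
  }
})

test_that("APC constants scale linearly with APC counts", {
  expect_equal(unlist(apc_constants(0, 0, par_default)),
               c(APC1 = 0, APC2 = 0))
  a64 <- apc_constants(6, 4, par_default)
  expect_equal(a64$APC1 / a64$APC2, 6 / 4)
  a10 <- apc_constants(10, 10, par_default)
  expect_equal(a10$APC1, a10$APC2)
  expect_equal(a10$APC1, 10 * par_default$kappa_apc)
  expect_error(apc_constants(-1, 2, par_default), "non-negative")
})

test_that("balance index and attractor labels follow the documented rule", {
  expect_equal(balance_index(0, 0), 0.5)
  expect_equal(balance_index(c(3, 0, 1), c(1, 2, 1)), c(0.75, 0, 0.5))
  expect_equal(classify_attractor(c(9, 1, 1), c(1, 9, 1)),
               c("Th1", "Th2", "mixed"))
})
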