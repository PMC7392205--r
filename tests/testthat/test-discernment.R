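test_that("APC schedules validate their segments and evaluate by time", {
  sched <- apc_schedule(c(0, 10, 50), c(1, 0, 2), c(0, 1, 2))
  expect_equal(apc_at(sched, 0), c(APC1 = 1, APC2 = 0))
  expect_equal(apc_at(sched, 10), c(APC1 = 0, APC2 = 1))
  expect_equal(apc_at(sched, 49.9), c(APC1 = 0, APC2 = 1))
  expect_equal(apc_at(sched, 1000), c(APC1 = 2, APC2 = 2))
  expect_equal(schedule_bias(sched, 0), 1)
  expect_equal(schedule_bias(sched, 60), 0.5)
  expect_error(apc_schedule(c(5, 10), c(1, 1), c(1, 1)), "start at t = 0")
  expect_error(apc_schedule(c(0, 10, 10), c(1, 1, 1), c(1, 1, 1)),
               "strictly increasing")
  expect_error(apc_schedule(0, -1, 0), "non-negative")
  csv <- tempfile(fileext = ".csv")
  write_schedule(sched, csv)
  expect_equal(read_schedule(csv)$APC1, sched$APC1)
})

test_that("the random time-course generator is reproducible and spans
           transient and sustained complete switches", {
  s1 <- random_apc_timecourse(seed = 10)
  s2 <- random_apc_timecourse(seed = 10)
  expect_identical(s1, s2)
  tau <- 48
  n_sustained <- 0L
  n_transient <- 0L
  for (seed in 1:100) {
    s <- random_apc_timecourse(seed = seed)
    tot <- s$APC1 + s$APC2
    expect_true(all(tot > 0))
    bias <- s$APC1 / tot
    durs <- diff(c(s$t_start, 500))
    opt <- optimal_response(s, tau)
    if (length(opt$label) > 1L) n_sustained <- n_sustained + 1L
    ## a complete segment shorter than tau (a transient excursion)
    if (any(bias %in% c(0, 1) & durs < tau)) n_transient <- n_transient + 1L
  }
  expect_gt(n_sustained, 5)
  expect_gt(n_transient, 5)
})

test_that("the optimal response obeys only sustained, complete changes", {
  tau <- 48
  k <- 1
  const <- apc_schedule(0, k, 0)
  opt <- optimal_response(const, tau)
  expect_equal(opt$label, "Th1")
  ## sustained complete switch: flips once, exactly tau after it starts
  sus <- apc_schedule(c(0, 100), c(k, 0), c(0, k))
  opt <- optimal_response(sus, tau)
  expect_equal(opt$label, c("Th1", "Th2"))
  expect_equal(opt$t_start, c(0, 100 + tau))
  ## a complete excursion of length tau/2 never flips the target
  trans <- apc_schedule(c(0, 100, 100 + tau / 2), c(k, 0, k), c(0, k, 0))
  expect_equal(optimal_response(trans, tau)$label, "Th1")
  ## an incomplete (75%) sustained change never flips the target
  inc <- apc_schedule(c(0, 100), c(k, k / 4), c(0, 3 * k / 4))
  expect_equal(optimal_response(inc, tau)$label, "Th1")
  ## a complete run split across consecutive segments accumulates
  split <- apc_schedule(c(0, 100, 130), c(k, 0, 0), c(0, k, k))
  opt <- optimal_response(split, tau)
  expect_equal(opt$t_start, c(0, 148))
  expect_error(optimal_response(apc_schedule(0, 0, 0), tau), "zero total")
})

## minimal hand-built ensemble pinned at a chosen balance
pinned_ensemble <- function(theta, times = 0:100) {
  states <- array(0, dim = c(length(times), 4, 1),
                  dimnames = list(NULL, c("TF1", "TF2", "CY1", "CY2"), NULL))
  states[, 1, 1] <- 100 * theta
  states[, 2, 1] <- 100 * (1 - theta)
  structure(list(time = times, states = states, seeds = 1L,
                 master_seed = 1L, rho = 1e9, secretion_scale = 1,
                 schedule = apc_schedule(0, 1, 0),
                 noise = c(n_TF1 = 0, n_TF2 = 0, n_CY1 = 0, n_CY2 = 0)),
            class = "th_ensemble")
}

test_that("tracking performance scores agreement with the target label", {
  opt_th1 <- optimal_response(apc_schedule(0, 1, 0), tau = 48)
  opt_th2 <- optimal_response(apc_schedule(0, 0, 1), tau = 48)
  expect_equal(tracking_performance(pinned_ensemble(1), opt_th1)$pooled, 1)
  expect_equal(tracking_performance(pinned_ensemble(1), opt_th2)$pooled, 0)
  ## a mixed path disagrees with every target
  expect_equal(tracking_performance(pinned_ensemble(0.5), opt_th1)$pooled, 0)
  ## scoring is invariant under relabeling Th1 <-> Th2 on both sides
  sus <- apc_schedule(c(0, 40), c(1, 0), c(0, 1))
  mir <- apc_schedule(c(0, 40), c(0, 1), c(1, 0))
  p1 <- tracking_performance(pinned_ensemble(0.9),
                             optimal_response(sus, 24))$pooled
  p2 <- tracking_performance(pinned_ensemble(0.1),
                             optimal_response(mir, 24))$pooled
  expect_equal(p1, p2)
})

test_that("a single-cell performance grid self-normalizes to 1", {
  g <- performance_grid(par_default, n_tf_grid = 0.1, n_cy_grid = 0.1,
                        tau = 48, n_timecourses = 2, n_paths = 2,
                        master_seed = 21, horizon = 100, dt = 0.05)
  expect_equal(nrow(g), 1)
  expect_equal(g$relative_performance, 1)
  g2 <- performance_grid(par_default, n_tf_grid = 0.1, n_cy_grid = 0.1,
                         tau = 48, n_timecourses = 2, n_paths = 2,
                         master_seed = 21, horizon = 100, dt = 0.05)
  expect_identical(g, g2)
})
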