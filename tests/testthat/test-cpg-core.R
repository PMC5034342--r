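test_that("zero state with no tonic drive is an exact fixed point", {
  p <- cpg_params(c = 0)
  s <- cpg_state()
  for (i in 1:5) s <- cpg_step(s, p, 0.005)
  expect_identical(c(s$x1, s$v1, s$x2, s$v2), c(0, 0, 0, 0))
})

test_that("one RK4 step matches a finely subdivided Euler integration", {
  p <- cpg_params()
  s0 <- cpg_state(0.3, 0.1, -0.2, 0.05)
  dt <- 1e-4
  s_rk <- cpg_step(s0, p, dt)
  s_eu <- euler_cpg(s0, p, dt, 10000)
  rel <- abs(c(s_rk$x1, s_rk$v1, s_rk$x2, s_rk$v2) - s_eu) /
    pmax(abs(s_eu), 1e-8)
  expect_lt(max(rel), 1e-6)
})

test_that("single-step API and compiled trace integration agree exactly", {
  p <- cpg_params()
  tr <- fx_ref_trace()
  s <- cpg_state(attr(tr, "init")[1], attr(tr, "init")[2],
                 attr(tr, "init")[3], attr(tr, "init")[4])
  for (i in 1:40) s <- cpg_step(s, p, attr(tr, "dt"))
  expect_equal(c(s$x1, s$v1, s$x2, s$v2),
               unname(unlist(tr[41, c("x1", "v1", "x2", "v2")])),
               tolerance = 1e-14)
})

test_that("trace against an independent adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- cpg_params()
  rhs <- function(t, y, parms) {
    y1 <- max(0, y[1]); y2 <- max(0, y[3])
    list(c((-y[1] - p$beta * y[2] - p$mu21 * y2 + p$c) / p$tau1,
           (-y[2] + y1) / p$tau2,
           (-y[3] - p$beta * y[4] - p$mu12 * y1 + p$c) / p$tau1,
           (-y[4] + y2) / p$tau2))
  }
  tr <- fx_ref_trace()
  times <- seq(0, 2, by = 0.001)
  ref <- deSolve::ode(attr(tr, "init"), times, rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  i <- nrow(ref)
  # fixed-step RK4 on a rectified (non-smooth) RHS carries O(dt^2) error
  # at the switching corners, so agreement is to ~1e-4, not machine level
  expect_equal(unname(unlist(tr[i, c("x1", "v1", "x2", "v2")])),
               unname(ref[i, 2:5]), tolerance = 1e-4)
})

test_that("simulation traces satisfy the output identities", {
  tr <- fx_ref_trace()
  expect_true(all(tr$y1 >= 0))
  expect_true(all(tr$y2 >= 0))
  expect_identical(tr$y_out, tr$y1 - tr$y2)
  expect_equal(diff(tr$t), rep(attr(tr, "dt"), nrow(tr) - 1),
               tolerance = 1e-12)
})

test_that("simulation is deterministic and breaks symmetric inits", {
  p <- cpg_params()
  a <- cpg_simulate(p, duration = 2.5)
  b <- cpg_simulate(p, duration = 2.5)
  expect_identical(a$y_out, b$y_out)
  expect_true(attr(a, "perturbed"))
  asym <- cpg_simulate(p, duration = 2.5, init = cpg_state(x1 = 0.5))
  expect_false(attr(asym, "perturbed"))
})

test_that("reference parameters give a sustained, non-decaying rhythm", {
  tr <- fx_ref_trace()
  last <- tr$y_out[tr$t >= 8]
  prev <- tr$y_out[tr$t >= 6 & tr$t < 8]
  expect_gt(diff(range(last)), 1)
  expect_equal(diff(range(last)), diff(range(prev)), tolerance = 0.05)
})

test_that("without tonic drive the output decays to zero", {
  p <- cpg_params(c = 0)
  tr <- cpg_simulate(p, duration = 20 * p$tau2,
                     init = cpg_state(0.7, 0.2, -0.4, 0.1))
  expect_lt(max(abs(tr$y_out[tr$t >= 20 * p$tau2 - 0.01])), 1e-3)
})

test_that("frequency estimator is exact on a known sine", {
  tt <- seq(0, 10, by = 0.001)
  tr <- data.frame(t = tt, y_out = sin(2 * pi * 2 * tt))
  expect_equal(estimate_frequency(tr, discard = 1), 2, tolerance = 1e-6)
})

test_that("zero-crossing estimate agrees with the FFT peak", {
  tr <- fx_ref_trace()
  f_zc <- estimate_frequency(tr, discard = 2)
  y <- tr$y_out[tr$t >= 2]
  spec <- Mod(stats::fft(y - mean(y)))[seq_len(length(y) %/% 2)]
  f_fft <- (which.max(spec[-1])) / (length(y) * attr(tr, "dt"))
  expect_lt(abs(f_zc - f_fft), 1 / (length(y) * attr(tr, "dt")) + 1e-9)
})

test_that("frequency estimate converges under step refinement", {
  p <- cpg_params()
  fs <- vapply(c(0.002, 0.001, 0.0005), function(dt)
    estimate_frequency(cpg_simulate(p, duration = 8, dt = dt), 2),
    numeric(1))
  expect_lt(abs(fs[3] - fs[2]), abs(fs[2] - fs[1]) + 1e-12)
  expect_lt(abs(fs[2] - fs[1]) / fs[2], 0.001)
})

test_that("estimator input validation and degenerate returns", {
  tr <- fx_ref_trace()
  expect_error(estimate_frequency(tr, discard = 11), "shorter")
  flat <- data.frame(t = seq(0, 3, 0.01), y_out = 0)
  expect_identical(estimate_frequency(flat, 1), 0)
})

test_that("oscillation amplitude grows with tonic drive", {
  amps <- vapply(c(10, 30, 50.6, 80), function(cc) {
    tr <- cpg_simulate(cpg_params(c = cc), duration = 8)
    diff(range(tr$y_out[tr$t >= 4]))
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("frequency falls as both time constants are scaled up", {
  fr <- vapply(c(1, 1.5, 2), function(k) {
    p <- cpg_params(tau1 = 0.10 * k, tau2 = 0.20 * k)
    estimate_frequency(cpg_simulate(p, duration = 12), 3)
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("stability report: reference set stable, decoupled set not", {
  st <- check_stability(cpg_params())
  expect_true(st$stable)
  expect_true(st$analytic$oscillatory)
  st0 <- check_stability(cpg_params(mu12 = 0, mu21 = 0))
  expect_false(st0$stable)
  expect_false(st0$analytic$oscillatory)
})

test_that("analytic and empirical stability verdicts agree on random draws", {
  sc <- cpg_search_config()
  lo <- vapply(sc$bounds, `[`, numeric(1), 1)
  hi <- vapply(sc$bounds, `[`, numeric(1), 2)
  set.seed(7)
  agree <- vapply(seq_len(60), function(i) {
    v <- stats::runif(6, lo, hi)
    p <- cpg_params(v[1], v[2], v[3], v[4], v[5], v[6])
    st <- check_stability(p, duration = 10, dt = min(0.002, p$tau1 / 10))
    st$stable == st$analytic$oscillatory
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("parameter and step validation raise informative errors", {
  expect_error(cpg_params(tau1 = -1), "tau1")
  expect_error(cpg_params(beta = -0.1), ">= 0")
  expect_error(cpg_step(cpg_state(), cpg_params(), 0.05), "tau1/10")
  expect_error(cpg_simulate(cpg_params(), duration = 1), ">= 2")
})

test_that("trace CSV round-trips with its metadata sidecar", {
  tr <- cpg_simulate(cpg_params(), duration = 2.5)
  path <- tempfile(fileext = ".csv")
  write_cpg_trace(tr, path)
  back <- read_cpg_trace(path)
  expect_equal(back$y_out, tr$y_out, tolerance = 1e-12)
  expect_equal(attr(back, "params")$beta, 8.44)
  unlink(c(path, paste0(path, ".json")))
})
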