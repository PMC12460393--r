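test_that("directed Hausdorff distance is exact, asymmetric and matches brute force", {
  V <- point_cloud(c(0, 2)); W <- point_cloud(0)
  expect_identical(directed_hausdorff(V, V), 0)
  expect_identical(directed_hausdorff(V, W), 2)
  expect_identical(directed_hausdorff(W, V), 0)
  set.seed(99)
  A <- point_cloud(matrix(runif(200), ncol = 2))
  B <- point_cloud(rbind(unclass(A), c(5, 5)))
  expect_identical(directed_hausdorff(A, B), 0)
  expect_gt(directed_hausdorff(B, A), 0)
  # oracle equivalence on random cloud pairs
  for (i in 1:5) {
    set.seed(i)
    V <- point_cloud(matrix(rnorm(2 * (20 + i)), ncol = 2))
    W <- point_cloud(matrix(rnorm(2 * (30 - i)), ncol = 2))
    expect_equal(directed_hausdorff(V, W), oracle_directed_hausdorff(V, W),
                 tolerance = 1e-12)
  }
  expect_error(directed_hausdorff(point_cloud(1), point_cloud(matrix(1, 1, 2))),
               "dimension")
})

test_that("global attractor estimation recovers fixed points and flags divergence", {
  sys <- autonomous_system(1, function(l, x) 1 + (x - 1) * exp(-l),
                           bounds = cbind(-5, 5))
  est <- estimate_global_attractor(sys, point_cloud(seq(-5, 5, length.out = 20)),
                                   t_max = 30)
  expect_identical(est$report$verdict, "pass")
  expect_lt(directed_hausdorff(est$attractor, point_cloud(1)), 1e-6)
  expect_lt(est$report$invariance_residual, 1e-6)

  halving <- autonomous_system(1, function(l, x) x / 2^l,
                               time = time_structure("discrete", sample_range = 4),
                               bounds = cbind(-1, 1))
  est2 <- estimate_global_attractor(halving, point_cloud(seq(-1, 1, 0.25)),
                                    t_max = 60, n_steps = 60)
  expect_lt(directed_hausdorff(est2$attractor, point_cloud(0)), 1e-6)

  grow <- autonomous_system(1, function(l, x) x * exp(l), bounds = cbind(-5, 5))
  est3 <- estimate_global_attractor(grow, point_cloud(1), t_max = 60, n_steps = 30)
  expect_identical(est3$report$verdict, "no bounded attractor found")
  expect_null(est3$attractor)
})

test_that("forward convergence tracks moving fibres at the closed-form rate", {
  proc <- relaxation_process()
  B <- point_cloud(seq(-5, 5, length.out = 11))
  cand <- set_fibres(c(5, 10, 20), list(point_cloud(1), point_cloud(1), point_cloud(1)))
  rep <- forward_convergence(proc, B, start = 0, cand, horizon = c(5, 10, 20),
                             tol = 1e-6)
  expect_identical(rep$verdict, "pass")
  # sup over B of e^{-(t-s)} |x - 1| with sup |x-1| = 6
  expect_equal(rep$distance, 6 * exp(-c(5, 10, 20)), tolerance = 1e-6)
  # candidate equal to the evolved cloud itself: distance 0 everywhere
  ev <- lapply(c(5, 10), function(t)
    point_cloud(vapply(as.numeric(B), function(x) proc$evolve(0, t, x), 0)))
  rep0 <- forward_convergence(proc, B, 0, set_fibres(c(5, 10), ev), c(5, 10))
  expect_equal(max(rep0$distance), 0)
  expect_error(forward_convergence(proc, B, 0, cand, horizon = c(5, 7)), "missing fibre")
  # linearly growing states never settle into a bounded candidate
  aging <- load_fixture("aging_growth_process")
  repf <- forward_convergence(aging, point_cloud(c(1, 2)), start = 1,
                              set_fibres(c(10, 100, 1000), list(point_cloud(1),
                                                                point_cloud(1),
                                                                point_cloud(1))),
                              horizon = c(10, 100, 1000), tol = 1e-6)
  expect_identical(repf$verdict, "fail")
})

test_that("pullback estimation: fixed target, receding starts", {
  proc <- relaxation_process()
  B <- point_cloud(seq(-5, 5, length.out = 10))
  pb <- pullback_convergence(proc, B, target = 0, starts = -(1:30), tol = 1e-6)
  expect_identical(pb$report$verdict, "pass")
  expect_lt(directed_hausdorff(pb$fibre, point_cloud(1)), 1e-6)
  # for an autonomous system wrapped as a process, pullback = forward estimate
  sys <- autonomous_system(1, function(l, x) 1 + (x - 1) * exp(-l),
                           bounds = cbind(-5, 5))
  fwd <- estimate_global_attractor(sys, B, t_max = 30)
  expect_lt(max(directed_hausdorff(pb$fibre, fwd$attractor),
                directed_hausdorff(fwd$attractor, pb$fibre)), 1e-6)
  # aging growth blows up as the start recedes to the time origin
  aging <- load_fixture("aging_growth_process")
  aging$time$origin  # t0 = 1; starts approach it from above toward 0 depth
  pbf <- pullback_convergence(
    process_system(1, function(s, t, x) (t / s) * x,
                   time = time_structure("continuous", origin = 0.001,
                                         sample_range = 3),
                   bounds = cbind(0.1, 10)),
    point_cloud(c(0.5, 1)), target = 1,
    starts = c(0.5, 0.1, 0.05, 0.01, 0.005), tol = 1e-6)
  expect_identical(pbf$report$verdict, "fail")
})

test_that("random pullback fibres match the geometric-series oracle", {
  rdsys <- rds_from_maps(load_fixture("affine_random_contraction"))
  B <- point_cloud(seq(0, 1, length.out = 8))
  est <- random_pullback_estimate(rdsys, omega_seed = 2, depths = 1:40, B = B)
  expect_identical(est$report$verdict, "pass")
  b <- seq_read(est$omega, -(1:40)) - 1L
  series <- sum(b * 2^-(1:40))
  expect_lt(max(abs(as.numeric(est$fibre) - series)), 1e-10)
  # geometric contraction bound on successive fibres: <= 2^-k diam(B)
  expect_true(all(est$report$distance <= 2^-(1:39) * 1 + 1e-12))
  # singleton alphabet: deterministic pullback equals the global attractor
  det <- rds_from_maps(random_map_system(list(function(x) x / 2), c(0, 1), p = 1,
                                         sided = "two"))
  estd <- random_pullback_estimate(det, omega_seed = 1, depths = 1:50, B = B)
  aut <- autonomous_system(1, function(l, x) x / 2^l,
                           time = time_structure("discrete", sample_range = 4),
                           bounds = cbind(0, 1))
  ga <- estimate_global_attractor(aut, B, t_max = 50, n_steps = 50)
  expect_lt(max(directed_hausdorff(estd$fibre, ga$attractor),
                directed_hausdorff(ga$attractor, estd$fibre)), 1e-9)
  # expanding dynamics: clouds grow, verdict fail
  expanding <- random_dynamical_system(
    bernoulli_scheme(c(0.5, 0.5), "two"),
    cocycle = function(t, omega, x) x * 2^t, domain = c(-1e12, 1e12))
  estf <- random_pullback_estimate(expanding, omega_seed = 3, depths = 1:20,
                                   B = point_cloud(c(-1, 1)))
  expect_identical(estf$report$verdict, "fail")
  # one-sided driving cannot be pulled back through its past
  oneside <- rds_from_maps(load_fixture("random_quadratic_halving"))
  expect_error(random_pullback_estimate(oneside, 1, 1:5, B), "two-sided")
})

test_that("residence bookkeeping segments trajectories into transients", {
  # constant trajectory inside set 1: one open residence from t = 0
  r1 <- transient_length(0:99, rep(0, 100), list(point_cloud(0), point_cloud(3)),
                         radius = 0.5)
  expect_equal(nrow(r1), 1L)
  expect_identical(r1$set, 1L)
  expect_equal(r1$entry_time, 0)
  expect_true(r1$open)
  # crafted two-block path: one transition at step 1000
  r2 <- transient_length(0:1999, c(rep(-1, 1000), rep(1, 1000)),
                         list(point_cloud(-1), point_cloud(1)), radius = 0.2)
  expect_identical(r2$set, c(1L, 2L))
  expect_equal(r2$entry_time, c(0, 1000))
  expect_equal(r2$exit_time[1], 999)
  expect_true(r2$open[2])
  # double-well ODE from x0 = 0.9: single residence in the +1 well, no exit
  sol <- integrate_ode(function(x) x - x^3, 0.9, seq(0, 30, 0.1))
  r3 <- transient_length(sol[, 1], sol[, 2],
                         list(point_cloud(-1), point_cloud(1)), radius = 0.2)
  expect_identical(r3$set, 2L)
  expect_true(r3$open)
  expect_error(transient_length(0:9, rep(0, 10),
                                list(point_cloud(0), point_cloud(0.3)), 0.2),
               "overlap")
})
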