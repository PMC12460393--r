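test_that("mass-action formation rates match hand computations and a small-instance oracle", {
  bd <- load_fixture("birth_death")
  expect_identical(species_formation_rate(bd, 3), -1)
  conv <- reaction_network(nu = matrix(c(1, 0), 2), nu_prime = matrix(c(0, 1), 2),
                           k = 2)
  expect_identical(species_formation_rate(conv, c(3, 0)), c(-6, 6))
  empty <- reaction_network(nu = matrix(numeric(0), 2, 0),
                            nu_prime = matrix(numeric(0), 2, 0), k = numeric(0))
  expect_identical(species_formation_rate(empty, c(1, 2)), c(0, 0))
  expect_error(species_formation_rate(bd, c(1, 2)), "dimension")
  expect_error(species_formation_rate(bd, -1), "negative")
  # exhaustive single-reaction oracle: all stoichiometries with entries <= 2, N <= 3
  for (N in 1:3) {
    combos <- as.matrix(expand.grid(rep(list(0:2), 2 * N)))
    set.seed(N)
    pick <- combos[sample(nrow(combos), min(25, nrow(combos))), , drop = FALSE]
    x <- runif(N, 0.1, 2)
    for (r in seq_len(nrow(pick))) {
      nu <- pick[r, 1:N]; nup <- pick[r, N + 1:N]
      net <- reaction_network(matrix(nu, N), matrix(nup, N), k = 1.5)
      manual <- 1.5 * prod(x^nu) * (nup - nu)
      expect_equal(species_formation_rate(net, x), as.numeric(manual),
                   tolerance = 1e-12)
    }
  }
})

test_that("ODE integration reproduces closed forms and conserves closed networks", {
  expect_equal(unname(integrate_ode(function(x) x, 1, c(0, 1))[2, 2]), exp(1),
               tolerance = 1e-6)
  const <- integrate_ode(function(x) 0 * x, c(2, 3), seq(0, 5, 1))
  expect_true(all(abs(const[, 2] - 2) < 1e-12) && all(abs(const[, 3] - 3) < 1e-12))
  bd <- load_fixture("birth_death")
  sol <- integrate_ode(bd, 0, seq(0, 20, 0.5))
  expect_equal(unname(sol[nrow(sol), 2]), 2, tolerance = 1e-4)  # k1/k2 (1 - e^{-k2 t})
  # A <-> B conversion conserves total mass
  ab <- reaction_network(nu = cbind(c(1, 0), c(0, 1)),
                         nu_prime = cbind(c(0, 1), c(1, 0)), k = c(1, 0.5))
  sol2 <- integrate_ode(ab, c(2, 1), seq(0, 10, 0.25))
  expect_true(all(abs(rowSums(sol2[, 2:3]) - 3) < 1e-7))
  expect_error(integrate_ode(function(x) x, 1, c(1, 0.5)), "increasing")
})

test_that("fixed points are located and classified by Jacobian eigenvalues", {
  rep <- find_fixed_points(function(x) x - x^3, guesses = c(-2, 0.1, 2))
  locs <- sort(vapply(rep$points, function(p) p$location, 0))
  expect_equal(locs, c(-1, 0, 1), tolerance = 1e-6)
  cls <- vapply(rep$points, function(p) p$classification, "")
  locs_raw <- vapply(rep$points, function(p) p$location, 0)
  expect_identical(cls[order(locs_raw)], c("stable", "unstable", "stable"))
  ev <- vapply(rep$points[order(locs_raw)], function(p) Re(p$eigenvalues[1]), 0)
  expect_equal(ev, c(-2, 1, -2), tolerance = 1e-4)

  rep2 <- find_fixed_points(function(x) -x, guesses = 3)
  expect_length(rep2$points, 1)
  expect_identical(rep2$points[[1]]$classification, "stable")

  rep3 <- find_fixed_points(load_fixture("birth_death"), guesses = 0.3)
  expect_equal(rep3$points[[1]]$location, 2, tolerance = 1e-8)
  expect_identical(rep3$points[[1]]$classification, "stable")
  # no root reachable: empty report, not an error
  rep4 <- find_fixed_points(function(x) x * 0 + 1, guesses = 0)
  expect_length(rep4$points, 0)
})

test_that("Euler-Maruyama: zero diffusion is deterministic Euler; seeding is bitwise", {
  det <- sde_model(function(x, t, th) -x, diffusion = 0, eps = 2, dim = 1L,
                   positivity = "none", vectorized = TRUE)
  grid <- seq(0, 2, 0.01)
  ens <- simulate_sde(det, 1, grid, n_paths = 3, seed = 1)
  euler <- 1
  for (k in seq_along(grid)[-1])
    euler <- c(euler, euler[k - 1] + (-euler[k - 1]) * (grid[k] - grid[k - 1]))
  expect_identical(as.numeric(ens$paths[2, , 1]), as.numeric(euler))
  ou <- load_fixture("ou_process")
  e1 <- simulate_sde(ou, 0, grid, 50, seed = 7)
  e2 <- simulate_sde(ou, 0, grid, 50, seed = 7)
  expect_identical(e1$paths, e2$paths)
  # stationary variance of dx = -x dt + sqrt(eps) dW is eps / 2 = 1
  grid10 <- seq(0, 10, 0.01)
  e3 <- simulate_sde(ou, 0, grid10, 1000, seed = 11)
  v <- var(e3$paths[, length(grid10), 1])
  expect_lt(abs(v - 1), 4 * sqrt(2 / 999))
  # the non-vectorized path agrees with the vectorized one
  ou_slow <- sde_model(function(x, t, th) -x, diffusion = 1, eps = 2, dim = 1L,
                       positivity = "none", vectorized = FALSE)
  e4 <- simulate_sde(ou_slow, 0, seq(0, 1, 0.1), 4, seed = 5)
  e5 <- simulate_sde(ou, 0, seq(0, 1, 0.1), 4, seed = 5)
  expect_equal(e4$paths, e5$paths, tolerance = 1e-12)
})

test_that("density estimation normalizes and concentrates deterministic mass", {
  ou <- load_fixture("ou_process")
  ens <- simulate_sde(ou, 0, seq(0, 10, 0.01), 400, seed = 3)
  dens <- estimate_density(ens, list(pool = TRUE, burn_in = 0.5),
                           breaks = seq(-4, 4, length.out = 41))
  expect_equal(sum(dens$density * diff(dens$edges[[1]])), 1, tolerance = 1e-9)
  det <- sde_model(function(x, t, th) -x, diffusion = 0, dim = 1L,
                   positivity = "none", vectorized = TRUE)
  ens0 <- simulate_sde(det, 1, seq(0, 5, 0.01), 20, seed = 2)
  d0 <- estimate_density(ens0, list(time_index = 501),
                         breaks = seq(-1, 1, length.out = 21))
  expect_identical(sum(d0$counts > 0), 1L)  # all mass in the endpoint bin
  expect_error(estimate_density(ens, list(time_index = 1e6)), "out of range")
})

test_that("the quasi-potential is a shifted negative log-density with finite floor", {
  # uniform density: U_q identically zero
  ufix <- structure(list(d = 1L, edges = list(seq(0, 1, 0.1)),
                         mids = list(seq(0.05, 0.95, 0.1)),
                         density = rep(1, 10), counts = rep(10, 10), n = 100),
                    class = "density_grid")
  qpu <- quasipotential(ufix)
  expect_true(all(qpu$U == 0))
  expect_warning(vu <- find_valleys(qpu), "constant")
  expect_identical(nrow(vu), 0L)
  # analytic standard normal density: U_q - x^2/2 constant above the floor
  mids <- seq(-3.975, 3.975, 0.05)
  rho <- dnorm(mids); rho <- rho / sum(rho * 0.05)
  gfix <- structure(list(d = 1L, edges = list(seq(-4, 4, 0.05)), mids = list(mids),
                         density = rho, counts = round(rho * 1e5), n = 1e5),
                    class = "density_grid")
  qp <- quasipotential(gfix, floor = 1e-12)
  resid <- qp$U - mids^2 / 2
  expect_lt(max(resid) - min(resid), 1e-9)
  expect_identical(min(qp$U), 0)
  expect_error(quasipotential(gfix, floor = -1), "positive")
})

test_that("valleys are local minima merged by separation", {
  mids <- seq(-2, 2, 0.1)
  quad <- structure(list(d = 1L, edges = list(seq(-2.05, 2.05, 0.1)), mids = list(mids),
                         density = exp(-mids^2 / 2), counts = 0, n = 1),
                    class = "density_grid")
  v1 <- find_valleys(quasipotential(quad, floor = 1e-12))
  expect_identical(nrow(v1), 1L)
  expect_lt(abs(v1$x), 0.1)
  dw <- structure(list(d = 1L, edges = list(seq(-2.05, 2.05, 0.1)), mids = list(mids),
                       density = exp(-(mids^4 / 4 - mids^2 / 2) / 0.25), counts = 0,
                       n = 1),
                  class = "density_grid")
  v2 <- find_valleys(quasipotential(dw, floor = 1e-12), min_separation = 0.5)
  expect_identical(nrow(v2), 2L)
  expect_equal(sort(v2$x), c(-1, 1), tolerance = 1e-9)
})

test_that("fate transitions are detected per path with exit and entry times", {
  valleys <- data.frame(x = c(-1, 1), U = c(0, 0), index = c(1, 2))
  mk_ens <- function(tracks) {
    a <- array(NA_real_, dim = c(length(tracks), length(tracks[[1]]), 1))
    for (i in seq_along(tracks)) a[i, , 1] <- tracks[[i]]
    structure(list(times = seq_along(tracks[[1]]) - 1, paths = a,
                   flagged = rep(FALSE, length(tracks)), seed = 0, model = NULL),
              class = "trajectory_ensemble")
  }
  # deterministic relaxation into one valley: no events
  ens1 <- mk_ens(list(1 - exp(-(0:99 / 10))))
  expect_identical(nrow(detect_transitions(ens1, valleys, 0.3)), 0L)
  # crafted two-segment path: exactly one event V1 -> V2
  ens2 <- mk_ens(list(c(rep(-1, 50), rep(1, 50))))
  ev <- detect_transitions(ens2, valleys, 0.3)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$from, 1L)
  expect_identical(ev$to, 2L)
  expect_equal(ev$exit_time, 49)
  expect_equal(ev$entry_time, 50)
  # counts are invariant under relabelling of valleys
  ev_swap <- detect_transitions(ens2, valleys[2:1, ], 0.3)
  expect_identical(nrow(ev_swap), nrow(ev))
  expect_identical(ev_swap$from, 2L)
  expect_error(detect_transitions(ens2, data.frame(x = c(0, 0.3)), 0.3), "overlap")
  # fewer than two valleys: trivially empty
  expect_identical(nrow(detect_transitions(ens2, valleys[1, , drop = FALSE], 0.3)), 0L)
})

test_that("time-reversibility requires gradient drift and constant diffusion", {
  expect_identical(gradient_check(load_fixture("ou_process"),
                                  probes = seq(-2, 2, 0.5))$verdict,
                   "time-reversible form")
  rot <- sde_model(function(x, t, th) c(-x[2], x[1]), 1, 1, dim = 2L,
                   positivity = "none")
  gr <- gradient_check(rot, probes = cbind(c(0.3, -1, 2), c(0.7, 0.2, -0.5)))
  expect_identical(gr$verdict, "irreversible")
  expect_false(gr$gradient_drift)
  expect_equal(gr$symmetry_residual, 2, tolerance = 1e-6)
  varying <- sde_model(function(x, t, th) -x,
                       function(x, t, th) 1 + x^2, 1, dim = 1L, positivity = "none")
  gv <- gradient_check(varying, probes = seq(-2, 2, 0.5))
  expect_identical(gv$verdict, "irreversible")
  expect_false(gv$constant_diffusion)
  expect_true(gv$gradient_drift)  # every smooth 1-D drift is a gradient
})
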