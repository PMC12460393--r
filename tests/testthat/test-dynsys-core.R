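test_that("time structures sample valid durations and reject degenerate windows", {
  ts <- time_structure("continuous", origin = 1, sample_range = 3)
  D <- sample_durations(ts, 50, seed = 1)
  expect_true(all(D[, "s"] <= D[, "t"]))
  expect_true(all(D[, "s"] >= 1))
  td <- time_structure("discrete", origin = 0, sample_range = 4)
  l <- sample_lengths(td, 50, seed = 2)
  expect_true(all(l == round(l)) && all(l >= 0))
  # duration lengths are closed under addition within the represented range
  m <- sample_lengths(td, 50, seed = 3)
  expect_true(all((l + m) == round(l + m)))
  expect_error(time_structure("continuous", sample_range = 0), "zero-length")
})

test_that("autonomous evolution matches closed forms and enforces preconditions", {
  sys <- load_fixture("exp_growth")
  expect_identical(evolve_autonomous(sys, 0, 5), 5)
  expect_equal(evolve_autonomous(sys, 1, 1), exp(1), tolerance = 1e-12)
  # independent ODE oracle for f' = f, f(0) = 1
  ode_val <- unname(integrate_ode(function(x) x, 1, c(0, 1))[2, 2])
  expect_equal(evolve_autonomous(sys, 1, 1), ode_val, tolerance = 1e-8)
  fwd <- autonomous_system(1, function(l, x) x * exp(l), bounds = cbind(0.1, 10))
  expect_error(evolve_autonomous(fwd, -1, 1), "forward-only")
  expect_error(evolve_autonomous(fwd, 1, 100), "bounds")
  # repeated calls are bitwise identical
  expect_identical(evolve_autonomous(sys, 1.234, 2.5), evolve_autonomous(sys, 1.234, 2.5))
})

test_that("left shift on a periodic two-symbol sequence has period 2", {
  ss <- symbol_sequence(c(1L, 2L), offset = 0, n_symbols = 2, sided = "two",
                        extend = "periodic")
  shifted2 <- shift_sequence(ss, 2)
  expect_identical(seq_read(shifted2, -4:4), seq_read(ss, -4:4))
  shifted1 <- shift_sequence(ss, 1)
  expect_identical(seq_read(shifted1, 0:3), c(2L, 1L, 2L, 1L))
})

test_that("process evolution: initial value, printed formula, causality by hand", {
  proc <- load_fixture("aging_growth_process")
  expect_equal(evolve_process(proc, 1, 2, 3), 6)
  expect_identical(evolve_process(proc, 2, 2, 7.5), 7.5)
  # phi((1,4), x) = phi((2,4), phi((1,2), x)) = 4x
  x <- 1.7
  expect_equal(evolve_process(proc, 1, 4, x), 4 * x, tolerance = 1e-12)
  expect_equal(evolve_process(proc, 2, 4, evolve_process(proc, 1, 2, x)), 4 * x,
               tolerance = 1e-12)
  expect_error(evolve_process(proc, 3, 2, 1), "t < s")
})

test_that("skew-product evaluation drives base and fibre together", {
  flow <- load_fixture("aging_growth_skew")
  out <- evolve_skew(flow, 1, 1, 3)
  expect_equal(out$p, 2)
  expect_equal(out$x, 6)
  out0 <- evolve_skew(flow, 0, 1.3, 2.2)
  expect_identical(out0$p, 1.3)
  expect_identical(out0$x, 2.2)
  # cocycle witness: phi(2,1,x) = phi(1, theta(1,1), phi(1,1,x)) = 3x
  x <- 0.9
  expect_equal(flow$cocycle(2, 1, x), 3 * x, tolerance = 1e-12)
  expect_equal(flow$cocycle(1, 2, flow$cocycle(1, 1, x)), 3 * x, tolerance = 1e-12)
})

test_that("axiom checks pass on analytic fixtures and fail on counterexamples", {
  expect_true(all_verdicts_pass(check_axioms(load_fixture("exp_growth"),
                                             n_samples = 300, seed = 1, tol = 1e-9)))
  reps <- check_axioms(load_fixture("aging_growth_process"), n_samples = 300,
                       seed = 1, tol = 1e-9, translation_invariance = TRUE)
  expect_identical(reps$initial_value$verdict, "pass")
  expect_identical(reps$causality$verdict, "pass")
  expect_identical(reps$translation_invariance$verdict, "fail")
  expect_true(all(c("s", "t", "r", "x") %in% names(reps$translation_invariance$witness)))

  # deliberately broken cocycle phi(l, p, x) = x + l^2
  drv <- autonomous_system(1, function(l, p) l + p, bounds = cbind(0.5, 5))
  broken <- skew_product_flow(1, function(l, p, x) x + l^2, drv, bounds = cbind(0.1, 10))
  reps <- check_axioms(broken, n_samples = 100, seed = 2, tol = 1e-9)
  expect_identical(reps$identity$verdict, "pass")
  expect_identical(reps$cocycle$verdict, "fail")

  # an evolution map that raises is recorded as a failure, not an exception
  bad <- autonomous_system(1, function(l, x) stop("boom"), bounds = cbind(0, 1))
  reps <- check_axioms(bad, n_samples = 5, seed = 3)
  expect_identical(reps$semigroup$verdict, "fail")
  expect_match(reps$semigroup$witness$error, "boom")
  expect_error(check_axioms(load_fixture("exp_growth"), n_samples = 0), ">= 1")
})

test_that("duration-length form: valid for invariant processes, refused otherwise", {
  expproc <- process_system(1, function(s, t, x) x * exp(t - s),
                            time = time_structure("continuous", origin = 1),
                            bounds = cbind(0.1, 10))
  theta <- duration_length_form(expproc, seed = 5)
  expect_equal(evolve_autonomous(theta, 1, 1), exp(1), tolerance = 1e-12)
  expect_true(all_verdicts_pass(check_axioms(theta, 200, seed = 6)))
  # round trip: re-expand eta((s,t),x) := theta(t-s, x) and compare pointwise
  D <- sample_durations(expproc$time, 50, seed = 7)
  xs <- runif(50, 0.1, 5)
  for (i in seq_len(50))
    expect_equal(theta$evolve(D[i, 2] - D[i, 1], xs[i]),
                 expproc$evolve(D[i, 1], D[i, 2], xs[i]), tolerance = 1e-12)

  const <- process_system(1, function(s, t, x) x, bounds = cbind(-1, 1))
  expect_identical(evolve_autonomous(duration_length_form(const), 2, 0.3), 0.3)
  expect_error(duration_length_form(load_fixture("aging_growth_process")),
               "not time-translation invariant")
})

test_that("process -> skew embedding reproduces the worked skew fixture", {
  proc <- load_fixture("aging_growth_process")
  emb <- process_to_skew(proc)
  ref <- load_fixture("aging_growth_skew")
  for (tp in list(c(1, 1, 3), c(0.5, 2, 1.2), c(2, 1.5, 0.7))) {
    expect_equal(emb$cocycle(tp[1], tp[2], tp[3]), ref$cocycle(tp[1], tp[2], tp[3]),
                 tolerance = 1e-12)
    expect_equal(emb$driving$evolve(tp[1], tp[2]), ref$driving$evolve(tp[1], tp[2]))
  }
  expect_true(all_verdicts_pass(check_axioms(emb, 200, seed = 8)))
  # identity process embeds to a noise-blind cocycle
  idp <- process_system(1, function(s, t, x) x,
                        time = time_structure("continuous", origin = 1),
                        bounds = cbind(-1, 1))
  emb2 <- process_to_skew(idp)
  expect_identical(emb2$cocycle(2, 5, 0.4), 0.4)
  # exp-growth process embeds to a p-independent fibre map
  emb3 <- process_to_skew(process_system(1, function(s, t, x) x * exp(t - s),
                                         time = time_structure("continuous", origin = 1),
                                         bounds = cbind(0.1, 10)))
  expect_equal(emb3$cocycle(1, 2, 1), emb3$cocycle(1, 7, 1), tolerance = 1e-12)
  expect_true(all_verdicts_pass(check_axioms(emb3, 100, seed = 9)))
})

test_that("skew -> autonomous collapse acts componentwise on P x X", {
  flow <- load_fixture("aging_growth_skew")
  aut <- skew_to_autonomous(flow)
  expect_equal(aut$evolve(1, c(1, 3)), c(2, 6))
  expect_equal(aut$evolve(0, c(1.4, 2.7)), c(1.4, 2.7))
  expect_true(all_verdicts_pass(check_axioms(aut, 200, seed = 10)))
  # semigroup residual of the collapse mirrors the cocycle residual
  emb <- process_to_skew(load_fixture("aging_growth_process"))
  aut2 <- skew_to_autonomous(emb)
  r1 <- check_axioms(emb, 200, seed = 11)$cocycle$max_residual
  r2 <- check_axioms(aut2, 200, seed = 11)$semigroup$max_residual
  expect_lt(abs(r1 - r2), 1e-12)
  # singleton base: the collapse is the fibre dynamics alongside a frozen p
  single <- skew_product_flow(1, function(l, p, x) x * exp(l),
                              autonomous_system(1, function(l, p) p,
                                                bounds = cbind(1, 1)),
                              bounds = cbind(0.1, 10))
  aut3 <- skew_to_autonomous(single)
  expect_equal(aut3$evolve(1, c(1, 1)), c(1, exp(1)), tolerance = 1e-12)
})
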