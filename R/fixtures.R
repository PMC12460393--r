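# Registry of built-in worked-example systems. Each fixture is constructed
# fresh on every load so objects are never shared between callers.

fixture_registry <- new.env(parent = emptyenv())

register_fixture <- function(name, description, builder) {
  assign(name, list(description = description, builder = builder),
         envir = fixture_registry)
}

#' List the built-in fixtures
#' @return a data frame with fixture names and one-line descriptions.
#' @export
list_fixtures <- function() {
  nms <- sort(ls(fixture_registry))
  data.frame(name = nms,
             description = vapply(nms, function(n)
               get(n, envir = fixture_registry)$description, ""))
}

#' Load a built-in fixture by name
#'
#' The registry ships one ready-made system per worked example used in the
#' documentation and tests: deterministic growth systems in all three
#' formalisms, shift spaces and Bernoulli schemes, random map systems, SDE
#' landscape models, a mass-action birth–death network and a two-gene
#' Boolean network.
#'
#' @param name fixture name; see [list_fixtures()].
#' @return the built system object (class depends on the fixture).
#' @export
load_fixture <- function(name) {
  if (!exists(name, envir = fixture_registry))
    stop_fd(sprintf("unknown fixture '%s'; available: %s", name,
                    paste(sort(ls(fixture_registry)), collapse = ", ")))
  get(name, envir = fixture_registry)$builder()
}

# ---- registrations ----------------------------------------------------------

register_fixture("exp_growth",
  "autonomous exponential growth theta(l, x) = x e^l on X = R>0",
  function() autonomous_system(
    1, function(l, x) x * exp(l),
    time = time_structure("continuous", origin = 0, sample_range = 2),
    bounds = cbind(0.1, 10), invertible = TRUE, name = "exp_growth"))

register_fixture("aging_growth_process",
  "nonautonomous growth phi((s,t), x) = (t/s) x; causal but not autonomous",
  function() process_system(
    1, function(s, t, x) (t / s) * x,
    time = time_structure("continuous", origin = 1, sample_range = 3),
    bounds = cbind(0.1, 10), name = "aging_growth_process"))

register_fixture("aging_growth_skew",
  "skew-product form of aging growth: phi(l, p, x) = ((l+p)/p) x over theta(l, p) = l + p",
  function() skew_product_flow(
    1, function(l, p, x) ((l + p) / p) * x,
    driving = autonomous_system(
      1, function(l, p) l + p,
      time = time_structure("continuous", origin = 1, sample_range = 3),
      bounds = cbind(0.5, 5), name = "time translation"),
    bounds = cbind(0.1, 10), name = "aging_growth_skew"))

register_fixture("shift_space",
  "left shift on bi-infinite binary sequences as an autonomous system",
  function() scheme_shift_system(bernoulli_scheme(c(0.5, 0.5), "two")))

register_fixture("bernoulli_2",
  "two-sided Bernoulli scheme with p = (1/2, 1/2)",
  function() bernoulli_scheme(c(0.5, 0.5), "two"))

register_fixture("random_quadratic_halving",
  "random map system f1(x) = x/2, f2(x) = x^2 on [0,1], one-sided fair driving",
  function() random_map_system(
    list(function(x) x / 2, function(x) x^2),
    domain = c(0, 1), p = c(0.5, 0.5), sided = "one",
    name = "random_quadratic_halving"))

register_fixture("affine_random_contraction",
  "random affine contraction f_b(x) = x/2 + b/2, b in {0, 1}, two-sided driving",
  function() random_map_system(
    list(function(x) x / 2, function(x) x / 2 + 1 / 2),
    domain = c(0, 1), p = c(0.5, 0.5), sided = "two",
    name = "affine_random_contraction"))

register_fixture("ou_process",
  "Ornstein-Uhlenbeck model: drift -x, unit diffusion, eps = 2 (stationary variance 1)",
  function() sde_model(
    drift = function(x, t, theta) -x, diffusion = 1, eps = 2, dim = 1L,
    positivity = "none", vectorized = TRUE))

register_fixture("double_well",
  "double-well landscape model: drift x - x^3 (potential x^4/4 - x^2/2), unit diffusion",
  function() sde_model(
    drift = function(x, t, theta) x - x^3, diffusion = 1, eps = 0.5, dim = 1L,
    positivity = "none", vectorized = TRUE))

register_fixture("birth_death",
  "mass-action birth-death network: 0 -> A at rate 2, A -> 0 at rate 1",
  function() reaction_network(nu = cbind(0, 1), nu_prime = cbind(1, 0),
                              k = c(2, 1), species = "A"))

register_fixture("net2_k1",
  "two-gene Boolean network g1' = NOT g2, g2' = g1 (single 4-cycle)",
  function() boolean_network(inputs = list(2L, 1L),
                             tables = list(c(1L, 0L), c(0L, 1L))))
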