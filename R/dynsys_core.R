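#' Autonomous deterministic dynamical system
#'
#' An autonomous system is a tuple \eqn{(X, L, \theta)}: a state space
#' \eqn{X \subseteq R^n}, a duration-length monoid \eqn{L}, and an evolution
#' map \eqn{\theta : L \times X \to X} satisfying the identity axiom
#' \eqn{\theta(0, x) = x} and the semigroup property
#' \eqn{\theta(l + m, x) = \theta(m, \theta(l, x))}. The map is supplied as
#' an opaque callable; the axioms are verified numerically by
#' [check_axioms()] on seeded samples.
#'
#' @param dim state dimension \eqn{n}.
#' @param evolve function `(l, x) -> x'` implementing \eqn{\theta}. Must be
#'   pure and deterministic.
#' @param time a [time_structure()] describing \eqn{L}.
#' @param bounds `dim x 2` matrix of lower/upper state-space bounds, also
#'   used as the sampling box for axiom checks. Rows are coordinates.
#' @param invertible whether negative duration lengths are admissible.
#'   By default only the nonnegative cone of \eqn{L} is used.
#' @param sample_state optional `function(n, seed)` returning `n` sampled
#'   states (a matrix with `n` rows, or a list for non-vector state spaces
#'   such as shift spaces). Defaults to uniform sampling in `bounds`.
#' @param state_distance optional `function(x, y)` returning a nonnegative
#'   residual used to compare states; defaults to the componentwise relative
#'   residual \eqn{\max_i |x_i - y_i| / (1 + |x_i|)}.
#' @param name optional label used in printing and reports.
#' @return an object of class `autonomous_system`.
#' @examples
#' sys <- autonomous_system(1, function(l, x) x * exp(l),
#'                          bounds = cbind(0.1, 10), name = "exponential growth")
#' evolve_autonomous(sys, 1, 1)
#' @export
autonomous_system <- function(dim, evolve, time = time_structure("continuous"),
                              bounds = cbind(rep(-1, dim), rep(1, dim)),
                              invertible = FALSE, sample_state = NULL,
                              state_distance = NULL, name = NULL) {
  stopifnot(is.function(evolve), inherits(time, "time_structure"))
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  if (nrow(bounds) != dim) stop_fd("`bounds` must have one row per state dimension")
  sys <- structure(list(dim = dim, evolve = evolve, time = time, bounds = bounds,
                        invertible = invertible, name = name,
                        sample_state = sample_state, state_distance = state_distance),
                   class = "autonomous_system")
  sys
}

#' @export
print.autonomous_system <- function(x, ...) {
  cat(sprintf("<autonomous_system>%s dim %d, %s time\n",
              if (is.null(x$name)) "" else paste0(" ", sQuote(x$name)),
              x$dim, x$time$kind))
  invisible(x)
}

#' Nonautonomous deterministic system (process formalism)
#'
#' A process is a tuple \eqn{(X, D, \phi)} with evolution map
#' \eqn{\phi : D \times X \to X} over the duration set
#' \eqn{D = \{(s,t) : s \le t\}}, satisfying the initial-value axiom
#' \eqn{\phi((t,t), x) = x} and causality
#' \eqn{\phi((s,t), x) = \phi((u,t), \phi((s,u), x))} for \eqn{s \le u \le t}.
#' Unlike an autonomous system, the dynamics may depend on the actual time
#' points, not just on the duration length.
#'
#' @param dim state dimension.
#' @param evolve function `(s, t, x) -> x'` implementing \eqn{\phi((s,t),x)}.
#' @inheritParams autonomous_system
#' @return an object of class `process_system`.
#' @examples
#' # a growing population whose growth rate decays with age: phi((s,t),x) = (t/s) x
#' proc <- process_system(1, function(s, t, x) (t / s) * x,
#'                        time = time_structure("continuous", origin = 1),
#'                        bounds = cbind(0.1, 10), name = "aging growth")
#' evolve_process(proc, 1, 2, 3)  # 6
#' @export
process_system <- function(dim, evolve, time = time_structure("continuous"),
                           bounds = cbind(rep(-1, dim), rep(1, dim)),
                           sample_state = NULL, state_distance = NULL, name = NULL) {
  stopifnot(is.function(evolve), inherits(time, "time_structure"))
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  if (nrow(bounds) != dim) stop_fd("`bounds` must have one row per state dimension")
  structure(list(dim = dim, evolve = evolve, time = time, bounds = bounds,
                 sample_state = sample_state, state_distance = state_distance,
                 name = name),
            class = "process_system")
}

#' @export
print.process_system <- function(x, ...) {
  cat(sprintf("<process_system>%s dim %d, %s time from t0 = %g\n",
              if (is.null(x$name)) "" else paste0(" ", sQuote(x$name)),
              x$dim, x$time$kind, x$time$origin))
  invisible(x)
}

#' Skew-product flow: a cocycle over a driving autonomous system
#'
#' A skew-product flow is a tuple \eqn{(X, \phi, (P, L, \theta))}: fibre
#' dynamics \eqn{\phi : L \times P \times X \to X} driven by an autonomous
#' system \eqn{\theta} on a parameter (base) space \eqn{P}. The cocycle
#' axioms are \eqn{\phi(0, p, x) = x} and
#' \eqn{\phi(t + s, p, x) = \phi(t, \theta(s, p), \phi(s, p, x))}.
#'
#' @param dim fibre state dimension.
#' @param cocycle function `(l, p, x) -> x'` implementing \eqn{\phi}.
#' @param driving an [autonomous_system()] on the parameter space `P`; its
#'   `evolve` is \eqn{\theta} and its state sampler supplies base points.
#' @inheritParams autonomous_system
#' @return an object of class `skew_product_flow`.
#' @examples
#' drv <- autonomous_system(1, function(l, p) l + p, bounds = cbind(0.5, 5))
#' flow <- skew_product_flow(1, function(l, p, x) ((l + p) / p) * x, drv,
#'                           bounds = cbind(0.1, 10))
#' evolve_skew(flow, 1, 1, 3)  # p' = 2, x' = 6
#' @export
skew_product_flow <- function(dim, cocycle, driving,
                              bounds = cbind(rep(-1, dim), rep(1, dim)),
                              sample_state = NULL, state_distance = NULL,
                              name = NULL) {
  stopifnot(is.function(cocycle), inherits(driving, "autonomous_system"))
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  if (nrow(bounds) != dim) stop_fd("`bounds` must have one row per state dimension")
  structure(list(dim = dim, cocycle = cocycle, driving = driving,
                 time = driving$time, bounds = bounds,
                 sample_state = sample_state, state_distance = state_distance,
                 name = name),
            class = "skew_product_flow")
}

#' @export
print.skew_product_flow <- function(x, ...) {
  cat(sprintf("<skew_product_flow>%s fibre dim %d over %s driving system\n",
              if (is.null(x$name)) "" else paste0(" ", sQuote(x$name)),
              x$dim, x$driving$time$kind))
  invisible(x)
}

# ---- evaluation -------------------------------------------------------------

check_in_bounds <- function(x, bounds, what = "state") {
  if (!is.numeric(x)) return(invisible(TRUE))  # structured states check themselves
  tol <- 1e-9
  if (any(x < bounds[, 1] - tol) || any(x > bounds[, 2] + tol))
    stop_fd(sprintf("%s (%s) outside declared bounds", what, fmt_num(x)))
  invisible(TRUE)
}

#' Evaluate the evolution map of an autonomous system
#'
#' Returns \eqn{\theta(l, x)}. Negative duration lengths are rejected unless
#' the system declares invertibility.
#' @param sys an [autonomous_system()].
#' @param l duration length.
#' @param x state.
#' @return the evolved state.
#' @export
evolve_autonomous <- function(sys, l, x) {
  stopifnot(inherits(sys, "autonomous_system"))
  if (l < 0 && !sys$invertible)
    stop_fd("negative duration length on a forward-only system")
  if (sys$time$kind == "discrete" && l != round(l))
    stop_fd("duration length must be an integer for discrete time")
  check_in_bounds(x, sys$bounds)
  sys$evolve(l, x)
}

#' Evaluate the evolution map of a process
#'
#' Returns \eqn{\phi((s, t), x)} for a duration \eqn{(s,t)} with
#' \eqn{s \le t}.
#' @param proc a [process_system()].
#' @param s,t initial and final time points, `s <= t`.
#' @param x state.
#' @return the evolved state.
#' @export
evolve_process <- function(proc, s, t, x) {
  stopifnot(inherits(proc, "process_system"))
  if (t < s) stop_fd("(s, t) is not a duration: t < s")
  check_in_bounds(x, proc$bounds)
  proc$evolve(s, t, x)
}

#' Evaluate a skew-product flow
#'
#' Drives the base point and the fibre state together: returns
#' \eqn{(\theta(l, p), \phi(l, p, x))}.
#' @param flow a [skew_product_flow()].
#' @param l duration length.
#' @param p base (parameter) point.
#' @param x fibre state.
#' @return a list with elements `p` (driven parameter) and `x` (fibre state).
#' @export
evolve_skew <- function(flow, l, p, x) {
  stopifnot(inherits(flow, "skew_product_flow"))
  if (l < 0 && !flow$driving$invertible)
    stop_fd("negative duration length on a forward-only flow")
  check_in_bounds(x, flow$bounds)
  list(p = flow$driving$evolve(l, p), x = flow$cocycle(l, p, x))
}

# ---- axiom checking ---------------------------------------------------------

axiom_report <- function(axiom, n, max_residual, tol, witness = NULL) {
  structure(list(axiom = axiom, n = n, max_residual = max_residual, tol = tol,
                 verdict = if (is.finite(max_residual) && max_residual <= tol)
                   "pass" else "fail",
                 witness = witness),
            class = "axiom_report")
}

#' @export
print.axiom_report <- function(x, ...) {
  cat(sprintf("<axiom_report> %-24s %s (max residual %.3g over %d samples, tol %.3g)\n",
              x$axiom, toupper(x$verdict), x$max_residual, x$n, x$tol))
  if (x$verdict == "fail" && !is.null(x$witness)) {
    cat("  worst witness: ", paste(names(x$witness),
                                   vapply(x$witness, fmt_num, ""),
                                   sep = " = ", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
format.axiom_report <- function(x, ...) {
  sprintf("%s: %s (residual %.3g)", x$axiom, x$verdict, x$max_residual)
}

# Run one sampled-residual sweep; any error inside `f` is recorded as a
# failing report with the offending tuple as witness.
sweep_axiom <- function(axiom, n, tol, tuples, f) {
  worst <- -Inf; witness <- NULL
  for (i in seq_len(n)) {
    res <- tryCatch(f(tuples[[i]]), error = function(e)
      list(residual = Inf, error = conditionMessage(e)))
    r <- res$residual
    if (r > worst) {
      worst <- r
      witness <- c(tuples[[i]]["show"][[1]] %||% tuples[[i]],
                   if (!is.null(res$error)) list(error = res$error))
    }
  }
  axiom_report(axiom, n, worst, tol, witness)
}

default_state_sampler <- function(obj) {
  if (!is.null(obj$sample_state)) return(obj$sample_state)
  bounds <- obj$bounds
  function(n, seed) local_seed(seed, {
    m <- matrix(stats::runif(n * nrow(bounds), bounds[, 1], bounds[, 2]),
                nrow = n, byrow = TRUE)
    m
  })
}

state_i <- function(states, i) {
  if (is.list(states)) states[[i]] else states[i, , drop = TRUE]
}

default_distance <- function(obj) obj$state_distance %||% rel_residual

#' Check the defining axioms of a dynamical system numerically
#'
#' Samples tuples of times/durations and states reproducibly from `seed` and
#' measures the worst relative residual \eqn{|lhs - rhs| / (1 + |lhs|)} of
#' each applicable axiom:
#' \itemize{
#'   \item autonomous systems: identity and the semigroup property;
#'   \item processes: initial value and causality, plus (on request)
#'     time-translation invariance — the property that distinguishes an
#'     autonomous system written in time-point form;
#'   \item skew-product flows: identity and the cocycle property.
#' }
#' Sampling-based checking is used because evolution maps are opaque
#' callables; a passing verdict certifies the axiom on the sampled tuples at
#' the given tolerance, not symbolically.
#'
#' @param system an [autonomous_system()], [process_system()] or
#'   [skew_product_flow()].
#' @param n_samples number of sampled tuples per axiom (>= 1).
#' @param seed integer seed for reproducible sampling.
#' @param tol nonnegative relative tolerance.
#' @param ... passed to methods; for processes, `translation_invariance = TRUE`
#'   adds the autonomy check.
#' @return a list of `axiom_report` objects, one per axiom, each with the
#'   axiom name, sample count, worst residual, tolerance, verdict and the
#'   worst-case witness tuple.
#' @examples
#' sys <- autonomous_system(1, function(l, x) x * exp(l), bounds = cbind(0.1, 10))
#' check_axioms(sys, n_samples = 100, seed = 1, tol = 1e-9)
#' @export
check_axioms <- function(system, n_samples = 100, seed = 1, tol = 1e-9, ...) {
  if (n_samples < 1) stop_fd("`n_samples` must be >= 1")
  if (tol < 0) stop_fd("`tol` must be nonnegative")
  UseMethod("check_axioms")
}

#' @rdname check_axioms
#' @export
check_axioms.autonomous_system <- function(system, n_samples = 100, seed = 1,
                                           tol = 1e-9, ...) {
  smp <- default_state_sampler(system)
  dist <- default_distance(system)
  reports <- list()

  if (system$time$has_identity) {
    xs <- smp(n_samples, sub_seed(seed, 11))
    tuples <- lapply(seq_len(n_samples), function(i)
      list(x = state_i(xs, i), show = list(l = 0, x = state_i(xs, i))))
    reports$identity <- sweep_axiom("identity", n_samples, tol, tuples, function(tp)
      list(residual = dist(tp$x, system$evolve(0, tp$x))))
  }

  ls <- sample_lengths(system$time, n_samples, sub_seed(seed, 12))
  ms <- sample_lengths(system$time, n_samples, sub_seed(seed, 13))
  xs <- smp(n_samples, sub_seed(seed, 14))
  tuples <- lapply(seq_len(n_samples), function(i)
    list(l = ls[i], m = ms[i], x = state_i(xs, i),
         show = list(l = ls[i], m = ms[i], x = state_i(xs, i))))
  reports$semigroup <- sweep_axiom("semigroup", n_samples, tol, tuples, function(tp) {
    lhs <- system$evolve(tp$l + tp$m, tp$x)
    rhs <- system$evolve(tp$m, system$evolve(tp$l, tp$x))
    list(residual = dist(lhs, rhs))
  })
  reports
}

#' @rdname check_axioms
#' @param translation_invariance for processes: also check time-translation
#'   invariance \eqn{\phi((s,t),x) = \phi((s+r, t+r), x)}, which holds iff
#'   the process is autonomous in disguise.
#' @export
check_axioms.process_system <- function(system, n_samples = 100, seed = 1,
                                        tol = 1e-9,
                                        translation_invariance = FALSE, ...) {
  smp <- default_state_sampler(system)
  dist <- default_distance(system)
  reports <- list()

  ts <- sample_times(system$time, n_samples, sub_seed(seed, 21))
  xs <- smp(n_samples, sub_seed(seed, 22))
  tuples <- lapply(seq_len(n_samples), function(i)
    list(t = ts[i], x = state_i(xs, i), show = list(s = ts[i], t = ts[i], x = state_i(xs, i))))
  reports$initial_value <- sweep_axiom("initial_value", n_samples, tol, tuples,
    function(tp) list(residual = dist(tp$x, system$evolve(tp$t, tp$t, tp$x))))

  ss <- sample_times(system$time, n_samples, sub_seed(seed, 23))
  l1 <- sample_lengths(system$time, n_samples, sub_seed(seed, 24))
  l2 <- sample_lengths(system$time, n_samples, sub_seed(seed, 25))
  xs <- smp(n_samples, sub_seed(seed, 26))
  tuples <- lapply(seq_len(n_samples), function(i)
    list(s = ss[i], u = ss[i] + l1[i], t = ss[i] + l1[i] + l2[i],
         x = state_i(xs, i),
         show = list(s = ss[i], u = ss[i] + l1[i], t = ss[i] + l1[i] + l2[i],
                     x = state_i(xs, i))))
  reports$causality <- sweep_axiom("causality", n_samples, tol, tuples, function(tp) {
    lhs <- system$evolve(tp$s, tp$t, tp$x)
    rhs <- system$evolve(tp$u, tp$t, system$evolve(tp$s, tp$u, tp$x))
    list(residual = dist(lhs, rhs))
  })

  if (translation_invariance) {
    ss <- sample_times(system$time, n_samples, sub_seed(seed, 27))
    ll <- sample_lengths(system$time, n_samples, sub_seed(seed, 28))
    rr <- sample_lengths(system$time, n_samples, sub_seed(seed, 29))
    xs <- smp(n_samples, sub_seed(seed, 30))
    tuples <- lapply(seq_len(n_samples), function(i)
      list(s = ss[i], t = ss[i] + ll[i], r = rr[i], x = state_i(xs, i),
           show = list(s = ss[i], t = ss[i] + ll[i], r = rr[i], x = state_i(xs, i))))
    reports$translation_invariance <-
      sweep_axiom("translation_invariance", n_samples, tol, tuples, function(tp) {
        lhs <- system$evolve(tp$s, tp$t, tp$x)
        rhs <- system$evolve(tp$s + tp$r, tp$t + tp$r, tp$x)
        list(residual = dist(lhs, rhs))
      })
  }
  reports
}

#' @rdname check_axioms
#' @export
check_axioms.skew_product_flow <- function(system, n_samples = 100, seed = 1,
                                           tol = 1e-9, ...) {
  smp <- default_state_sampler(system)
  psmp <- default_state_sampler(system$driving)
  dist <- default_distance(system)
  reports <- list()

  ps <- psmp(n_samples, sub_seed(seed, 31))
  xs <- smp(n_samples, sub_seed(seed, 32))
  tuples <- lapply(seq_len(n_samples), function(i)
    list(p = state_i(ps, i), x = state_i(xs, i),
         show = list(l = 0, p = state_i(ps, i), x = state_i(xs, i))))
  reports$identity <- sweep_axiom("identity", n_samples, tol, tuples, function(tp)
    list(residual = dist(tp$x, system$cocycle(0, tp$p, tp$x))))

  ss <- sample_lengths(system$time, n_samples, sub_seed(seed, 33))
  tt <- sample_lengths(system$time, n_samples, sub_seed(seed, 34))
  ps <- psmp(n_samples, sub_seed(seed, 35))
  xs <- smp(n_samples, sub_seed(seed, 36))
  tuples <- lapply(seq_len(n_samples), function(i)
    list(s = ss[i], t = tt[i], p = state_i(ps, i), x = state_i(xs, i),
         show = list(s = ss[i], t = tt[i], p = state_i(ps, i), x = state_i(xs, i))))
  reports$cocycle <- sweep_axiom("cocycle", n_samples, tol, tuples, function(tp) {
    lhs <- system$cocycle(tp$t + tp$s, tp$p, tp$x)
    rhs <- system$cocycle(tp$t, system$driving$evolve(tp$s, tp$p),
                          system$cocycle(tp$s, tp$p, tp$x))
    list(residual = dist(lhs, rhs))
  })
  reports
}

all_pass <- function(reports) all(vapply(reports, function(r) r$verdict, "") == "pass")

# ---- conversions between formalisms ----------------------------------------

#' Convert a translation-invariant process to duration-length form
#'
#' For a process whose dynamics depend only on the duration length
#' \eqn{l = t - s} (time-translation invariance), defines the autonomous
#' evolution \eqn{\theta(l, x) := \phi((s, s + l), x)} for any admissible
#' start time \eqn{s}. The construction is ill-defined for genuinely
#' nonautonomous processes, so translation invariance is verified first and
#' conversion is refused (with the failing witness) when it does not hold.
#'
#' @param proc a [process_system()].
#' @param n_samples,seed,tol parameters of the translation-invariance check.
#' @return an [autonomous_system()] with the same state space.
#' @export
duration_length_form <- function(proc, n_samples = 200, seed = 1, tol = 1e-9) {
  stopifnot(inherits(proc, "process_system"))
  rep <- check_axioms(proc, n_samples = n_samples, seed = seed, tol = tol,
                      translation_invariance = TRUE)$translation_invariance
  if (rep$verdict != "pass") {
    stop_fd(sprintf(paste0(
      "process is not time-translation invariant (residual %.3g > tol %.3g at ",
      "witness %s): the duration-length construction is ill-defined"),
      rep$max_residual, rep$tol,
      paste(names(rep$witness), vapply(rep$witness, fmt_num, ""),
            sep = " = ", collapse = ", ")))
  }
  t0 <- proc$time$origin
  autonomous_system(
    dim = proc$dim,
    evolve = function(l, x) proc$evolve(t0, t0 + l, x),
    time = proc$time, bounds = proc$bounds,
    sample_state = proc$sample_state, state_distance = proc$state_distance,
    name = if (is.null(proc$name)) NULL else paste0(proc$name, " (duration-length form)"))
}

#' Embed a process as a skew-product flow over its own time axis
#'
#' Any process can be read as a cocycle driven by time itself: the base
#' space is the time set with driving \eqn{\theta(l, s) = s + l}, and the
#' fibre map is \eqn{\phi(l, s, x) := \phi_{proc}((s, s + l), x)}. The
#' resulting flow satisfies the cocycle axiom exactly when the process
#' satisfies causality.
#'
#' @param proc a [process_system()].
#' @return a [skew_product_flow()].
#' @export
process_to_skew <- function(proc) {
  stopifnot(inherits(proc, "process_system"))
  tmin <- proc$time$origin
  driving <- autonomous_system(
    1, evolve = function(l, s) s + l, time = proc$time,
    bounds = cbind(tmin, tmin + proc$time$sample_range),
    name = "time translation")
  skew_product_flow(
    dim = proc$dim,
    cocycle = function(l, p, x) proc$evolve(p, p + l, x),
    driving = driving, bounds = proc$bounds,
    sample_state = proc$sample_state, state_distance = proc$state_distance,
    name = if (is.null(proc$name)) NULL else paste0(proc$name, " (skew form)"))
}

#' Collapse a skew-product flow to an autonomous system on P x X
#'
#' The associated skew product flow is the autonomous system on the product
#' space \eqn{P \times X} with
#' \eqn{\eta(l, (p, x)) = (\theta(l, p), \phi(l, p, x))}; its semigroup
#' property holds iff the cocycle property of the input holds.
#'
#' @param flow a [skew_product_flow()] whose base space is a real vector
#'   space (structured bases such as shift spaces cannot be concatenated
#'   with the fibre state).
#' @return an [autonomous_system()] of dimension `dim(P) + dim(X)`.
#' @export
skew_to_autonomous <- function(flow) {
  stopifnot(inherits(flow, "skew_product_flow"))
  pd <- flow$driving$dim
  xd <- flow$dim
  psmp <- default_state_sampler(flow$driving)
  xsmp <- default_state_sampler(flow)
  autonomous_system(
    dim = pd + xd,
    evolve = function(l, px) {
      p <- px[seq_len(pd)]; x <- px[pd + seq_len(xd)]
      c(flow$driving$evolve(l, p), flow$cocycle(l, p, x))
    },
    time = flow$time,
    bounds = rbind(flow$driving$bounds, flow$bounds),
    sample_state = function(n, seed)
      cbind(psmp(n, seed), xsmp(n, sub_seed(seed, 1))),
    name = if (is.null(flow$name)) "skew product flow"
           else paste0(flow$name, " (autonomous on P x X)"))
}
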