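#' Random map system
#'
#' A finite family of self-maps \eqn{(f_1, \ldots, f_n)} on a declared
#' interval/box, composed in the order dictated by a driving Bernoulli
#' scheme with matching alphabet size: the canonical construction of a
#' discrete-time random dynamical system. Each map is spot-checked to send
#' the declared domain into itself on a grid of sampled points.
#'
#' @param maps list of functions, each mapping the domain into itself.
#' @param domain numeric `c(lo, hi)` interval (or `d x 2` matrix for boxes).
#' @param p probability vector for the driving scheme; length must equal
#'   the number of maps.
#' @param sided sidedness of the driving scheme. One-sided driving matches
#'   forward composition; two-sided driving additionally supports pullback
#'   sampling through the past of the noise path.
#' @param name optional label.
#' @param n_check number of domain points for the into-domain spot check.
#' @return an object of class `random_map_system`.
#' @examples
#' rms <- random_map_system(list(function(x) x / 2, function(x) x^2),
#'                          domain = c(0, 1), p = c(0.5, 0.5))
#' omega <- sample_path(rms$scheme, 0, 9, seed = 7)
#' compose_cocycle(rms, 2, omega, 0.5)
#' @export
random_map_system <- function(maps, domain, p = rep(1 / length(maps), length(maps)),
                              sided = c("one", "two"), name = NULL,
                              n_check = 33) {
  sided <- match.arg(sided)
  if (!is.list(maps) || !all(vapply(maps, is.function, NA)))
    stop_fd("`maps` must be a list of functions")
  if (length(p) != length(maps))
    stop_fd("alphabet size (length of `p`) must equal the number of maps")
  domain <- matrix(as.numeric(domain), ncol = 2)
  grid <- seq(domain[1, 1], domain[1, 2], length.out = n_check)
  for (i in seq_along(maps)) {
    y <- vapply(grid, maps[[i]], 0)
    if (any(y < domain[1, 1] - 1e-12 | y > domain[1, 2] + 1e-12))
      stop_fd(sprintf("map %d does not send the domain into itself (f(%.4g) = %.4g)",
                      i, grid[which.max(abs(y))], y[which.max(abs(y))]))
  }
  structure(list(maps = maps, domain = domain,
                 scheme = bernoulli_scheme(p, sided), name = name),
            class = "random_map_system")
}

#' @export
print.random_map_system <- function(x, ...) {
  cat(sprintf("<random_map_system>%s %d maps on [%g, %g], %s-sided driving\n",
              if (is.null(x$name)) "" else paste0(" ", sQuote(x$name)),
              length(x$maps), x$domain[1, 1], x$domain[1, 2], x$scheme$sided))
  invisible(x)
}

#' Compose the cocycle of a random map system
#'
#' Evaluates \eqn{\phi(z, \omega, x) = f_{\omega(z-1)} \circ \cdots \circ
#' f_{\omega(0)}(x)}, with the convention \eqn{\phi(0, \omega, x) = x}.
#'
#' @param rms a [random_map_system()].
#' @param z nonnegative integer number of composition steps.
#' @param omega a [symbol_sequence()] readable on indices `0..z-1`.
#' @param x state in the declared domain.
#' @return the composed state.
#' @export
compose_cocycle <- function(rms, z, omega, x) {
  stopifnot(inherits(rms, "random_map_system"), inherits(omega, "symbol_sequence"))
  z <- as.integer(z)
  if (z < 0) stop_fd("`z` must be a nonnegative integer")
  if (any(x < rms$domain[, 1] - 1e-12) || any(x > rms$domain[, 2] + 1e-12))
    stop_fd(sprintf("state (%s) outside the declared domain", fmt_num(x)))
  if (z == 0L) return(x)
  syms <- seq_read(omega, 0:(z - 1L))
  if (any(syms < 1L | syms > length(rms$maps)))
    stop_fd("symbol outside the alphabet of the map family")
  for (s in syms) x <- rms$maps[[s]](x)
  x
}

#' Random dynamical system (perfect cocycle over a Bernoulli scheme)
#'
#' Bundles a driving [bernoulli_scheme()] with a cocycle
#' \eqn{\phi : L \times \Omega \times X \to X} that reads finitely many
#' symbols of the noise path. The cocycle is *perfect* when its composition
#' identity holds for every realization, which [check_perfect_cocycle()]
#' verifies on seeded samples.
#'
#' @param scheme the driving [bernoulli_scheme()].
#' @param cocycle function `(t, omega, x) -> x'` with `t` a nonnegative
#'   integer and `omega` a [symbol_sequence()].
#' @param domain state-space interval/box (`d x 2` matrix or `c(lo, hi)`).
#' @param dim fibre dimension.
#' @param name optional label.
#' @return an object of class `random_dynamical_system`.
#' @seealso [rds_from_maps()] for the map-composition construction.
#' @export
random_dynamical_system <- function(scheme, cocycle, domain, dim = 1L,
                                    name = NULL) {
  stopifnot(inherits(scheme, "bernoulli_scheme"), is.function(cocycle))
  domain <- matrix(as.numeric(domain), ncol = 2)
  structure(list(scheme = scheme, cocycle = cocycle, domain = domain,
                 dim = as.integer(dim), name = name),
            class = "random_dynamical_system")
}

#' @export
print.random_dynamical_system <- function(x, ...) {
  cat(sprintf("<random_dynamical_system>%s fibre dim %d over a %s-sided Bernoulli scheme (n = %d)\n",
              if (is.null(x$name)) "" else paste0(" ", sQuote(x$name)),
              x$dim, x$scheme$sided, x$scheme$n))
  invisible(x)
}

#' Build a random dynamical system from a random map system
#' @param rms a [random_map_system()].
#' @return a [random_dynamical_system()] whose cocycle is map composition.
#' @export
rds_from_maps <- function(rms) {
  stopifnot(inherits(rms, "random_map_system"))
  random_dynamical_system(
    scheme = rms$scheme,
    cocycle = function(t, omega, x) compose_cocycle(rms, t, omega, x),
    domain = rms$domain, dim = nrow(rms$domain), name = rms$name)
}

sample_domain <- function(domain, n, seed) {
  local_seed(seed, matrix(stats::runif(n * nrow(domain), domain[, 1], domain[, 2]),
                          nrow = n, byrow = TRUE))
}

#' Check the perfect-cocycle property of a random dynamical system
#'
#' Samples tuples \eqn{(s, t, \omega, x)} and verifies the identity
#' \eqn{\phi(0, \omega, x) = x} and the cocycle property
#' \eqn{\phi(t + s, \omega, x) = \phi(t, \theta(s, \omega), \phi(s, \omega, x))},
#' where \eqn{\theta} is the shift on the noise path. For symbol-driven map
#' compositions the residual is exactly zero; errors raised by the cocycle
#' are recorded as failures with the offending witness.
#'
#' @param rds a [random_dynamical_system()].
#' @param n_samples number of sampled tuples (>= 1).
#' @param seed integer seed.
#' @param tol nonnegative tolerance.
#' @return a list of two `axiom_report`s (`identity`, `cocycle`).
#' @export
check_perfect_cocycle <- function(rds, n_samples = 100, seed = 1, tol = 0) {
  stopifnot(inherits(rds, "random_dynamical_system"))
  if (n_samples < 1) stop_fd("`n_samples` must be >= 1")
  ss <- sample_lengths(rds$scheme$time, n_samples, sub_seed(seed, 41))
  tt <- sample_lengths(rds$scheme$time, n_samples, sub_seed(seed, 42))
  xs <- sample_domain(rds$domain, n_samples, sub_seed(seed, 43))
  omegas <- lapply(seq_len(n_samples), function(i)
    sample_path(rds$scheme, 0L, max(ss[i] + tt[i], 1L), sub_seed(seed, 100 + i)))

  tuples <- lapply(seq_len(n_samples), function(i)
    list(x = xs[i, ], omega = omegas[[i]],
         show = list(t = 0, omega_window = seq_read(omegas[[i]], 0:3), x = xs[i, ])))
  id_rep <- sweep_axiom("identity", n_samples, tol, tuples, function(tp)
    list(residual = rel_residual(tp$x, rds$cocycle(0L, tp$omega, tp$x))))

  tuples <- lapply(seq_len(n_samples), function(i)
    list(s = ss[i], t = tt[i], omega = omegas[[i]], x = xs[i, ],
         show = list(s = ss[i], t = tt[i],
                     omega_window = seq_read(omegas[[i]], 0:max(ss[i] + tt[i] - 1, 0)),
                     x = xs[i, ])))
  co_rep <- sweep_axiom("cocycle", n_samples, tol, tuples, function(tp) {
    lhs <- rds$cocycle(tp$t + tp$s, tp$omega, tp$x)
    rhs <- rds$cocycle(tp$t, shift_sequence(tp$omega, tp$s),
                       rds$cocycle(tp$s, tp$omega, tp$x))
    list(residual = max(abs(lhs - rhs)))
  })
  list(identity = id_rep, cocycle = co_rep)
}

#' Reduce a noise-independent random system to a deterministic one
#'
#' A random dynamical system whose cocycle does not depend on the noise
#' path (for instance when all maps coincide, or the parameter space is a
#' singleton) is a deterministic measurable system in disguise: define
#' \eqn{\hat\theta(t, x) := \phi(t, \omega^*, x)} for a fixed reference
#' path \eqn{\omega^*}. Noise-independence is decided by sampling: for
#' `n_probe` tuples \eqn{(t, x)} and pairs of independent paths the outputs
#' must agree within `tol`; any detected dependence refuses the conversion
#' with a concrete witness.
#'
#' @param rds a [random_dynamical_system()].
#' @param n_probe number of probe tuples.
#' @param seed integer seed.
#' @param tol tolerance for the independence probe.
#' @return an [autonomous_system()] with discrete time.
#' @export
degenerate_to_deterministic <- function(rds, n_probe = 50, seed = 1, tol = 1e-12) {
  stopifnot(inherits(rds, "random_dynamical_system"))
  ts <- sample_lengths(rds$scheme$time, n_probe, sub_seed(seed, 51))
  xs <- sample_domain(rds$domain, n_probe, sub_seed(seed, 52))
  for (i in seq_len(n_probe)) {
    w1 <- sample_path(rds$scheme, 0L, max(ts[i], 1L), sub_seed(seed, 200 + 2 * i))
    w2 <- sample_path(rds$scheme, 0L, max(ts[i], 1L), sub_seed(seed, 201 + 2 * i))
    y1 <- rds$cocycle(ts[i], w1, xs[i, ])
    y2 <- rds$cocycle(ts[i], w2, xs[i, ])
    if (max(abs(y1 - y2)) > tol) {
      stop_fd(sprintf(paste0(
        "cocycle depends on the noise path: phi(%d, omega1, %s) = %s but ",
        "phi(%d, omega2, %s) = %s (omega1 = %s..., omega2 = %s...)"),
        ts[i], fmt_num(xs[i, ]), fmt_num(y1), ts[i], fmt_num(xs[i, ]), fmt_num(y2),
        paste(seq_read(w1, 0:min(ts[i], 5)), collapse = ""),
        paste(seq_read(w2, 0:min(ts[i], 5)), collapse = "")))
    }
  }
  omega_ref <- sample_path(rds$scheme, 0L, 64L, sub_seed(seed, 53))
  autonomous_system(
    dim = rds$dim,
    evolve = function(l, x) rds$cocycle(as.integer(l), omega_ref, x),
    time = time_structure("discrete", origin = 0, sample_range = 5),
    bounds = rds$domain,
    name = if (is.null(rds$name)) "degenerate random system"
           else paste0(rds$name, " (deterministic reduction)"))
}

#' Push an ensemble of initial states through a random cocycle
#'
#' For each of `n_omega` seeded noise paths and each initial state, returns
#' \eqn{\phi(t, \omega, x)}. This is the raw material for empirical random
#' attractor estimation.
#'
#' @param rds a [random_dynamical_system()].
#' @param t nonnegative integer duration.
#' @param initial_states numeric matrix (rows are states) or vector.
#' @param n_omega number of noise paths (>= 1).
#' @param seed integer seed.
#' @return a data frame with columns `omega_id`, `state_id` and `x_1..x_d`.
#' @export
pushforward_ensemble <- function(rds, t, initial_states, n_omega, seed) {
  stopifnot(inherits(rds, "random_dynamical_system"))
  if (n_omega < 1) stop_fd("`n_omega` must be >= 1")
  X <- if (is.matrix(initial_states)) initial_states else matrix(initial_states, ncol = rds$dim)
  out <- vector("list", n_omega)
  for (w in seq_len(n_omega)) {
    omega <- sample_path(rds$scheme, 0L, max(as.integer(t), 1L), sub_seed(seed, w))
    Y <- t(apply(X, 1, function(x) rds$cocycle(as.integer(t), omega, x)))
    if (rds$dim == 1L) Y <- matrix(Y, ncol = 1)
    out[[w]] <- data.frame(omega_id = w, state_id = seq_len(nrow(X)), Y)
  }
  res <- do.call(rbind, out)
  names(res) <- c("omega_id", "state_id", paste0("x_", seq_len(rds$dim)))
  rownames(res) <- NULL
  res
}
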