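#' Mass-action reaction network
#'
#' A chemical reaction network over `N` molecular species: each reaction
#' \eqn{j} has reactant stoichiometry \eqn{\nu_j}, product stoichiometry
#' \eqn{\nu'_j} and a positive rate constant \eqn{k_j}. Under mass action,
#' the species formation rate function is
#' \deqn{f(s) = \sum_j k_j \prod_i x_i^{\nu_{ij}} (\nu'_j - \nu_j),}
#' with the convention \eqn{0^0 = 1}.
#'
#' @param nu,nu_prime `N x R` matrices of nonnegative integer reactant and
#'   product stoichiometries (columns are reactions).
#' @param k vector of `R` positive rate constants.
#' @param species optional species names.
#' @return an object of class `reaction_network`.
#' @examples
#' # birth-death: 0 -> A at rate 2, A -> 0 at rate 1
#' bd <- reaction_network(nu = cbind(0, 1), nu_prime = cbind(1, 0), k = c(2, 1))
#' species_formation_rate(bd, 3)  # 2 - 3 = -1
#' @export
reaction_network <- function(nu, nu_prime, k, species = NULL) {
  nu <- as.matrix(nu); nu_prime <- as.matrix(nu_prime)
  if (!all(dim(nu) == dim(nu_prime)))
    stop_fd("`nu` and `nu_prime` must have identical dimensions")
  if (any(nu < 0) || any(nu_prime < 0) || any(nu != round(nu)) ||
      any(nu_prime != round(nu_prime)))
    stop_fd("stoichiometries must be nonnegative integers")
  if (length(k) != ncol(nu) || any(k <= 0))
    stop_fd("`k` must hold one positive rate constant per reaction")
  structure(list(N = nrow(nu), R = ncol(nu), nu = nu, nu_prime = nu_prime,
                 k = as.numeric(k),
                 species = species %||% paste0("x", seq_len(nrow(nu)))),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d mass-action reactions\n", x$N, x$R))
  invisible(x)
}

#' Species formation rate under mass action
#'
#' Evaluates the net deterministic rate of change of each species:
#' \eqn{f(s) = \sum_j k_j \prod_i x_i^{\nu_{ij}} (\nu'_{ij} - \nu_{ij})}.
#'
#' @param net a [reaction_network()].
#' @param s nonnegative abundance vector of length `N`.
#' @param allow_negative permit negative abundances (useful when probing
#'   the rate function off-domain); default rejects them.
#' @return numeric rate vector of length `N`.
#' @export
species_formation_rate <- function(net, s, allow_negative = FALSE) {
  stopifnot(inherits(net, "reaction_network"))
  if (length(s) != net$N) stop_fd("state dimension mismatch")
  if (!allow_negative && any(s < 0))
    stop_fd("negative abundance; molecular abundances live on the nonnegative orthant")
  if (net$R == 0) return(numeric(net$N))
  rates <- vapply(seq_len(net$R), function(j)
    net$k[j] * prod(s^net$nu[, j]), 0)   # x^0 = 1 covers the 0^0 convention
  as.numeric((net$nu_prime - net$nu) %*% rates)
}

#' Integrate deterministic network dynamics
#'
#' Solves \eqn{ds/dt = F(s)} on the given grid with `deSolve`. `rate` may
#' be a [reaction_network()] (mass-action right-hand side) or any function
#' `s -> ds/dt`.
#'
#' @param rate rate function or [reaction_network()].
#' @param x0 initial state.
#' @param t_grid strictly increasing time grid.
#' @param method `deSolve` integrator (default `"lsoda"`).
#' @param atol,rtol integrator tolerances.
#' @return a matrix with the time grid in column 1 and one column per state
#'   variable (the `deSolve` layout).
#' @export
integrate_ode <- function(rate, x0, t_grid, method = "lsoda",
                          atol = 1e-10, rtol = 1e-10) {
  if (is.unsorted(t_grid, strictly = TRUE)) stop_fd("`t_grid` must be strictly increasing")
  F <- if (inherits(rate, "reaction_network"))
    function(s) species_formation_rate(rate, s, allow_negative = TRUE)
  else rate
  sol <- deSolve::ode(y = as.numeric(x0), times = t_grid,
                      func = function(t, y, parms) list(F(y)),
                      parms = NULL, method = method, atol = atol, rtol = rtol)
  diag <- attributes(sol)$istate
  if (nrow(sol) < length(t_grid))
    stop_fd(sprintf("integration failed after t = %g", sol[nrow(sol), 1]))
  unclass(sol)
}

# Finite-difference Jacobian wrapper (pracma); exposed internally only.
fd_jacobian <- function(f, x) pracma::jacobian(function(z) as.numeric(f(z)), x)

#' Locate fixed points and classify their stability
#'
#' Finds roots of the rate function from each starting guess (a BFGS
#' minimisation of \eqn{|f|^2} followed by Newton polishing with a
#' finite-difference Jacobian), deduplicates them, and classifies each
#' hyperbolic root by the real parts of its Jacobian eigenvalues: stable
#' when all are negative, unstable when any is positive, nonhyperbolic
#' when some real part lies within `eig_tol` of zero.
#'
#' @param rate rate function or [reaction_network()].
#' @param guesses list (or matrix rows, or vector for 1-D) of starting
#'   points; at least one.
#' @param tol residual tolerance: a candidate is accepted as a fixed point
#'   only when \eqn{\max |f(x^*)| \le tol}.
#' @param eig_tol half-width of the nonhyperbolic band around zero.
#' @return an object of class `fixed_point_report`: a list of records with
#'   `location`, `eigenvalues`, `classification` and `residual`. Empty when
#'   no guess converges.
#' @examples
#' rep <- find_fixed_points(function(x) x - x^3, guesses = c(-2, 0.1, 2))
#' sapply(rep$points, function(p) p$classification)
#' @export
find_fixed_points <- function(rate, guesses, tol = 1e-8, eig_tol = 1e-6) {
  F <- if (inherits(rate, "reaction_network"))
    function(s) species_formation_rate(rate, s, allow_negative = TRUE)
  else rate
  G <- if (is.matrix(guesses)) lapply(seq_len(nrow(guesses)), function(i) guesses[i, ])
  else if (is.list(guesses)) guesses
  else as.list(guesses)
  if (length(G) == 0) stop_fd("at least one guess is required")
  roots <- list()
  for (g in G) {
    x <- as.numeric(g)
    opt <- tryCatch(
      stats::optim(x, function(z) 0.5 * sum(as.numeric(F(z))^2), method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(opt)) x <- opt$par
    for (it in 1:25) {                       # Newton polish
      fx <- as.numeric(F(x))
      if (max(abs(fx)) < tol * 1e-3) break
      J <- fd_jacobian(F, x)
      dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) break
      x <- x + dx
    }
    fx <- as.numeric(F(x))
    if (!all(is.finite(fx)) || max(abs(fx)) > tol) next
    dup <- any(vapply(roots, function(r) max(abs(r$location - x)) < 1e-6, NA))
    if (isTRUE(dup)) next
    J <- fd_jacobian(F, x)
    ev <- eigen(J, only.values = TRUE)$values
    re <- Re(ev)
    cls <- if (any(abs(re) <= eig_tol)) "nonhyperbolic"
    else if (all(re < 0)) "stable" else "unstable"
    roots[[length(roots) + 1]] <- list(location = x, eigenvalues = ev,
                                       classification = cls,
                                       residual = max(abs(fx)))
  }
  structure(list(points = roots), class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat(sprintf("<fixed_point_report> %d fixed point(s)\n", length(x$points)))
  for (p in x$points)
    cat(sprintf("  x* = (%s): %s, Re(eigen) = (%s), |f| = %.2g\n",
                fmt_num(p$location), p$classification,
                fmt_num(Re(p$eigenvalues)), p$residual))
  invisible(x)
}

#' Stochastic differential equation model
#'
#' The Langevin-type model \eqn{dx = f(x; \theta, t)\,dt +
#' g(x; \theta, t)\,dW_t}, with drift \eqn{f}, diffusion \eqn{g} and Wiener
#' increments satisfying \eqn{E[dW_t] = 0},
#' \eqn{E[dW_t dW_s] = \epsilon\,\delta(t - s)}: the noise strength
#' \eqn{\epsilon} scales the increment variance, while `g` carries any
#' state dependence. The Ito interpretation is fixed (Euler–Maruyama
#' discretisation).
#'
#' @param drift function `f(x, t, theta)` returning a vector of length `d`.
#' @param diffusion function `g(x, t, theta)` (scalar, length-`d` vector or
#'   `d x d` matrix) or a constant.
#' @param eps noise strength \eqn{\epsilon \ge 0}.
#' @param theta parameter vector passed through to `drift`/`diffusion`.
#' @param dim state dimension `d`.
#' @param positivity `"none"` for models on all of \eqn{R^d}, or
#'   `"reflect"` to reflect excursions below zero back into the
#'   nonnegative orthant (molecular-abundance models).
#' @param vectorized if `TRUE`, `drift` and `diffusion` accept an
#'   `n_paths x d` matrix of states and return the same shape (fast path
#'   for path ensembles).
#' @return an object of class `sde_model`.
#' @export
sde_model <- function(drift, diffusion = 1, eps = 1, theta = NULL, dim = 1L,
                      positivity = c("none", "reflect"), vectorized = FALSE) {
  positivity <- match.arg(positivity)
  if (eps < 0) stop_fd("`eps` must be nonnegative")
  stopifnot(is.function(drift))
  structure(list(drift = drift, diffusion = diffusion, eps = eps,
                 theta = theta, dim = as.integer(dim), positivity = positivity,
                 vectorized = vectorized),
            class = "sde_model")
}

#' @export
print.sde_model <- function(x, ...) {
  cat(sprintf("<sde_model> d = %d, eps = %g, positivity = %s\n",
              x$dim, x$eps, x$positivity))
  invisible(x)
}

eval_diffusion <- function(model, X, t) {
  g <- model$diffusion
  if (!is.function(g)) return(g)
  g(X, t, model$theta)
}

#' Simulate an ensemble of SDE paths (Euler–Maruyama)
#'
#' Discretises \eqn{x_{k+1} = x_k + f(x_k)\Delta t +
#' g(x_k)\sqrt{\epsilon \Delta t}\,\xi_k} with \eqn{\xi_k} i.i.d. standard
#' normal, reproducibly from `seed`. With `diffusion = 0` every path equals
#' the deterministic Euler solution. Paths that leave the representable
#' range are flagged (`NaN`/overflow) and the run continues.
#'
#' @param model an [sde_model()].
#' @param x0 initial state: a vector of length `d` (shared by all paths) or
#'   an `n_paths x d` matrix.
#' @param t_grid strictly increasing time grid.
#' @param n_paths number of paths (>= 1).
#' @param seed integer seed.
#' @return an object of class `trajectory_ensemble`: list with `times`,
#'   `paths` (array `n_paths x n_times x d`), `flagged` (logical per path),
#'   `seed` and `model`.
#' @export
simulate_sde <- function(model, x0, t_grid, n_paths, seed) {
  stopifnot(inherits(model, "sde_model"))
  if (n_paths < 1) stop_fd("`n_paths` must be >= 1")
  if (is.unsorted(t_grid, strictly = TRUE)) stop_fd("`t_grid` must be strictly increasing")
  d <- model$dim
  nt <- length(t_grid)
  X <- if (is.matrix(x0)) x0 else matrix(rep(as.numeric(x0), each = n_paths),
                                         nrow = n_paths)
  if (ncol(X) != d || nrow(X) != n_paths) stop_fd("`x0` has the wrong shape")
  paths <- array(NA_real_, dim = c(n_paths, nt, d))
  paths[, 1, ] <- X
  local_seed(seed, {
    for (k in seq_len(nt - 1)) {
      dt <- t_grid[k + 1] - t_grid[k]
      tk <- t_grid[k]
      xi <- matrix(stats::rnorm(n_paths * d), n_paths, d)
      if (model$vectorized) {
        drift <- model$drift(X, tk, model$theta)
        gX <- eval_diffusion(model, X, tk)
        X <- X + drift * dt + gX * sqrt(model$eps * dt) * xi
      } else {
        for (i in seq_len(n_paths)) {
          fi <- as.numeric(model$drift(X[i, ], tk, model$theta))
          gi <- eval_diffusion(model, X[i, ], tk)
          noise <- if (is.matrix(gi)) as.numeric(gi %*% xi[i, ]) else gi * xi[i, ]
          X[i, ] <- X[i, ] + fi * dt + noise * sqrt(model$eps * dt)
        }
      }
      if (model$positivity == "reflect") X <- abs(X)
      paths[, k + 1, ] <- X
    }
  })
  flagged <- apply(paths, 1, function(p) any(!is.finite(p)))
  structure(list(times = t_grid, paths = paths, flagged = flagged,
                 seed = seed, model = model),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d paths x %d times x d = %d (%d flagged)\n",
              dim(x$paths)[1], dim(x$paths)[2], dim(x$paths)[3],
              sum(x$flagged)))
  invisible(x)
}

#' Population profile: histogram density of an ensemble
#'
#' Estimates the population profile \eqn{\rho(x, t)} at one time index, or
#' the pooled stationary profile \eqn{\rho(x)} over all times after a
#' burn-in fraction. Histogram binning on a user grid; the density is
#' normalized to integrate to 1 over the grid.
#'
#' @param ens a [trajectory_ensemble()] (1-D or 2-D state).
#' @param selection `list(time_index = k)` for a snapshot, or
#'   `list(pool = TRUE, burn_in = fraction)` for stationary pooling.
#' @param breaks bin edges: numeric vector (1-D) or list of two vectors
#'   (2-D).
#' @return an object of class `density_grid`: bin edges, midpoints, the
#'   density array and the sample count.
#' @export
estimate_density <- function(ens, selection, breaks) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  d <- dim(ens$paths)[3]
  if (d > 2) stop_fd("grid density estimation is implemented for d <= 2")
  keep <- !ens$flagged
  if (!is.null(selection$time_index)) {
    k <- selection$time_index
    if (k < 1 || k > dim(ens$paths)[2]) stop_fd("time index out of range")
    pts <- matrix(ens$paths[keep, k, ], ncol = d)
  } else if (isTRUE(selection$pool)) {
    burn <- selection$burn_in %||% 0.5
    ks <- seq_len(dim(ens$paths)[2])
    ks <- ks[ks > burn * length(ks)]
    pts <- matrix(ens$paths[keep, ks, ], ncol = d)
  } else stop_fd("`selection` must give a time_index or pool = TRUE")
  if (nrow(pts) == 0) stop_fd("empty selection")
  if (d == 1L) {
    edges <- if (is.list(breaks)) breaks[[1]] else breaks
    h <- diff(edges)
    idx <- findInterval(pts[, 1], edges, rightmost.closed = TRUE)
    inside <- idx >= 1 & idx <= length(h)
    counts <- tabulate(idx[inside], nbins = length(h))
    dens <- counts / (sum(counts) * h)
    structure(list(d = 1L, edges = list(edges),
                   mids = list((edges[-1] + edges[-length(edges)]) / 2),
                   density = dens, counts = counts, n = sum(counts)),
              class = "density_grid")
  } else {
    ex <- breaks[[1]]; ey <- breaks[[2]]
    hx <- diff(ex); hy <- diff(ey)
    ix <- findInterval(pts[, 1], ex, rightmost.closed = TRUE)
    iy <- findInterval(pts[, 2], ey, rightmost.closed = TRUE)
    inside <- ix >= 1 & ix <= length(hx) & iy >= 1 & iy <= length(hy)
    counts <- matrix(0, length(hx), length(hy))
    for (k in which(inside)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
    vol <- outer(hx, hy)
    dens <- counts / (sum(counts) * vol)
    structure(list(d = 2L, edges = list(ex, ey),
                   mids = list((ex[-1] + ex[-length(ex)]) / 2,
                               (ey[-1] + ey[-length(ey)]) / 2),
                   density = dens, counts = counts, n = sum(counts)),
              class = "density_grid")
  }
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> d = %d, %s bins, n = %d samples\n",
              x$d, paste(vapply(x$mids, length, 0L), collapse = " x "), x$n))
  invisible(x)
}

#' Quasi-potential landscape from a stationary density
#'
#' Computes \eqn{U_q(x) = -\ln \rho(x)} (proportionality constant fixed to
#' 1), regularized by a positive density floor so that \eqn{U_q} stays
#' finite where the histogram is empty, and shifted so \eqn{\min U_q = 0}
#' — only differences of the quasi-potential are meaningful. Local minima
#' of \eqn{U_q} are the valleys identified with cell fates.
#'
#' @param density a [estimate_density()] result.
#' @param floor positive density floor; defaults to `0.1 / (n * bin volume)`
#'   — a tenth of the density a single observation would contribute.
#' @return an object of class `quasipotential_grid` with the density, the
#'   quasi-potential array `U` and the floor used.
#' @export
quasipotential <- function(density, floor = NULL) {
  stopifnot(inherits(density, "density_grid"))
  vol <- if (density$d == 1L) mean(diff(density$edges[[1]]))
  else mean(outer(diff(density$edges[[1]]), diff(density$edges[[2]])))
  if (is.null(floor)) floor <- 0.1 / (density$n * vol)
  if (floor <= 0) stop_fd("`floor` must be positive")
  U <- -log(pmax(density$density, floor))
  U <- U - min(U)
  structure(list(d = density$d, edges = density$edges, mids = density$mids,
                 rho = density$density, U = U, floor = floor),
            class = "quasipotential_grid")
}

#' @export
print.quasipotential_grid <- function(x, ...) {
  cat(sprintf("<quasipotential_grid> d = %d, max U_q = %.3g (floor %.3g)\n",
              x$d, max(x$U), x$floor))
  invisible(x)
}

#' Identify valleys (local minima) of a quasi-potential
#'
#' Discrete analogue of the stationarity condition at a fate: grid points
#' whose \eqn{U_q} value is strictly smaller than all axis neighbours,
#' merged when closer than `min_separation` (keeping the deeper valley).
#' A candidate only counts when the density estimate has local support —
#' the point and its neighbours must all lie above the regularization
#' floor — so isolated stray observations in empty regions of state space
#' cannot masquerade as fates. A constant landscape yields no valleys and
#' a degeneracy warning.
#'
#' @param qp a [quasipotential()] result.
#' @param min_separation merge radius in state units.
#' @return a data frame with valley locations (`x`, and `y` for 2-D),
#'   quasi-potential values `U` and grid indices.
#' @export
find_valleys <- function(qp, min_separation = 0) {
  stopifnot(inherits(qp, "quasipotential_grid"))
  if (max(qp$U) - min(qp$U) < 1e-12) {
    warning("quasi-potential is constant: no valleys (degenerate landscape)")
    return(data.frame(x = numeric(0), U = numeric(0), index = integer(0)))
  }
  supported <- qp$rho > qp$floor
  if (qp$d == 1L) {
    U <- qp$U
    n <- length(U)
    is_min <- vapply(seq_len(n), function(i) {
      nbi <- c(if (i > 1) i - 1, if (i < n) i + 1)
      all(supported[c(i, nbi)]) && all(U[i] < U[nbi])
    }, NA)
    idx <- which(is_min)
    vals <- data.frame(x = qp$mids[[1]][idx], U = U[idx], index = idx)
  } else {
    U <- qp$U
    nx <- nrow(U); ny <- ncol(U)
    idx <- which(vapply(seq_len(nx * ny), function(k) {
      i <- (k - 1) %% nx + 1; j <- (k - 1) %/% nx + 1
      nbk <- c(if (i > 1) k - 1, if (i < nx) k + 1,
               if (j > 1) k - nx, if (j < ny) k + nx)
      all(supported[c(k, nbk)]) && all(U[k] < U[nbk])
    }, NA))
    i <- (idx - 1) %% nx + 1; j <- (idx - 1) %/% nx + 1
    vals <- data.frame(x = qp$mids[[1]][i], y = qp$mids[[2]][j],
                       U = U[idx], index = idx)
  }
  vals <- vals[order(vals$U), , drop = FALSE]
  if (min_separation > 0 && nrow(vals) > 1) {
    loc <- as.matrix(vals[, setdiff(names(vals), c("U", "index")), drop = FALSE])
    keep <- 1L
    for (r in seq_len(nrow(vals))[-1]) {
      dmin <- min(sqrt(rowSums((loc[keep, , drop = FALSE] -
                                  matrix(loc[r, ], length(keep), ncol(loc),
                                         byrow = TRUE))^2)))
      if (dmin > min_separation) keep <- c(keep, r)
    }
    vals <- vals[keep, , drop = FALSE]
  }
  rownames(vals) <- NULL
  vals
}

#' Detect fate transitions between valleys along ensemble paths
#'
#' Assigns each trajectory point to the valley whose location lies within
#' `radius` (or to no valley), and emits a transition event
#' \eqn{V_i \to V_j} whenever consecutive valley memberships differ, with
#' the exit time from \eqn{V_i} and the entry time into \eqn{V_j}.
#'
#' @param ens a [trajectory_ensemble()].
#' @param valleys data frame from [find_valleys()] (columns `x`, optionally
#'   `y`).
#' @param radius nonnegative membership radius; valley neighbourhoods must
#'   not overlap at this radius.
#' @return a data frame with columns `path`, `from`, `to`, `exit_time`,
#'   `entry_time`; zero rows when fewer than two valleys exist.
#' @export
detect_transitions <- function(ens, valleys, radius) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  empty <- data.frame(path = integer(0), from = integer(0), to = integer(0),
                      exit_time = numeric(0), entry_time = numeric(0))
  if (nrow(valleys) < 2) return(empty)
  loc <- as.matrix(valleys[, intersect(c("x", "y"), names(valleys)), drop = FALSE])
  dd <- as.matrix(stats::dist(loc))
  diag(dd) <- Inf
  if (min(dd) <= 2 * radius)
    stop_fd(sprintf("valley neighbourhoods overlap at radius %g (min separation %.3g)",
                    radius, min(dd)))
  d <- dim(ens$paths)[3]
  events <- list()
  for (p in seq_len(dim(ens$paths)[1])) {
    if (ens$flagged[p]) next
    traj <- matrix(ens$paths[p, , ], ncol = d)
    # membership: nearest valley within radius, else 0
    mem <- integer(nrow(traj))
    for (v in seq_len(nrow(loc))) {
      dv <- sqrt(rowSums((traj - matrix(loc[v, ], nrow(traj), d, byrow = TRUE))^2))
      mem[dv <= radius] <- v
    }
    occ <- which(mem != 0L)
    if (length(occ) < 2) next
    mseq <- mem[occ]
    ch <- which(diff(mseq) != 0)
    for (c0 in ch) {
      events[[length(events) + 1]] <- data.frame(
        path = p, from = mseq[c0], to = mseq[c0 + 1],
        exit_time = ens$times[occ[c0]], entry_time = ens$times[occ[c0 + 1]])
    }
  }
  if (length(events) == 0) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Check the gradient/constant-diffusion time-reversibility condition
#'
#' Forward and backward transition paths between fates can only coincide
#' when the drift is purely a gradient field, \eqn{f = -\nabla U}, and the
#' diffusion is constant. The check is numerical: (a) `g` is evaluated at
#' all probe states and compared to its value at the first; (b) for
#' \eqn{d \ge 2} the finite-difference Jacobian of `f` must be symmetric
#' at every probe (equality of mixed partials is the local criterion for a
#' gradient field; every smooth 1-D drift is a gradient).
#'
#' @param model an [sde_model()].
#' @param probes matrix of probe states (rows), or a vector for 1-D.
#' @param tol nonnegative tolerance for both clauses.
#' @return a list of class `gradient_report` with `constant_diffusion`,
#'   `gradient_drift`, the worst residuals, and `verdict`
#'   (`"time-reversible form"` or `"irreversible"`).
#' @export
gradient_check <- function(model, probes, tol = 1e-6) {
  stopifnot(inherits(model, "sde_model"))
  P <- if (is.matrix(probes)) probes else matrix(as.numeric(probes), ncol = 1)
  if (ncol(P) != model$dim) stop_fd("probe dimension mismatch")
  g0 <- eval_diffusion(model, P[1, ], 0)
  g_res <- max(vapply(seq_len(nrow(P)), function(i)
    max(abs(eval_diffusion(model, P[i, ], 0) - g0)), 0))
  if (model$dim == 1L) {
    sym_res <- 0
  } else {
    sym_res <- max(vapply(seq_len(nrow(P)), function(i) {
      J <- fd_jacobian(function(x) model$drift(x, 0, model$theta), P[i, ])
      max(abs(J - t(J)))
    }, 0))
  }
  const_ok <- g_res <= tol
  grad_ok <- sym_res <= tol
  structure(list(constant_diffusion = const_ok, diffusion_residual = g_res,
                 gradient_drift = grad_ok, symmetry_residual = sym_res,
                 tol = tol,
                 verdict = if (const_ok && grad_ok) "time-reversible form"
                 else "irreversible"),
            class = "gradient_report")
}

#' @export
print.gradient_report <- function(x, ...) {
  cat(sprintf(paste0("<gradient_report> %s: constant diffusion %s (residual %.3g), ",
                     "gradient drift %s (residual %.3g)\n"),
              x$verdict, x$constant_diffusion, x$diffusion_residual,
              x$gradient_drift, x$symmetry_residual))
  invisible(x)
}
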