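#' Finite point-cloud stand-in for a compact set
#'
#' Attraction is quantified between finite point clouds: compactness is
#' modelled by finiteness, and the attraction of a bounded set is measured
#' by the cloud-to-cloud directed Hausdorff distance. The sampling error of
#' this surrogate is reported by the estimators, never hidden.
#'
#' @param x numeric vector (1-D cloud) or matrix with one point per row.
#' @return an object of class `point_cloud` (a matrix).
#' @examples
#' directed_hausdorff(point_cloud(c(0, 2)), point_cloud(0))  # 2
#' directed_hausdorff(point_cloud(0), point_cloud(c(0, 2)))  # 0 (asymmetry)
#' @export
point_cloud <- function(x) {
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  if (nrow(m) == 0) stop_fd("a point cloud must be nonempty")
  if (!all(is.finite(m))) stop_fd("point clouds must be finite")
  structure(m, class = c("point_cloud", "matrix"))
}

as_cloud <- function(x) if (inherits(x, "point_cloud")) x else point_cloud(x)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points in R^%d\n", nrow(x), ncol(x)))
  utils::head(unclass(x))
  invisible(x)
}

#' Directed (nonsymmetric) Hausdorff distance between point clouds
#'
#' Computes \eqn{d_H(V, W) = \sup_{v \in V} \inf_{w \in W} d(v, w)} exactly
#' over the finite clouds, with Euclidean metric. Zero iff every point of
#' `V` coincides with some point of `W`; not symmetric.
#'
#' @param V,W nonempty [point_cloud()]s (or coercible vectors/matrices) of
#'   equal dimension.
#' @return nonnegative scalar.
#' @export
directed_hausdorff <- function(V, W) {
  V <- as_cloud(V); W <- as_cloud(W)
  if (ncol(V) != ncol(W)) stop_fd("dimension mismatch between clouds")
  worst <- 0
  for (i in seq_len(nrow(V))) {
    d2 <- rowSums((W - matrix(V[i, ], nrow(W), ncol(W), byrow = TRUE))^2)
    worst <- max(worst, min(d2))
  }
  sqrt(worst)
}

hausdorff_sym <- function(V, W) max(directed_hausdorff(V, W),
                                    directed_hausdorff(W, V))

# Greedy deduplication of a cloud within tolerance `tol`.
dedup_cloud <- function(V, tol) {
  V <- as_cloud(V)
  keep <- 1L
  for (i in seq_len(nrow(V))[-1]) {
    d2 <- rowSums((V[keep, , drop = FALSE] -
                     matrix(V[i, ], length(keep), ncol(V), byrow = TRUE))^2)
    if (min(d2) > tol^2) keep <- c(keep, i)
  }
  point_cloud(V[keep, , drop = FALSE])
}

#' Family of fibres of a nonautonomous set
#'
#' A nonautonomous (or random) set is stored fibre-wise: a mapping from a
#' fibre label (time point, base parameter, or noise-path id) to a
#' nonempty point cloud.
#'
#' @param labels vector of fibre labels.
#' @param clouds list of [point_cloud()]s, parallel to `labels`.
#' @return an object of class `set_fibres`.
#' @export
set_fibres <- function(labels, clouds) {
  if (length(labels) != length(clouds)) stop_fd("one cloud per label required")
  clouds <- lapply(clouds, as_cloud)
  structure(list(labels = labels, clouds = clouds), class = "set_fibres")
}

#' Look up one fibre of a nonautonomous set
#' @param fibres a [set_fibres()].
#' @param label a fibre label.
#' @return the fibre's [point_cloud()].
#' @export
fibre <- function(fibres, label) {
  stopifnot(inherits(fibres, "set_fibres"))
  i <- match(label, fibres$labels)
  if (is.na(i)) {
    # tolerate floating labels
    j <- which(abs(as.numeric(fibres$labels) - as.numeric(label)) < 1e-9)
    if (length(j) == 0) stop_fd(sprintf("missing fibre for label %s", format(label)))
    i <- j[1]
  }
  fibres$clouds[[i]]
}

convergence_report <- function(index, distance, tol, verdict, extra = list()) {
  structure(c(list(index = index, distance = distance,
                   final_distance = utils::tail(distance, 1),
                   monotone = all(diff(distance) <= 1e-12) || length(distance) < 2,
                   tol = tol, verdict = verdict),
              extra),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> %s: final distance %.3g (tol %.3g, %s trend, %d stages)\n",
              toupper(x$verdict), x$final_distance, x$tol,
              if (isTRUE(x$monotone)) "monotone" else "non-monotone",
              length(x$distance)))
  invisible(x)
}

verdict_from <- function(distance, tol) {
  fin <- utils::tail(distance, 1)
  if (fin <= tol) "pass"
  else if (length(distance) >= 2 && fin < distance[1]) "inconclusive"
  else "fail"
}

# Evolve a cloud rowwise through a 1-argument state map.
evolve_cloud <- function(V, f) {
  V <- as_cloud(V)
  out <- t(apply(V, 1, f))
  if (ncol(V) == 1L) out <- matrix(out, ncol = 1)
  point_cloud(out)
}

#' Estimate the global attractor of an autonomous system
#'
#' Iterates a bounded starting cloud forward in steps of `t_max / n_steps`,
#' and takes the final (deduplicated) cloud as the attractor estimate. The
#' report records the directed Hausdorff distance from each intermediate
#' cloud to the estimate, and an invariance residual
#' \eqn{\max(d_H(\theta(\Delta, A), A), d_H(A, \theta(\Delta, A)))} for one
#' further step. Divergence (cloud norm beyond `diverge_bound`) yields the
#' verdict `"no bounded attractor found"`.
#'
#' @param sys an [autonomous_system()].
#' @param B0 starting [point_cloud()] within bounds.
#' @param t_max total integration horizon.
#' @param n_steps number of evolution stages.
#' @param tol deduplication / convergence tolerance.
#' @param diverge_bound norm bound beyond which the orbit counts as divergent.
#' @return a list with elements `attractor` (a [point_cloud()]) and `report`
#'   (a `convergence_report` with `invariance_residual`).
#' @export
estimate_global_attractor <- function(sys, B0, t_max, n_steps = 30, tol = 1e-6,
                                      diverge_bound = 1e8) {
  stopifnot(inherits(sys, "autonomous_system"))
  B0 <- as_cloud(B0)
  dt <- t_max / n_steps
  if (sys$time$kind == "discrete") dt <- max(1, round(dt))
  clouds <- vector("list", n_steps + 1)
  clouds[[1]] <- B0
  for (k in seq_len(n_steps)) {
    clouds[[k + 1]] <- evolve_cloud(clouds[[k]], function(x) sys$evolve(dt, x))
    if (max(abs(clouds[[k + 1]])) > diverge_bound) {
      return(list(attractor = NULL,
                  report = convergence_report(
                    index = seq_len(k) * dt,
                    distance = rep(Inf, k), tol = tol,
                    verdict = "no bounded attractor found")))
    }
  }
  A <- dedup_cloud(clouds[[n_steps + 1]], tol)
  dists <- vapply(clouds[-length(clouds)], directed_hausdorff, 0, W = A)
  Anext <- evolve_cloud(A, function(x) sys$evolve(dt, x))
  inv_res <- hausdorff_sym(Anext, A)
  list(attractor = A,
       report = convergence_report(
         index = (0:(n_steps - 1)) * dt, distance = dists, tol = tol,
         verdict = verdict_from(dists, tol),
         extra = list(invariance_residual = inv_res)))
}

#' Forward convergence of a bounded set towards candidate fibres
#'
#' Measures forward attraction: for each horizon entry the bounded cloud is
#' evolved from the start and compared with the candidate fibre by the
#' directed Hausdorff distance — \eqn{d_H(\phi((s, t), B), A_t)} for a
#' process, or \eqn{d_H(\phi(t, p, B), A_{\theta(t, p)})} for a
#' skew-product flow (fibres indexed by the driven parameter).
#'
#' @param flow a [process_system()] or [skew_product_flow()].
#' @param B bounded starting [point_cloud()].
#' @param start initial time point (process) or base parameter (skew flow).
#' @param candidate a [set_fibres()] with a fibre at every horizon label.
#' @param horizon increasing vector of final times (process) or duration
#'   lengths (skew flow).
#' @param tol pass tolerance on the final distance.
#' @return a `convergence_report`.
#' @export
forward_convergence <- function(flow, B, start, candidate, horizon, tol = 1e-6) {
  B <- as_cloud(B)
  stopifnot(inherits(candidate, "set_fibres"))
  dists <- numeric(length(horizon))
  for (i in seq_along(horizon)) {
    t <- horizon[i]
    if (inherits(flow, "process_system")) {
      Bt <- evolve_cloud(B, function(x) flow$evolve(start, t, x))
      A <- fibre(candidate, t)
    } else if (inherits(flow, "skew_product_flow")) {
      Bt <- evolve_cloud(B, function(x) flow$cocycle(t, start, x))
      A <- fibre(candidate, flow$driving$evolve(t, start))
    } else stop_fd("`flow` must be a process or a skew-product flow")
    dists[i] <- directed_hausdorff(Bt, A)
  }
  convergence_report(horizon, dists, tol, verdict_from(dists, tol))
}

#' Pullback convergence: fixed target, receding start times
#'
#' Evolves the bounded cloud from progressively earlier start times to the
#' fixed target time and tracks the distance between successive arriving
#' clouds: the limit object is the pullback fibre \eqn{A_{target}}. The
#' verdict is `"pass"` when successive clouds have stabilized within `tol`,
#' `"inconclusive"` when distances still decrease at the deepest start
#' (pullback limits are asymptotic), `"fail"` when they grow.
#'
#' @param flow a [process_system()] (or [skew_product_flow()], where
#'   `starts` are interpreted as pullback depths \eqn{t} evolving from
#'   \eqn{\theta(-t, p)}; requires an invertible driving system).
#' @param B bounded starting [point_cloud()].
#' @param target fixed target time (process) or base parameter (skew flow).
#' @param starts vector of start times earlier than `target`, processed
#'   from the latest to the earliest.
#' @param tol stabilization tolerance.
#' @return a list with `fibre` (the final [point_cloud()] estimating
#'   \eqn{A_{target}}) and `report` (a `convergence_report` over successive
#'   distances).
#' @export
pullback_convergence <- function(flow, B, target, starts, tol = 1e-6) {
  B <- as_cloud(B)
  if (inherits(flow, "process_system")) {
    if (any(starts >= target)) stop_fd("all starts must be earlier than the target")
    starts <- sort(starts, decreasing = TRUE)  # progressively earlier
    clouds <- lapply(starts, function(s)
      evolve_cloud(B, function(x) flow$evolve(s, target, x)))
  } else if (inherits(flow, "skew_product_flow")) {
    if (!flow$driving$invertible)
      stop_fd("pullback through a skew flow needs an invertible driving system")
    starts <- sort(starts)  # depths, increasing
    clouds <- lapply(starts, function(k) {
      p_past <- flow$driving$evolve(-k, target)
      evolve_cloud(B, function(x) flow$cocycle(k, p_past, x))
    })
  } else stop_fd("`flow` must be a process or a skew-product flow")
  succ <- vapply(seq_len(length(clouds) - 1), function(i)
    hausdorff_sym(clouds[[i]], clouds[[i + 1]]), 0)
  if (length(succ) == 0) succ <- 0
  idx <- if (length(starts) >= 2) starts[-1] else starts
  list(fibre = dedup_cloud(clouds[[length(clouds)]], tol),
       report = convergence_report(idx, succ, tol, verdict_from(succ, tol)))
}

#' Estimate a random pullback attractor fibre at time zero
#'
#' Realizes one two-sided noise path \eqn{\omega} and, for each depth
#' \eqn{k}, transports the bounded cloud through the `k` past symbols
#' \eqn{\omega(-k), \ldots, \omega(-1)} up to index 0 — that is, evaluates
#' \eqn{\phi(k, \theta(-k, \omega), B)}. For a contracting system the
#' arriving clouds converge to the attractor fibre \eqn{A(\omega)}; the
#' deepest cloud is returned as the estimate. A single realization cannot
#' certify almost-sure statements; it estimates the fibre of the one
#' sampled path.
#'
#' @param rds a [random_dynamical_system()] with a two-sided driving scheme.
#' @param omega_seed seed realizing the noise path.
#' @param depths increasing vector of pullback depths.
#' @param B bounded starting [point_cloud()].
#' @param tol stabilization tolerance.
#' @return a list with `fibre` (the estimated \eqn{A(\omega)}), `omega`
#'   (the realized path) and `report`.
#' @export
random_pullback_estimate <- function(rds, omega_seed, depths, B, tol = 1e-9) {
  stopifnot(inherits(rds, "random_dynamical_system"))
  if (rds$scheme$sided != "two")
    stop_fd("random pullback estimation needs a two-sided driving scheme")
  depths <- sort(as.integer(depths))
  B <- as_cloud(B)
  omega <- sample_path(rds$scheme, -max(depths), max(depths), omega_seed)
  clouds <- lapply(depths, function(k)
    evolve_cloud(B, function(x) rds$cocycle(k, shift_sequence(omega, -k), x)))
  succ <- vapply(seq_len(length(clouds) - 1), function(i)
    hausdorff_sym(clouds[[i]], clouds[[i + 1]]), 0)
  if (length(succ) == 0) succ <- 0
  idx <- if (length(depths) >= 2) depths[-1] else depths
  list(fibre = dedup_cloud(clouds[[length(clouds)]], max(tol, 1e-12)),
       omega = omega,
       report = convergence_report(idx, succ, tol, verdict_from(succ, tol)))
}

#' Residence bookkeeping for long-transient diagnostics
#'
#' Segments a time-indexed trajectory into residence intervals relative to
#' a list of reference sets: the trajectory is "in" set \eqn{i} while
#' within distance `radius` of it. Long transients and quasistability are
#' read off the returned bookkeeping (long residences in a set that is not
#' a true attractor, followed by an exit). Reference sets that a single
#' point could match simultaneously at the given radius are rejected as
#' ambiguous.
#'
#' @param times increasing numeric vector of observation times.
#' @param states numeric matrix of trajectory states (rows parallel to
#'   `times`) or a vector for 1-D.
#' @param reference_sets list of [point_cloud()]s.
#' @param radius nonnegative residence radius.
#' @return a data frame with columns `set`, `entry_time`, `exit_time`
#'   (`NA` for an open residence at the end of the record) and `open`.
#' @export
transient_length <- function(times, states, reference_sets, radius) {
  if (is.unsorted(times)) stop_fd("`times` must be sorted increasingly")
  X <- if (is.matrix(states)) states else matrix(as.numeric(states), ncol = 1)
  sets <- lapply(reference_sets, as_cloud)
  ns <- length(sets)
  if (ns >= 2) {
    for (a in seq_len(ns - 1)) for (b in (a + 1):ns) {
      gap <- min(vapply(seq_len(nrow(sets[[a]])), function(i)
        min(sqrt(rowSums((sets[[b]] - matrix(sets[[a]][i, ], nrow(sets[[b]]),
                                             ncol(sets[[b]]), byrow = TRUE))^2))), 0))
      if (gap <= 2 * radius)
        stop_fd(sprintf(
          "reference sets %d and %d overlap at radius %g (separation %.3g)",
          a, b, radius, gap))
    }
  }
  member <- integer(nrow(X))
  for (k in seq_len(nrow(X))) {
    d <- vapply(sets, function(S) directed_hausdorff(X[k, , drop = FALSE], S), 0)
    member[k] <- if (min(d) <= radius) which.min(d) else 0L
  }
  runs <- rle(member)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1L
  res <- data.frame(set = runs$values, entry_time = times[begins],
                    exit_time = ifelse(ends < length(times), times[ends], NA),
                    open = ends >= length(times))
  res[res$set != 0L, , drop = FALSE]
}
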