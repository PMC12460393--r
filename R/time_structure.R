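#' Time structure of a dynamical system
#'
#' Represents the time set \eqn{T}, its duration set
#' \eqn{D = \{(s,t) : s \le t\}} and the duration-length set
#' \eqn{L = \{t - s : (s,t) \in D\}} used by evolution functions. Time is
#' either a continuous interval \eqn{[t_0, \infty)} or a discrete integer
#' range starting at \eqn{t_0}. The structure also carries a deterministic,
#' seed-parameterised sampling contract used by the axiom checkers: sampled
#' durations always satisfy \eqn{s \le t}, sampled duration lengths are
#' nonnegative (the monoid identity 0 is included when `has_identity`), and
#' discrete structures emit integers only.
#'
#' @param kind `"continuous"` or `"discrete"`.
#' @param origin the origin \eqn{t_0} of the time set.
#' @param has_identity whether the duration-length set contains the identity
#'   element 0. Almost all systems here are monoids; set `FALSE` for a
#'   strictly positive semigroup.
#' @param sample_range positive width of the window from which time points
#'   and duration lengths are sampled for axiom checking. Must be nonzero:
#'   a degenerate sampling window would make every check vacuous.
#' @return an object of class `time_structure`.
#' @examples
#' ts <- time_structure("continuous", origin = 1)
#' sample_durations(ts, 5, seed = 1)
#' @export
time_structure <- function(kind = c("continuous", "discrete"), origin = 0,
                           has_identity = TRUE, sample_range = 3) {
  kind <- match.arg(kind)
  if (!is.numeric(origin) || length(origin) != 1 || !is.finite(origin))
    stop_fd("`origin` must be a finite number")
  if (!is.numeric(sample_range) || sample_range <= 0)
    stop_fd("`sample_range` must be positive: a zero-length sampling window is a configuration error")
  if (kind == "discrete") {
    origin <- round(origin)
    sample_range <- max(1, round(sample_range))
  }
  structure(list(kind = kind, origin = origin, has_identity = has_identity,
                 sample_range = sample_range),
            class = "time_structure")
}

#' @export
print.time_structure <- function(x, ...) {
  cat(sprintf("<time_structure> %s, T = [%g, Inf)%s, sampling window %g\n",
              x$kind, x$origin,
              if (x$has_identity) ", L has identity 0" else ", L = positive cone",
              x$sample_range))
  invisible(x)
}

#' Sample duration lengths from a time structure
#'
#' Draws `n` elements of the duration-length set reproducibly from `seed`.
#' @param ts a [time_structure()].
#' @param n number of samples.
#' @param seed integer seed.
#' @return numeric vector of nonnegative duration lengths (integers for
#'   discrete structures).
#' @export
sample_lengths <- function(ts, n, seed) {
  stopifnot(inherits(ts, "time_structure"))
  local_seed(seed, {
    if (ts$kind == "discrete") {
      lo <- if (ts$has_identity) 0L else 1L
      sample(lo:ts$sample_range, n, replace = TRUE)
    } else {
      stats::runif(n, min = if (ts$has_identity) 0 else 1e-6, max = ts$sample_range)
    }
  })
}

#' Sample time points from a time structure
#' @inheritParams sample_lengths
#' @return numeric vector of time points in `[origin, origin + sample_range]`.
#' @export
sample_times <- function(ts, n, seed) {
  stopifnot(inherits(ts, "time_structure"))
  local_seed(seed, {
    if (ts$kind == "discrete") {
      ts$origin + sample(0:ts$sample_range, n, replace = TRUE)
    } else {
      stats::runif(n, ts$origin, ts$origin + ts$sample_range)
    }
  })
}

#' Sample durations (s, t) with s <= t
#' @inheritParams sample_lengths
#' @return a two-column matrix with columns `s` and `t`, `s <= t` rowwise.
#' @export
sample_durations <- function(ts, n, seed) {
  s <- sample_times(ts, n, seed)
  l <- sample_lengths(ts, n, sub_seed(seed, 1))
  cbind(s = s, t = s + l)
}
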