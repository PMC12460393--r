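# Independent oracles used to cross-check package implementations.

# Brute-force directed Hausdorff distance: explicit double loop.
oracle_directed_hausdorff <- function(V, W) {
  V <- as.matrix(V); W <- as.matrix(W)
  worst <- 0
  for (i in seq_len(nrow(V))) {
    best <- Inf
    for (j in seq_len(nrow(W)))
      best <- min(best, sqrt(sum((V[i, ] - W[j, ])^2)))
    worst <- max(worst, best)
  }
  worst
}

# Orbit-following oracle for Boolean networks: iterate bn_step from a state
# until a repeat, return the cycle (as state codes) and the terminal cycle's
# canonical key.
oracle_terminal_cycle <- function(net, s0) {
  seen <- integer(0)
  s <- s0
  code <- function(s) sum(as.integer(s) * 2L^(seq_along(s) - 1L))
  repeat {
    c0 <- code(s)
    hit <- match(c0, seen)
    if (!is.na(hit)) {
      cyc <- seen[hit:length(seen)]
      shift <- which.min(cyc)
      return(c(cyc[shift:length(cyc)], cyc[seq_len(shift - 1)]))
    }
    seen <- c(seen, c0)
    s <- bn_step(net, s)
  }
}

all_verdicts_pass <- function(reports)
  all(vapply(reports, function(r) r$verdict, "") == "pass")

# A process realizing the linear relaxation x' = -x + 1 in closed form.
relaxation_process <- function(origin = -100, range = 50) {
  process_system(
    1, function(s, t, x) exp(-(t - s)) * x + 1 - exp(-(t - s)),
    time = time_structure("continuous", origin = origin, sample_range = range),
    bounds = cbind(-5, 5), name = "relax to 1")
}
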