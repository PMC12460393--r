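#' Kauffman-style Boolean network
#'
#' A network of `N` binary genes, each reading `K` inputs through a Boolean
#' truth table of length \eqn{2^K}. Synchronous deterministic update: at
#' every step each gene simultaneously applies its table to the current
#' state, making the dynamics Markovian on \eqn{\{0,1\}^N}.
#'
#' Truth-table convention: for a gene with inputs \eqn{(i_1, \ldots, i_K)},
#' the table entry consulted is `1 + sum(b_j * 2^(j-1))` where \eqn{b_j} is
#' the current bit of input \eqn{i_j} — the first listed input is the least
#' significant bit.
#'
#' @param inputs list of `N` integer vectors, each of length `K` with
#'   entries in `1..N` (a gene may read itself).
#' @param tables list of `N` 0/1 vectors, each of length `2^K`.
#' @param seed optional construction seed recorded for provenance.
#' @return an object of class `boolean_network`.
#' @examples
#' # g1' = NOT g2, g2' = g1
#' net <- boolean_network(inputs = list(2L, 1L),
#'                        tables = list(c(1L, 0L), c(0L, 1L)))
#' bn_step(net, c(0, 0))  # (1, 0)
#' @export
boolean_network <- function(inputs, tables, seed = NULL) {
  N <- length(inputs)
  if (N < 1 || length(tables) != N)
    stop_fd("`inputs` and `tables` must have one entry per gene")
  K <- length(inputs[[1]])
  for (g in seq_len(N)) {
    if (length(inputs[[g]]) != K)
      stop_fd("all genes must have the same in-degree K")
    if (any(inputs[[g]] < 1L | inputs[[g]] > N))
      stop_fd(sprintf("gene %d has an input index outside 1..N", g))
    if (length(tables[[g]]) != 2^K)
      stop_fd(sprintf("gene %d: truth table must have length 2^K = %d", g, 2^K))
    if (any(!tables[[g]] %in% c(0L, 1L)))
      stop_fd(sprintf("gene %d: truth table entries must be 0/1", g))
  }
  structure(list(N = as.integer(N), K = as.integer(K),
                 inputs = lapply(inputs, as.integer),
                 tables = lapply(tables, as.integer), seed = seed),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("<boolean_network> N = %d genes, K = %d inputs each (state space size %d)\n",
              x$N, x$K, 2^x$N))
  invisible(x)
}

net_signature <- function(net) {
  paste(c(net$N, net$K, unlist(net$inputs), unlist(net$tables)), collapse = ",")
}

#' Number of Boolean maps with K inputs
#'
#' There are \eqn{2^{2^K}} Boolean functions of `K` inputs — the size of
#' the pool from which random networks draw their truth tables. The count
#' grows doubly exponentially (16 maps for K = 2, 256 for K = 3, ...).
#'
#' @param K nonnegative in-degree.
#' @return the count \eqn{2^{2^K}} (exact as a double for `K <= 5`).
#' @export
count_boolean_maps <- function(K) {
  if (length(K) != 1 || K < 0 || K != round(K)) stop_fd("`K` must be a nonnegative integer")
  2^(2^K)
}

#' Generate a random Boolean network
#'
#' Each gene receives `K` distinct input indices drawn uniformly without
#' replacement from the `N` genes (self-inputs allowed), and a truth table
#' drawn uniformly from the \eqn{2^{2^K}} Boolean maps. The construction is
#' random; the resulting network behaves deterministically.
#'
#' @param N number of genes.
#' @param K in-degree, `1 <= K <= N`.
#' @param seed integer seed; fixed `(N, K, seed)` always yields the same
#'   network.
#' @return a [boolean_network()].
#' @export
generate_random_network <- function(N, K, seed) {
  if (K < 1 || K > N) stop_fd("`K` must satisfy 1 <= K <= N")
  local_seed(seed, {
    inputs <- lapply(seq_len(N), function(g) sample.int(N, K))
    tables <- lapply(seq_len(N), function(g)
      sample(c(0L, 1L), 2^K, replace = TRUE))
    boolean_network(inputs, tables, seed = seed)
  })
}

#' One synchronous update step
#'
#' Every gene reads its `K` inputs from the current state and outputs its
#' truth-table value; all genes update simultaneously.
#'
#' @param net a [boolean_network()].
#' @param s 0/1 state vector of length `N`.
#' @return the updated 0/1 state vector.
#' @export
bn_step <- function(net, s) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(s) != net$N) stop_fd("state length must equal N")
  s <- as.integer(s)
  vapply(seq_len(net$N), function(g) {
    bits <- s[net$inputs[[g]]]
    net$tables[[g]][1L + sum(bits * 2L^(seq_along(bits) - 1L))]
  }, 0L)
}

# state code (0..2^N-1) <-> bit vector; bit of gene g is 2^(g-1)
state_to_code <- function(s) sum(as.integer(s) * 2L^(seq_along(s) - 1L))
code_to_state <- function(code, N) as.integer(bitwAnd(code, 2L^(0:(N - 1L))) > 0L)

# Vectorized transition table: next state code for every code 0..2^N-1.
transition_table <- function(net) {
  N <- net$N
  codes <- 0:(2^N - 1L)
  nxt <- integer(length(codes))
  for (g in seq_len(N)) {
    idx <- rep(1L, length(codes))
    ins <- net$inputs[[g]]
    for (j in seq_along(ins))
      idx <- idx + as.integer(bitwAnd(codes, 2L^(ins[j] - 1L)) > 0L) * 2L^(j - 1L)
    nxt <- nxt + net$tables[[g]][idx] * 2L^(g - 1L)
  }
  nxt
}

#' Exhaustive cycle and basin enumeration
#'
#' Builds the full synchronous state-transition graph on all \eqn{2^N}
#' states, identifies every cycle (the invariant sets that, once entered,
#' are never left) and assigns every state to the basin of the cycle its
#' forward orbit terminates in. Cycles are stored in canonical form,
#' rotated so the lexicographically smallest state comes first.
#'
#' @param net a [boolean_network()].
#' @param max_N refuse exhaustive enumeration beyond this many genes
#'   (default 20, about a million states); larger networks need trajectory
#'   sampling instead.
#' @return an object of class `cycle_set`: a list with `cycles` (list of
#'   integer state-code vectors), `basin` (cycle index for every state code,
#'   1-indexed by code + 1), `basin_sizes`, and the source network signature.
#' @export
enumerate_cycles <- function(net, max_N = 20L) {
  stopifnot(inherits(net, "boolean_network"))
  if (net$N > max_N)
    stop_fd(sprintf(paste0("N = %d exceeds the exhaustive enumeration limit (%d); ",
                           "use trajectory sampling for larger networks"),
                    net$N, max_N))
  nxt <- transition_table(net)
  n_states <- length(nxt)
  basin <- integer(n_states)      # 0 = unassigned, else cycle index
  on_path <- integer(n_states)    # walk id currently exploring the state
  cycles <- list()
  for (s0 in seq_len(n_states)) {
    if (basin[s0] != 0L) next
    path <- integer(0)
    cur <- s0
    while (basin[cur] == 0L && on_path[cur] != s0) {
      on_path[cur] <- s0
      path <- c(path, cur)
      cur <- nxt[cur] + 1L
    }
    if (basin[cur] == 0L) {
      # closed a new cycle at `cur`
      start <- match(cur, path)
      cyc <- path[start:length(path)] - 1L
      shift <- which.min(cyc)
      cyc <- c(cyc[shift:length(cyc)], cyc[seq_len(shift - 1L)])
      cycles[[length(cycles) + 1L]] <- cyc
      cid <- length(cycles)
    } else {
      cid <- basin[cur]
    }
    basin[path] <- cid
  }
  structure(list(cycles = cycles, basin = basin,
                 basin_sizes = tabulate(basin, nbins = length(cycles)),
                 signature = net_signature(net), N = net$N),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycle(s) over %d states\n",
              length(x$cycles), 2^x$N))
  for (i in seq_along(x$cycles))
    cat(sprintf("  cycle %d: length %d, basin size %d\n",
                i, length(x$cycles[[i]]), x$basin_sizes[i]))
  invisible(x)
}

#' Decode a cycle into its state vectors
#' @param cycles a `cycle_set` from [enumerate_cycles()].
#' @param i cycle index.
#' @return a matrix whose rows are the successive 0/1 states of the cycle.
#' @export
cycle_states <- function(cycles, i) {
  stopifnot(inherits(cycles, "cycle_set"))
  t(vapply(cycles$cycles[[i]], code_to_state, integer(cycles$N), N = cycles$N))
}

#' Return/transition probabilities under single-bit perturbations
#'
#' Quantifies the likelihood of returning to a cycle, or transitioning to
#' another one, following perturbations: for every state on every cycle and
#' every single-bit flip, the deterministic orbit of the flipped state is
#' followed to its terminal cycle. With the (cycle state, bit) perturbation
#' chosen uniformly, the result is a cycle-to-cycle transition probability
#' matrix whose rows sum to 1.
#'
#' @param net a [boolean_network()].
#' @param cycles the matching `cycle_set` from [enumerate_cycles()].
#' @return a `n_cycles x n_cycles` matrix of transition probabilities.
#' @export
perturbation_analysis <- function(net, cycles) {
  stopifnot(inherits(net, "boolean_network"), inherits(cycles, "cycle_set"))
  if (!identical(cycles$signature, net_signature(net)))
    stop_fd("`cycles` was computed from a different network")
  nc <- length(cycles$cycles)
  P <- matrix(0, nc, nc)
  for (i in seq_len(nc)) {
    for (code in cycles$cycles[[i]]) {
      for (g in seq_len(net$N)) {
        flipped <- bitwXor(code, 2L^(g - 1L))
        j <- cycles$basin[flipped + 1L]
        P[i, j] <- P[i, j] + 1
      }
    }
    P[i, ] <- P[i, ] / (length(cycles$cycles[[i]]) * net$N)
  }
  P
}
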