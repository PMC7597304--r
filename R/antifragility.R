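#' Configuration of the external-perturbation protocol
#'
#' External perturbations are transient flips of node states during the
#' dynamics (as opposed to *internal* perturbations, i.e. structural
#' mutations). At every time step whose index is a multiple of the
#' perturbation period `O`, a fresh uniformly chosen subset of `X` nodes is
#' flipped in the current state, and then the synchronous update is applied.
#' Complexity is measured over the post-transient window `t = T+1 ... 2T`.
#'
#' Defaults follow the standard protocol for networks of this size:
#' `T = 200` time steps (fragility curves converge quickly in `T`), `O = 1`
#' (perturb every step, the most discriminating choice), `s = 1000` initial
#' states, and `X` ranging over `1 ... N`.
#'
#' @param T window length in time steps (the run lasts `2T` steps).
#' @param O perturbation period in steps.
#' @param s number of random initial states to average over. When
#'   `2^N <= s` the full state space is enumerated instead.
#' @param seed master seed; all randomness (initial states, per-step flip
#'   subsets) descends from it through named substreams.
#' @param X_values integer vector of perturbed-node counts; default
#'   `1:N`, resolved when a network is supplied.
#' @return an object of class `perturbation_config`.
#' @export
perturbation_config <- function(T = 200L, O = 1L, s = 1000L, seed = 1L,
                                X_values = NULL) {
  T <- as.integer(T); O <- as.integer(O); s <- as.integer(s)
  if (T < 1L || O < 1L || s < 1L) stop("need T >= 1, O >= 1, s >= 1")
  structure(list(T = T, O = O, s = s, seed = as.integer(seed),
                 X_values = if (!is.null(X_values)) as.integer(X_values)),
            class = "perturbation_config")
}

#' Binary Shannon entropy
#'
#' `-(p log2 p + (1-p) log2 (1-p))` with the convention `0 * log2 0 = 0`.
#' This is the emergence of a single node whose fraction of ON states over
#' the observation window is `p`; it is 0 for a constant node and 1 for a
#' node that is ON half the time.
#'
#' @param p probability (or vector of probabilities) in `[0, 1]`.
#' @return entropy in bits, in `[0, 1]`.
#' @export
binary_entropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(q) ifelse(q > 0, -q * log2(q), 0)
  term(p) + term(1 - p)
}

#' Emergence, self-organization and complexity of a state window
#'
#' Emergence `E` quantifies *change* of gene-expression information: for
#' each node, the binary Shannon entropy of its ON/OFF frequencies over the
#' window, averaged over nodes. Self-organization `S = 1 - E` quantifies
#' *regularity*, and complexity `C = 4 * E * S` their balance; `C` is
#' maximal (1) at `E = 0.5` and zero at both extremes.
#'
#' @param window a `T x N` 0/1 matrix of states, rows ordered in time (as
#'   returned by [perturbed_window()] or [trajectory()]).
#' @return an object of class `complexity_measurement`: a list with per-node
#'   `p0`, `p1`, `E_i`, and network-level `E`, `S`, `C`.
#' @export
emergence <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) == 0L) stop("empty window")
  if (!all(window %in% c(0L, 1L))) stop("window must contain only 0/1 states")
  p1 <- colMeans(window)
  E_i <- binary_entropy(p1)
  E <- mean(E_i)
  structure(list(p0 = 1 - p1, p1 = p1, E_i = E_i, E = E, S = 1 - E,
                 C = complexity(E)),
            class = "complexity_measurement")
}

#' @export
print.complexity_measurement <- function(x, ...) {
  cat(sprintf("E = %.4f  S = %.4f  C = %.4f  (%d nodes)\n",
              x$E, x$S, x$C, length(x$E_i)))
  invisible(x)
}

#' Complexity from emergence
#'
#' `C = 4 * E * (1 - E)`, the normalized product of emergence and
#' self-organization.
#'
#' @param E emergence value(s) in `[0, 1]`.
#' @return complexity in `[0, 1]`.
#' @examples
#' complexity(0.5)   # 1, the maximum
#' complexity(0.612) # ~0.95
#' @export
complexity <- function(E) {
  if (any(E < 0 | E > 1)) stop("E must be in [0, 1]")
  4 * E * (1 - E)
}

#' Degree of external perturbation
#'
#' `delta_x = X / (N * O)`: the fraction of node-steps perturbed, used to
#' normalise fragility across network sizes.
#'
#' @param X number of perturbed nodes, `0 <= X <= N`.
#' @param N node count.
#' @param O perturbation period.
#' @return a value in `[0, 1]`.
#' @export
delta_x <- function(X, N, O = 1L) {
  if (X < 0 || X > N) stop("need 0 <= X <= N")
  if (O < 1) stop("O must be >= 1")
  X / (N * O)
}

# initial-state sample as an s x N 0/1 matrix; enumerates the full state
# space when it is no larger than s
initial_state_matrix <- function(N, s, seed) {
  total <- 2^N
  codes <- if (total <= s) {
    0:(total - 1L)
  } else {
    withr::with_seed(seed, sample.int(total, s) - 1L)
  }
  M <- matrix(0L, nrow = length(codes), ncol = N)
  for (i in seq_len(N))
    M[, i] <- bitwAnd(bitwShiftR(codes, i - 1L), 1L)
  M
}

# core engine: run 2T synchronous steps from every row of M, flipping a
# fresh random X-subset per run at every step index that is a multiple of O
# (flip first, then update); accumulate per-run per-node counts of ones over
# the recorded window t = T+1 .. 2T.  With record = TRUE (single run only)
# the recorded states themselves are returned.
run_window <- function(net, M, X, T, O, seed, record = FALSE) {
  s <- nrow(M); N <- ncol(M)
  X <- as.integer(X)
  if (X < 0L || X > N) stop("need 0 <= X <= N")
  ones <- matrix(0L, s, N)
  states <- if (record) matrix(0L, T, N)
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(2L * T)) {
      if (X > 0L && (t - 1L) %% O == 0L) {
        idx <- vapply(seq_len(s), function(r) sample.int(N, X), integer(X))
        lin <- cbind(rep(seq_len(s), each = X), as.vector(idx))
        M[lin] <- 1L - M[lin]
      }
      M <- step_matrix(net, M)
      if (t > T) {
        ones <- ones + M
        if (record) states[t - T, ] <- M[1L, ]
      }
    }
  })
  if (record) states else ones
}

# mean over runs of C = 4 E (1 - E), E the per-run node-mean binary entropy
mean_complexity <- function(ones, T) {
  E_i <- matrix(binary_entropy(ones / T), nrow = nrow(ones))
  E <- rowMeans(E_i)
  mean(4 * E * (1 - E))
}

#' Perturbed state-transition window of a single run
#'
#' Runs `2T` synchronous steps from `initial`; at every step whose index is
#' a multiple of `O` a fresh uniformly chosen `X`-subset of nodes is flipped
#' in the current state *before* the update, and the post-update states are
#' recorded. Returns the `T` states at `t = T+1 ... 2T` — the post-transient
#' window over which emergence is measured. With `X = 0` this is simply the
#' tail of the unperturbed trajectory.
#'
#' @param net a [boolean_network()].
#' @param initial initial state (0/1 vector or state string).
#' @param X number of nodes to flip per perturbation event (`0 <= X <= N`).
#' @param T window length.
#' @param O perturbation period.
#' @param seed integer seed for the flip draws.
#' @return a `T x N` 0/1 matrix of states.
#' @export
perturbed_window <- function(net, initial, X, T = 200L, O = 1L, seed = 1L) {
  if (is.character(initial)) initial <- state_from_string(initial)
  M <- matrix(as.integer(initial), nrow = 1L)
  if (ncol(M) != net$N) stop("invalid initial state length")
  run_window(net, M, X, as.integer(T), as.integer(O), seed, record = TRUE)
}

fragility_point <- function(net, X, config, M0, C0) {
  T <- config$T; O <- config$O
  if (X == 0L) {
    C <- C0
  } else {
    ones <- run_window(net, M0, X, T, O,
                       derive_seed(config$seed, "perturb", X))
    C <- mean_complexity(ones, T)
  }
  dx <- delta_x(X, net$N, O)
  dsigma <- C - C0
  data.frame(X = X, delta_x = dx, C0 = C0, C = C, delta_sigma = dsigma,
             fragility = -dsigma * dx)
}

#' Fragility / antifragility of a network under external perturbation
#'
#' The fragility value at perturbation intensity `X` is
#' `-(C - C0) * X / (N * O)`, where `C0` and `C` are the mean complexities
#' of the unperturbed and perturbed dynamics over the same `s` initial
#' states. A negative value means the network *gains* complexity under
#' perturbation (antifragile), zero means robust, positive fragile. Common
#' random numbers are used throughout: the initial states and the per-step
#' flip draws depend only on the configuration, never on the network, so
#' original-versus-mutant comparisons under one configuration are paired.
#'
#' @param net a [boolean_network()].
#' @param X number of perturbed nodes (`fragility`) — for `X = 0` the value
#'   is exactly 0.
#' @param config a [perturbation_config()].
#' @return `fragility`: a one-row data frame with columns `X`, `delta_x`,
#'   `C0`, `C`, `delta_sigma`, `fragility`. `fragility_curve`: a data frame
#'   with one such row per `X` in `config$X_values` (default `1:N`), of
#'   class `fragility_curve` with attribute `N`; the unperturbed baseline
#'   `C0` is computed once and shared across `X`.
#' @export
fragility <- function(net, X, config = perturbation_config()) {
  M0 <- initial_state_matrix(net$N, config$s, derive_seed(config$seed, "init"))
  ones0 <- run_window(net, M0, 0L, config$T, config$O, 0L)
  C0 <- mean_complexity(ones0, config$T)
  fragility_point(net, as.integer(X), config, M0, C0)
}

#' @rdname fragility
#' @export
fragility_curve <- function(net, config = perturbation_config()) {
  Xs <- if (is.null(config$X_values)) seq_len(net$N) else config$X_values
  if (any(Xs < 0L | Xs > net$N)) stop("X_values must lie in [0, N]")
  if (is.unsorted(Xs, strictly = TRUE)) stop("X_values must be increasing")
  M0 <- initial_state_matrix(net$N, config$s, derive_seed(config$seed, "init"))
  ones0 <- run_window(net, M0, 0L, config$T, config$O, 0L)
  C0 <- mean_complexity(ones0, config$T)
  rows <- lapply(Xs, function(X)
    fragility_point(net, as.integer(X), config, M0, C0))
  out <- do.call(rbind, rows)
  attr(out, "N") <- net$N
  class(out) <- c("fragility_curve", class(out))
  out
}

#' Interpolated original-minus-mutant antifragility difference curve
#'
#' Both fragility curves are piecewise-linearly interpolated onto `points`
#' evenly spaced normalized abscissae spanning `[1/N, 1]` (so curves from
#' networks of any size share one feature grid), and the mutant's values are
#' subtracted from the original's pointwise. The 30-value default is the
#' feature vector consumed by the classification pipeline.
#'
#' @param original,mutated [fragility_curve()]s over the same `N` and `X`
#'   grid.
#' @param points number of interpolation points (default 30).
#' @return an object of class `difference_curve`: a list with `values`
#'   (length `points`), `grid` (the normalized abscissae) and `N`.
#' @export
difference_curve <- function(original, mutated, points = 30L) {
  N <- attr(original, "N")
  if (!identical(N, attr(mutated, "N")))
    stop("incomparable curves: different N")
  if (!identical(original$X, mutated$X))
    stop("incomparable curves: different X grids")
  grid <- seq(1 / N, 1, length.out = points)
  xs <- original$X / N
  f_orig <- stats::approx(xs, original$fragility, xout = grid, rule = 2)$y
  f_mut <- stats::approx(xs, mutated$fragility, xout = grid, rule = 2)$y
  structure(list(values = f_orig - f_mut, grid = grid, N = N),
            class = "difference_curve")
}
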