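#' Construct a synchronous Boolean network
#'
#' A Boolean network is a set of `N` binary-state nodes, each updated
#' synchronously in discrete time by a fixed Boolean function of its input
#' nodes. The function of node `i` is stored as an explicit truth table of
#' length `2^k_i`, where `k_i` is the number of inputs of node `i`.
#'
#' Two fixed bit conventions are used throughout the package:
#' * In the integer encoding of a network state, node 1 is the *least*
#'   significant bit (see [encode_state()]).
#' * Within one node's truth table, the *first* listed input is the *most*
#'   significant bit of the row index: for inputs `(a, b)` the rows are
#'   ordered `a=0,b=0`, `a=0,b=1`, `a=1,b=0`, `a=1,b=1`.
#'
#' Nodes with zero inputs are legal and carry a one-entry truth table (a
#' constant function); link deletion can produce such nodes. Self-inputs are
#' allowed, parallel edges (a duplicated input index) are not.
#'
#' @param inputs list of integer vectors, one per node; `inputs[[i]]` are the
#'   (1-based) indices of the input nodes of node `i`, in truth-table order.
#' @param truth_tables list of 0/1 integer vectors; `truth_tables[[i]]` has
#'   length `2^length(inputs[[i]])`.
#' @param node_names optional character vector of node identifiers; defaults
#'   to `n1, n2, ...`.
#' @return An object of class `boolean_network` with fields `node_names`,
#'   `inputs`, `truth_tables` and `N`.
#' @examples
#' # two-node mutual activation: A <- B, B <- A
#' net <- boolean_network(inputs = list(2L, 1L),
#'                        truth_tables = list(c(0L, 1L), c(0L, 1L)),
#'                        node_names = c("A", "B"))
#' synchronous_step(net, c(1L, 0L))
#' @export
boolean_network <- function(inputs, truth_tables, node_names = NULL) {
  stopifnot(is.list(inputs), is.list(truth_tables),
            length(inputs) == length(truth_tables))
  N <- length(inputs)
  if (N < 1L) stop("a Boolean network needs at least one node")
  if (is.null(node_names)) node_names <- paste0("n", seq_len(N))
  if (length(node_names) != N) stop("node_names length must equal node count")
  if (anyDuplicated(node_names)) stop("duplicated node names")
  inputs <- lapply(inputs, function(x) as.integer(x))
  truth_tables <- lapply(truth_tables, function(x) as.integer(x))
  for (i in seq_len(N)) {
    k <- length(inputs[[i]])
    if (k > 0L && (any(inputs[[i]] < 1L) || any(inputs[[i]] > N)))
      stop(sprintf("node %d: input index out of range [1, %d]", i, N))
    if (anyDuplicated(inputs[[i]]))
      stop(sprintf("node %d: duplicated input (parallel edges are forbidden)", i))
    if (length(truth_tables[[i]]) != 2^k)
      stop(sprintf("node %d: truth table length %d, expected 2^%d = %d",
                   i, length(truth_tables[[i]]), k, 2^k))
    if (!all(truth_tables[[i]] %in% c(0L, 1L)))
      stop(sprintf("node %d: truth table entries must be 0 or 1", i))
  }
  structure(list(node_names = node_names, inputs = inputs,
                 truth_tables = truth_tables, N = N),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes, %d links\n", x$N,
              sum(lengths(x$inputs))))
  for (i in seq_len(min(x$N, 20L))) {
    cat(sprintf("  %s <- [%s]  table=%s\n", x$node_names[i],
                paste(x$node_names[x$inputs[[i]]], collapse = ","),
                paste(x$truth_tables[[i]], collapse = "")))
  }
  if (x$N > 20L) cat("  ...\n")
  invisible(x)
}

#' Number of states of an N-node Boolean network
#'
#' The synchronous state space of an `N`-node network has `2^N` states.
#'
#' @param N node count.
#' @return `2^N` as a double (exact for `N <= 52`).
#' @export
state_space_size <- function(N) {
  stopifnot(N >= 1)
  2^N
}

#' State encoding helpers
#'
#' A network state is a 0/1 vector of length `N`, node `i` at position `i`.
#' Its integer code places node 1 at the least significant bit. The string
#' form prints node states left to right, `"011"` meaning node1=0, node2=1,
#' node3=1.
#'
#' @param bits 0/1 integer vector.
#' @param code integer state code in `[0, 2^N)`.
#' @param N node count.
#' @param s character like `"011"`.
#' @return `encode_state`: integer code; `decode_state`: 0/1 vector;
#'   `state_to_string` / `state_from_string`: conversions to/from the printed
#'   form.
#' @export
encode_state <- function(bits) {
  bits <- as.integer(bits)
  stopifnot(all(bits %in% c(0L, 1L)))
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

#' @rdname encode_state
#' @export
decode_state <- function(code, N) {
  stopifnot(code >= 0, code < 2^N)
  as.integer(bitwAnd(bitwShiftR(as.integer(code), seq_len(N) - 1L), 1L))
}

#' @rdname encode_state
#' @export
state_to_string <- function(bits) paste(as.integer(bits), collapse = "")

#' @rdname encode_state
#' @export
state_from_string <- function(s) {
  bits <- as.integer(strsplit(s, "")[[1]])
  stopifnot(all(bits %in% c(0L, 1L)))
  bits
}

# truth-table row index (0-based) for one node given the full state vector;
# first input carries the highest weight 2^(k-1)
table_row <- function(input_idx, bits) {
  k <- length(input_idx)
  if (k == 0L) return(0L)
  as.integer(sum(bits[input_idx] * 2^(k - seq_len(k))))
}

#' Advance a Boolean network one synchronous time step
#'
#' Computes `v(t+1) = f(v(t))`: every node reads the current states of its
#' inputs and applies its truth table; all nodes update simultaneously.
#'
#' @param net a [boolean_network()].
#' @param state 0/1 vector of length `net$N` (or a state string, see
#'   [state_from_string()]).
#' @return the successor state as a 0/1 integer vector.
#' @export
synchronous_step <- function(net, state) {
  if (is.character(state)) state <- state_from_string(state)
  state <- as.integer(state)
  if (length(state) != net$N || !all(state %in% c(0L, 1L)))
    stop(sprintf("invalid state: need a 0/1 vector of length %d", net$N))
  out <- integer(net$N)
  for (i in seq_len(net$N)) {
    out[i] <- net$truth_tables[[i]][table_row(net$inputs[[i]], state) + 1L]
  }
  out
}

# vectorised synchronous update of m states at once; M is an m x N 0/1 matrix
step_matrix <- function(net, M) {
  out <- M
  for (i in seq_len(net$N)) {
    idx <- net$inputs[[i]]
    k <- length(idx)
    if (k == 0L) {
      out[, i] <- net$truth_tables[[i]][1L]
    } else {
      rows <- as.vector(M[, idx, drop = FALSE] %*% 2^(k - seq_len(k)))
      out[, i] <- net$truth_tables[[i]][rows + 1L]
    }
  }
  out
}

#' Synchronous trajectory of a Boolean network
#'
#' @param net a [boolean_network()].
#' @param initial initial state (0/1 vector or state string).
#' @param steps number of update steps (`>= 0`).
#' @return a `(steps+1) x N` 0/1 matrix; row `t+1` is the state at time `t`.
#' @export
trajectory <- function(net, initial, steps) {
  if (is.character(initial)) initial <- state_from_string(initial)
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 0L) stop("steps must be a non-negative integer")
  out <- matrix(0L, nrow = steps + 1L, ncol = net$N)
  out[1L, ] <- as.integer(initial)
  if (steps > 0L) {
    for (t in seq_len(steps)) out[t + 1L, ] <- synchronous_step(net, out[t, ])
  }
  dimnames(out) <- list(paste0("t", 0:steps), net$node_names)
  out
}

#' Generate a Kauffman NK random Boolean network
#'
#' Each node receives exactly `K` distinct inputs drawn uniformly from all
#' `N` nodes (self-inputs allowed), and its truth-table outputs are i.i.d.
#' Bernoulli(`bias`). The same `(N, K, bias, seed)` always yields the same
#' network.
#'
#' @param N node count.
#' @param K inputs per node, `1 <= K <= N`.
#' @param seed integer seed.
#' @param bias probability that a truth-table output is 1 (default 0.5).
#' @return a [boolean_network()].
#' @export
generate_rbn <- function(N, K, seed, bias = 0.5) {
  N <- as.integer(N); K <- as.integer(K)
  if (K < 1L || K > N) stop("need 1 <= K <= N")
  if (bias < 0 || bias > 1) stop("bias must be in [0, 1]")
  withr::with_seed(as.integer(seed), {
    inputs <- lapply(seq_len(N), function(i) sample.int(N, K))
    tabs <- lapply(seq_len(N), function(i)
      as.integer(stats::rbinom(2^K, 1L, bias)))
    boolean_network(inputs, tabs)
  })
}

#' Three-node example network with a known attractor landscape
#'
#' A small fixture whose synchronous state-transition graph has three
#' fixed-point attractors (`000`, `010`, `111`), one 2-cycle
#' (`{011, 110}`), and the states `100` and `101` in the basin of that
#' cycle. Useful for demonstrating attractor enumeration and for tests.
#'
#' @return a [boolean_network()] with `N = 3`.
#' @export
example_network <- function() {
  # desired successor map on state strings v1 v2 v3
  succ <- c("000" = "000", "001" = "010", "010" = "010", "011" = "110",
            "100" = "011", "101" = "110", "110" = "011", "111" = "111")
  inputs <- list(1:3, 1:3, 1:3)
  tabs <- lapply(1:3, function(i) integer(8L))
  for (s in names(succ)) {
    bits <- state_from_string(s)
    nxt <- state_from_string(succ[[s]])
    row <- table_row(1:3, bits)
    for (i in 1:3) tabs[[i]][row + 1L] <- nxt[i]
  }
  boolean_network(inputs, tabs, node_names = c("A", "B", "C"))
}

# canonical serialisation of a network: per node, inputs sorted ascending with
# the truth table re-indexed accordingly.  Two networks with the same node
# functions compare equal regardless of input ordering.
canonical_encoding <- function(net) {
  parts <- vapply(seq_len(net$N), function(i) {
    idx <- net$inputs[[i]]
    k <- length(idx)
    if (k == 0L) return(paste0("|", net$truth_tables[[i]]))
    ord <- order(idx)
    tt <- net$truth_tables[[i]]
    if (!identical(ord, seq_len(k))) {
      rows <- 0:(2^k - 1L)
      # bit of input j (weight 2^(k-j)) in each old row
      bits <- vapply(seq_len(k), function(j)
        bitwAnd(rows %/% 2^(k - j), 1L), integer(2^k))
      new_rows <- as.vector(bits[, ord, drop = FALSE] %*% 2^(k - seq_len(k)))
      tt2 <- integer(2^k)
      tt2[new_rows + 1L] <- tt
      tt <- tt2
    }
    paste0(paste(idx[ord], collapse = ","), "|", paste(tt, collapse = ""))
  }, character(1))
  paste(parts, collapse = ";")
}

# derive a reproducible sub-seed < 2^31 from a master seed and labels
derive_seed <- function(seed, ...) {
  lab <- paste(c(...), collapse = "/")
  v <- utf8ToInt(lab)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 1000003
  as.integer(((as.numeric(seed) %% 2000003) * 1009 + h + 1) %% 2147483647)
}
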