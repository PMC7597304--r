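#' Exhaustively enumerate attractors and basins of attraction
#'
#' Under the synchronous update every initial state converges to a unique
#' attractor (a fixed point or a limit cycle). This function assigns all
#' `2^N` states to their attractor exactly: the one-step successor of every
#' state is computed in vectorised integer arithmetic, the successor map is
#' composed with itself `N` times (giving `f^(2^N)`, whose image lies inside
#' the attractors since no transient exceeds `2^N` steps), and the resulting
#' in-attractor representatives are traced into cycles.
#'
#' Memory and time grow as `2^N`; `cap` guards against state-space explosion
#' (the default 26 is a practical upper limit for exhaustive enumeration —
#' `2^26` = 67,108,864 states).
#'
#' @param net a [boolean_network()].
#' @param cap maximum admissible node count (default 26).
#' @return An object of class `state_space_analysis`: a list with
#'   `attractors` (each a list with integer-coded `states` rotated to start
#'   at the smallest code, `length`, `canonical_key` = smallest state code,
#'   and `basin_size`), `basin_sizes`, and `N`. Basin sizes count the
#'   attractor's own states and sum to `2^N`.
#' @examples
#' an <- find_attractors(example_network())
#' attractor_count(an)
#' normalized_basin_entropy(an)
#' @export
find_attractors <- function(net, cap = 26L) {
  N <- net$N
  if (N > cap)
    stop(sprintf("network has %d nodes, exceeding the exhaustive cap of %d",
                 N, cap))
  total <- as.integer(2^N)
  codes <- 0:(total - 1L)
  succ <- integer(total)
  for (i in seq_len(N)) {
    idx <- net$inputs[[i]]
    k <- length(idx)
    if (k == 0L) {
      out <- rep.int(net$truth_tables[[i]][1L], total)
    } else {
      row <- integer(total)
      for (j in seq_len(k)) {
        row <- row + bitwAnd(bitwShiftR(codes, idx[j] - 1L), 1L) *
          as.integer(2^(k - j))
      }
      out <- net$truth_tables[[i]][row + 1L]
    }
    succ <- succ + out * as.integer(2^(i - 1L))
  }
  # g = f^(2^N): every state's image is inside its attractor
  g <- succ
  for (d in seq_len(N)) g <- g[g + 1L]
  reps <- unique(g)
  aid <- integer(total)
  cycles <- list()
  for (r in reps) {
    if (aid[r + 1L] != 0L) next
    cyc <- r
    s <- succ[r + 1L]
    while (s != r) { cyc <- c(cyc, s); s <- succ[s + 1L] }
    id <- length(cycles) + 1L
    cycles[[id]] <- cyc
    aid[cyc + 1L] <- id
  }
  state_aid <- aid[g + 1L]
  basin <- tabulate(state_aid, nbins = length(cycles))
  attractors <- lapply(seq_along(cycles), function(id) {
    cyc <- cycles[[id]]
    shift <- which.min(cyc)
    cyc <- c(cyc[shift:length(cyc)], cyc[seq_len(shift - 1L)])
    list(states = cyc, length = length(cyc), canonical_key = cyc[1L],
         basin_size = basin[id])
  })
  ord <- order(vapply(attractors, `[[`, integer(1), "canonical_key"))
  structure(list(attractors = attractors[ord],
                 basin_sizes = vapply(attractors[ord], `[[`, integer(1),
                                      "basin_size"),
                 N = N),
            class = "state_space_analysis")
}

#' @export
print.state_space_analysis <- function(x, ...) {
  cat(sprintf("State-space analysis: N=%d, %d attractors, H=%.4f\n", x$N,
              attractor_count(x), normalized_basin_entropy(x)))
  for (a in x$attractors) {
    cat(sprintf("  {%s}  length=%d  basin=%d\n",
                paste(vapply(a$states, function(s)
                  state_to_string(decode_state(s, x$N)), character(1)),
                  collapse = ", "),
                a$length, a$basin_size))
  }
  invisible(x)
}

#' State-space summary statistics
#'
#' @param analysis a `state_space_analysis` from [find_attractors()].
#' @return `attractor_count`: the number of attractors (`>= 1`);
#'   `mean_attractor_length`: the average cycle length (1 for a network with
#'   only fixed points).
#' @export
attractor_count <- function(analysis) length(analysis$attractors)

#' @rdname attractor_count
#' @export
mean_attractor_length <- function(analysis) {
  mean(vapply(analysis$attractors, `[[`, integer(1), "length"))
}

#' Normalized basin entropy
#'
#' The Shannon entropy of the basin-size distribution, divided by the node
#' count: `H = -sum(p * log2(p)) / N`, where `p` is each attractor's basin
#' size over `2^N`. `H` is 0 when a single attractor absorbs the whole state
#' space and 1 when every state is its own fixed point; it measures how
#' evenly the attractor landscape divides the state space (the versatility
#' of the modelled cell functions).
#'
#' @param analysis a `state_space_analysis` from [find_attractors()].
#' @return a number in `[0, 1]`.
#' @export
normalized_basin_entropy <- function(analysis) {
  p <- analysis$basin_sizes / 2^analysis$N
  p <- p[p > 0]
  -sum(p * log2(p)) / analysis$N
}

# set-of-state-sets identity for attractor comparison: one key per attractor,
# equal iff the attractors consist of the same states
attractor_key_set <- function(analysis) {
  vapply(analysis$attractors, function(a)
    paste(sort(a$states), collapse = ","), character(1))
}
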