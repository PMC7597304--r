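#' Describe one elementary internal perturbation (mutation)
#'
#' Four mutation kinds model elementary structural changes to a gene
#' regulatory network, leaving the node set untouched:
#' * `"add"` — add a regulatory link `source -> target`. The new input
#'   becomes the most significant truth-table row bit: rows where it is 0
#'   copy the original table, rows where it is 1 are filled with seeded
#'   random bits (`fill_seed`), so the unperturbed regime preserves the
#'   original function and a subsequent `delete` of the same link restores
#'   the network exactly.
#' * `"delete"` — remove the link `source -> target`; the truth table is
#'   projected onto the sub-table where the deleted input is 0.
#' * `"change"` — re-point the existing link `source -> target` to come from
#'   `new_source` instead, keeping the truth table (same arity, new wiring).
#' * `"flip"` — flip a single output bit of `target`'s truth table
#'   (`table_row`, 1-based).
#'
#' Self-links are allowed in all kinds; parallel edges never arise because a
#' source already wired to the target is not eligible for `add`/`change`.
#'
#' @param kind one of `"add"`, `"delete"`, `"change"`, `"flip"`.
#' @param target index of the regulated node.
#' @param source input node index (`add`: the new input; `delete`/`change`:
#'   the existing input concerned).
#' @param new_source replacement input index (`change` only).
#' @param table_row 1-based truth-table row to flip (`flip` only).
#' @param fill_seed integer seed for the random new table rows (`add` only).
#' @return an object of class `bn_mutation`.
#' @export
mutation <- function(kind = c("add", "delete", "change", "flip"),
                     target, source = NULL, new_source = NULL,
                     table_row = NULL, fill_seed = NULL) {
  kind <- match.arg(kind)
  need <- switch(kind,
                 add = c(source = TRUE, new_source = FALSE, table_row = FALSE,
                         fill_seed = TRUE),
                 delete = c(source = TRUE, new_source = FALSE,
                            table_row = FALSE, fill_seed = FALSE),
                 change = c(source = TRUE, new_source = TRUE,
                            table_row = FALSE, fill_seed = FALSE),
                 flip = c(source = FALSE, new_source = FALSE, table_row = TRUE,
                          fill_seed = FALSE))
  given <- c(source = !is.null(source), new_source = !is.null(new_source),
             table_row = !is.null(table_row), fill_seed = !is.null(fill_seed))
  if (!identical(unname(given), unname(need)))
    stop(sprintf("mutation kind '%s' requires exactly: %s", kind,
                 paste(names(need)[need], collapse = ", ")))
  structure(list(kind = kind, target = as.integer(target),
                 source = if (!is.null(source)) as.integer(source),
                 new_source = if (!is.null(new_source)) as.integer(new_source),
                 table_row = if (!is.null(table_row)) as.integer(table_row),
                 fill_seed = if (!is.null(fill_seed)) as.integer(fill_seed)),
            class = "bn_mutation")
}

#' @export
print.bn_mutation <- function(x, ...) {
  cat(sprintf("mutation[%s] target=%d%s%s%s\n", x$kind, x$target,
              if (!is.null(x$source)) sprintf(" source=%d", x$source) else "",
              if (!is.null(x$new_source)) sprintf(" new_source=%d",
                                                  x$new_source) else "",
              if (!is.null(x$table_row)) sprintf(" row=%d",
                                                 x$table_row) else ""))
  invisible(x)
}

#' Apply one mutation to a Boolean network
#'
#' Returns a new network with exactly one elementary change; the input
#' network is never modified. Node count is always preserved. An
#' inapplicable mutation (adding an already-present link, deleting from a
#' zero-input node, ...) raises an error naming the violated precondition.
#'
#' @param net a [boolean_network()].
#' @param m a [mutation()].
#' @return a new [boolean_network()].
#' @export
apply_mutation <- function(net, m) {
  stopifnot(inherits(m, "bn_mutation"))
  i <- m$target
  if (i < 1L || i > net$N) stop("mutation target out of range")
  inputs <- net$inputs
  tabs <- net$truth_tables
  k <- length(inputs[[i]])
  switch(m$kind,
    add = {
      if (m$source < 1L || m$source > net$N) stop("mutation source out of range")
      if (m$source %in% inputs[[i]])
        stop(sprintf("cannot add link %d -> %d: already an input",
                     m$source, i))
      new_rows <- withr::with_seed(m$fill_seed,
                                   as.integer(stats::rbinom(2^k, 1L, 0.5)))
      inputs[[i]] <- c(m$source, inputs[[i]])
      tabs[[i]] <- c(tabs[[i]], new_rows)
    },
    delete = {
      j <- match(m$source, inputs[[i]])
      if (is.na(j))
        stop(sprintf("cannot delete link %d -> %d: not an input", m$source, i))
      w <- as.integer(2^(k - j))
      keep <- which(bitwAnd((0:(2^k - 1L)) %/% w, 1L) == 0L)
      inputs[[i]] <- inputs[[i]][-j]
      tabs[[i]] <- tabs[[i]][keep]
    },
    change = {
      j <- match(m$source, inputs[[i]])
      if (is.na(j))
        stop(sprintf("cannot re-point link %d -> %d: not an input",
                     m$source, i))
      if (m$new_source < 1L || m$new_source > net$N)
        stop("mutation new_source out of range")
      if (m$new_source %in% inputs[[i]])
        stop(sprintf("cannot re-point link to %d -> %d: already an input",
                     m$new_source, i))
      inputs[[i]][j] <- m$new_source
    },
    flip = {
      if (m$table_row < 1L || m$table_row > length(tabs[[i]]))
        stop(sprintf("table_row %d out of range for node %d (table length %d)",
                     m$table_row, i, length(tabs[[i]])))
      tabs[[i]][m$table_row] <- 1L - tabs[[i]][m$table_row]
    })
  boolean_network(inputs, tabs, node_names = net$node_names)
}

# draw one random mutation of the given kind, or NULL if the kind is
# inapplicable to this network
draw_mutation <- function(net, kind) {
  N <- net$N
  deg <- lengths(net$inputs)
  switch(kind,
    add = {
      ok <- which(deg < N)
      if (length(ok) == 0L) return(NULL)
      t <- ok[sample.int(length(ok), 1L)]
      free <- setdiff(seq_len(N), net$inputs[[t]])
      mutation("add", t, source = free[sample.int(length(free), 1L)],
               fill_seed = sample.int(2147483646L, 1L))
    },
    delete = {
      ok <- which(deg >= 1L)
      if (length(ok) == 0L) return(NULL)
      t <- ok[sample.int(length(ok), 1L)]
      mutation("delete", t,
               source = net$inputs[[t]][sample.int(deg[t], 1L)])
    },
    change = {
      ok <- which(deg >= 1L & deg < N)
      if (length(ok) == 0L) return(NULL)
      t <- ok[sample.int(length(ok), 1L)]
      free <- setdiff(seq_len(N), net$inputs[[t]])
      mutation("change", t,
               source = net$inputs[[t]][sample.int(deg[t], 1L)],
               new_source = free[sample.int(length(free), 1L)])
    },
    flip = {
      t <- sample.int(N, 1L)
      mutation("flip", t,
               table_row = sample.int(length(net$truth_tables[[t]]), 1L))
    })
}

#' Sample a balanced cohort of distinct mutants
#'
#' Draws `n` mutants of `net`, distributing the four mutation kinds as
#' equally as possible (per-kind counts differ by at most one; which kinds
#' receive the remainder of `n %% 4` is randomised). Mutants are pairwise
#' distinct *as networks*: two different mutation descriptions that yield the
#' same node functions count once (comparison is by canonical encoding, with
#' each node's inputs sorted). If a kind becomes inapplicable or exhausted,
#' its remaining draws go to the other kinds; if fewer than `n` distinct
#' mutants can be found within the retry budget, an error is raised.
#'
#' @param net a [boolean_network()].
#' @param n cohort size (`>= 1`).
#' @param seed integer seed; identical `(net, n, seed)` yields an identical
#'   cohort.
#' @param max_tries per-draw retry budget before a kind is declared
#'   exhausted.
#' @return a list of `n` elements, each a list with `mutation` and
#'   `network`; the kind counts are available as `attr(, "kind_counts")`.
#' @export
sample_mutants <- function(net, n, seed, max_tries = 200L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  kinds <- c("add", "delete", "change", "flip")
  withr::with_seed(as.integer(seed), {
    quota <- rep.int(n %/% 4L, 4L)
    rem <- n %% 4L
    if (rem > 0L) {
      bump <- sample.int(4L, rem)
      quota[bump] <- quota[bump] + 1L
    }
    names(quota) <- kinds
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- vector("list", n)
    filled <- 0L
    exhausted <- character(0)
    while (filled < n) {
      active <- setdiff(kinds[quota > 0L], exhausted)
      if (length(active) == 0L) break
      for (kind in active) {
        if (quota[kind] == 0L) next
        got <- NULL
        for (try in seq_len(max_tries)) {
          m <- draw_mutation(net, kind)
          if (is.null(m)) break
          mut <- apply_mutation(net, m)
          key <- canonical_encoding(mut)
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          got <- list(mutation = m, network = mut)
          break
        }
        if (is.null(got)) {
          # kind inapplicable or exhausted: hand its remaining quota to the
          # kinds that can still produce fresh mutants
          spare <- quota[kind]
          quota[kind] <- 0L
          exhausted <- c(exhausted, kind)
          others <- setdiff(kinds, exhausted)
          if (length(others) == 0L && spare > 0L)
            stop(sprintf(
              "mutant exhaustion: only %d distinct mutants found, %d requested",
              filled, n))
          quota[others] <- quota[others] +
            as.integer(diff(round(seq(0, spare, length.out =
                                        length(others) + 1L))))
        } else {
          filled <- filled + 1L
          out[[filled]] <- got
          quota[kind] <- quota[kind] - 1L
        }
      }
    }
    if (filled < n)
      stop(sprintf(
        "mutant exhaustion: only %d distinct mutants found, %d requested",
        filled, n))
    counts <- table(factor(vapply(out, function(e) e$mutation$kind,
                                  character(1)), levels = kinds))
    structure(out, kind_counts = counts)
  })
}
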