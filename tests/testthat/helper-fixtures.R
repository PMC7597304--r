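# shared fixtures and independent oracles

constant_zero_network <- function(N) {
  boolean_network(inputs = replicate(N, 1L, simplify = FALSE),
                  truth_tables = replicate(N, c(0L, 0L), simplify = FALSE))
}

identity_network <- function(N) {
  boolean_network(inputs = as.list(seq_len(N)),
                  truth_tables = replicate(N, c(0L, 1L), simplify = FALSE))
}

# brute-force attractor oracle: compute each state's successor by direct
# per-state simulation and follow every initial state until a revisit.
# Independent of find_attractors both in successor computation (loops over
# synchronous_step instead of vectorised bit arithmetic) and in detection
# (per-state convergence instead of pointer doubling).
oracle_attractors <- function(net) {
  N <- net$N
  total <- 2^N
  succ <- vapply(0:(total - 1L), function(cd)
    encode_state(synchronous_step(net, decode_state(cd, N))), integer(1))
  aid <- integer(total)
  cycles <- list()
  for (st in 0:(total - 1L)) {
    if (aid[st + 1L] != 0L) next
    path <- integer(0)
    cur <- st
    while (aid[cur + 1L] == 0L && !(cur %in% path)) {
      path <- c(path, cur)
      cur <- succ[cur + 1L]
    }
    if (aid[cur + 1L] != 0L) {
      id <- aid[cur + 1L]
    } else {
      pos <- match(cur, path)
      id <- length(cycles) + 1L
      cycles[[id]] <- sort(path[pos:length(path)])
    }
    aid[path + 1L] <- id
  }
  basin <- tabulate(aid, nbins = length(cycles))
  keys <- vapply(cycles, paste, character(1), collapse = ",")
  list(keys = keys, basin_sizes = basin,
       entropy = { p <- basin / total; -sum(p * log2(p)) / N })
}

# key/basin representation of a state_space_analysis for oracle comparison
analysis_key_basins <- function(an) {
  keys <- vapply(an$attractors, function(a)
    paste(sort(a$states), collapse = ","), character(1))
  stats::setNames(an$basin_sizes, keys)
}

# random Boolean rule expression over the given variable names
random_bool_expr <- function(vars, depth = 3L) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.15) return(sample(c("0", "1"), 1L))
    return(sample(vars, 1L))
  }
  op <- sample(c("and", "or", "not"), 1L)
  if (op == "not") return(paste0("!(", random_bool_expr(vars, depth - 1L), ")"))
  paste0("(", random_bool_expr(vars, depth - 1L),
         if (op == "and") " & " else " | ",
         random_bool_expr(vars, depth - 1L), ")")
}

# evaluate a rule expression with base R as an oracle for the parser
eval_expr_oracle <- function(expr, env01) {
  rexpr <- gsub("\\b0\\b", "FALSE", gsub("\\b1\\b", "TRUE", expr))
  env <- lapply(env01, function(v) v == 1L)
  as.integer(eval(parse(text = rexpr), envir = env))
}

# imbalanced 4-class feature set with well-separated class-mean curves
separable_feature_set <- function(counts = c(60L, 200L, 90L, 30L),
                                  sd = 0.05, seed = 1L) {
  shapes <- list(function(x) 0.3 * sin(2 * pi * x),
                 function(x) 0.3 * x,
                 function(x) -0.3 * x,
                 function(x) 0.3 * cos(2 * pi * x))
  withr::with_seed(seed, {
    x <- seq(0, 1, length.out = 30)
    feats <- do.call(rbind, lapply(seq_along(counts), function(i)
      t(replicate(counts[i], shapes[[i]](x) + stats::rnorm(30, sd = sd)))))
    feature_dataset(feats, rep(robustness_classes(), counts),
                    rep("synthetic", sum(counts)))
  })
}

# fabricate a fragility_curve object from raw values (for interpolation tests)
fake_curve <- function(X, values, N) {
  out <- data.frame(X = X, delta_x = X / N, C0 = 0, C = 0,
                    delta_sigma = 0, fragility = values)
  attr(out, "N") <- N
  class(out) <- c("fragility_curve", class(out))
  out
}
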