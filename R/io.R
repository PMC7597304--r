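#' Read and write Boolean networks in plain-text formats
#'
#' Two dialects are supported.
#'
#' **Rule dialect** (`format = "bnet"`), one line per node, with an optional
#' `targets, factors` header and `#` comments:
#' ```
#' targets, factors
#' A, B & !C
#' B, A | 0
#' C, C
#' ```
#' Expressions use `&` (AND), `|` (OR), `!` (NOT), parentheses and the
#' constants `0`/`1`. Every rule is compiled to an explicit truth table at
#' load time; the node's input list is the order of first appearance of each
#' referenced node in its rule.
#'
#' **Table dialect** (`format = "table"`), one line per node, giving the
#' input names and the truth-table bits directly (first input = most
#' significant row-index bit):
#' ```
#' A, inputs=B;C, table=0010
#' B, inputs=, table=1
#' ```
#' The table dialect round-trips any network exactly, including truth tables
#' with inputs the function does not actually depend on; the rule dialect
#' writes a disjunctive normal form and therefore drops such dummy inputs on
#' re-reading.
#'
#' @param path file path.
#' @param format `"auto"` (detect by the presence of `inputs=`), `"bnet"` or
#'   `"table"`.
#' @param net a [boolean_network()].
#' @return `read_network` returns a [boolean_network()]; `write_network`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, format = c("auto", "bnet", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L) stop("empty network file: ", path)
  if (grepl("^\\s*targets\\s*,\\s*factors\\s*$", body[1], ignore.case = TRUE)) {
    body <- body[-1]; lineno <- lineno[-1]
  }
  if (length(body) == 0L) stop("no node definitions in ", path)
  if (format == "auto")
    format <- if (any(grepl("inputs\\s*=", body))) "table" else "bnet"
  if (format == "table") parse_table_dialect(body, lineno)
  else parse_bnet_dialect(body, lineno)
}

parse_table_dialect <- function(body, lineno) {
  names_ <- character(0); raw_inputs <- list(); tabs <- list()
  for (i in seq_along(body)) {
    m <- regmatches(body[i], regexec(
      "^\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*,\\s*inputs\\s*=\\s*([A-Za-z0-9_.;]*)\\s*,\\s*table\\s*=\\s*([01]+)\\s*$",
      body[i]))[[1]]
    if (length(m) == 0L)
      stop(sprintf("line %d: malformed table-dialect line: %s",
                   lineno[i], body[i]))
    names_ <- c(names_, m[2])
    ins <- strsplit(m[3], ";", fixed = TRUE)[[1]]
    raw_inputs[[i]] <- ins[nzchar(ins)]
    tabs[[i]] <- as.integer(strsplit(m[4], "")[[1]])
  }
  inputs <- lapply(seq_along(raw_inputs), function(i) {
    idx <- match(raw_inputs[[i]], names_)
    if (anyNA(idx))
      stop(sprintf("line %d: undeclared input node '%s'",
                   lineno[i], raw_inputs[[i]][which(is.na(idx))[1]]))
    idx
  })
  boolean_network(inputs, tabs, node_names = names_)
}

parse_bnet_dialect <- function(body, lineno) {
  split_at <- regexpr(",", body, fixed = TRUE)
  if (any(split_at < 0))
    stop(sprintf("line %d: expected 'name, expression'",
                 lineno[which(split_at < 0)[1]]))
  names_ <- trimws(substr(body, 1L, split_at - 1L))
  exprs <- trimws(substr(body, split_at + 1L, nchar(body)))
  bad <- !grepl("^[A-Za-z_][A-Za-z0-9_.]*$", names_)
  if (any(bad))
    stop(sprintf("line %d: invalid node name '%s'",
                 lineno[which(bad)[1]], names_[which(bad)[1]]))
  if (anyDuplicated(names_))
    stop("duplicated node definition: ", names_[duplicated(names_)][1])
  inputs <- vector("list", length(names_))
  tabs <- vector("list", length(names_))
  for (i in seq_along(exprs)) {
    ast <- tryCatch(parse_bool_expr(exprs[i]), error = function(e)
      stop(sprintf("line %d: %s", lineno[i], conditionMessage(e))))
    vars <- bool_expr_vars(ast)
    idx <- match(vars, names_)
    if (anyNA(idx))
      stop(sprintf("line %d: undeclared node '%s' in rule for '%s'",
                   lineno[i], vars[which(is.na(idx))[1]], names_[i]))
    inputs[[i]] <- idx
    tabs[[i]] <- materialize_truth_table(ast, vars)
  }
  boolean_network(inputs, tabs, node_names = names_)
}

# ---- Boolean rule expressions -------------------------------------------

tokenize_bool <- function(s) {
  toks <- list(); i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "|", "!", "(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch); i <- i + 1L
    } else if (ch %in% c("0", "1")) {
      toks[[length(toks) + 1L]] <- list(type = "const", value = as.integer(ch))
      i <- i + 1L
    } else if (grepl("[A-Za-z_]", ch)) {
      m <- regmatches(substr(s, i, n),
                      regexpr("^[A-Za-z_][A-Za-z0-9_.]*", substr(s, i, n)))
      toks[[length(toks) + 1L]] <- list(type = "ident", value = m)
      i <- i + nchar(m)
    } else {
      stop("unexpected character '", ch, "' in rule expression")
    }
  }
  toks
}

# grammar: expr := term ('|' term)* ; term := factor ('&' factor)* ;
#          factor := '!' factor | '(' expr ')' | ident | const
parse_bool_expr <- function(s) {
  toks <- tokenize_bool(s)
  if (length(toks) == 0L) stop("empty rule expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$type else NA_character_
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && peek() == "|") {
      advance(); node <- list(op = "or", l = node, r = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && peek() == "&") {
      advance(); node <- list(op = "and", l = node, r = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of rule expression")
    if (t == "!") { advance(); return(list(op = "not", l = parse_factor())) }
    if (t == "(") {
      advance(); node <- parse_expr()
      if (is.na(peek()) || peek() != ")") stop("missing closing parenthesis")
      advance(); return(node)
    }
    if (t == "ident") return(list(op = "var", name = advance()$value))
    if (t == "const") return(list(op = "const", value = advance()$value))
    stop("unexpected token '", t, "' in rule expression")
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop("trailing input after rule expression (token '", peek(), "')")
  out
}

bool_expr_vars <- function(ast) {
  switch(ast$op,
         var = ast$name,
         const = character(0),
         not = bool_expr_vars(ast$l),
         unique(c(bool_expr_vars(ast$l), bool_expr_vars(ast$r))))
}

eval_bool_expr <- function(ast, env) {
  switch(ast$op,
         var = env[[ast$name]],
         const = ast$value,
         not = 1L - eval_bool_expr(ast$l, env),
         and = eval_bool_expr(ast$l, env) * eval_bool_expr(ast$r, env),
         or = as.integer(eval_bool_expr(ast$l, env) +
                           eval_bool_expr(ast$r, env) > 0L))
}

# enumerate all 2^k rows (first variable = most significant bit)
materialize_truth_table <- function(ast, vars) {
  k <- length(vars)
  if (k == 0L) return(eval_bool_expr(ast, list()))
  rows <- 0:(2^k - 1L)
  vapply(rows, function(r) {
    env <- as.list(bitwAnd(r %/% 2^(k - seq_len(k)), 1L))
    names(env) <- vars
    eval_bool_expr(ast, env)
  }, integer(1))
}

# DNF expression for one node's truth table (rule dialect writer)
table_to_expression <- function(input_names, tt) {
  k <- length(input_names)
  if (all(tt == 0L)) return("0")
  if (all(tt == 1L)) return("1")
  ones <- which(tt == 1L) - 1L
  terms <- vapply(ones, function(r) {
    bits <- bitwAnd(r %/% 2^(k - seq_len(k)), 1L)
    lits <- ifelse(bits == 1L, input_names, paste0("!", input_names))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

#' @rdname read_network
#' @export
write_network <- function(net, path, format = c("bnet", "table")) {
  format <- match.arg(format)
  if (format == "table") {
    lines <- vapply(seq_len(net$N), function(i) {
      sprintf("%s, inputs=%s, table=%s", net$node_names[i],
              paste(net$node_names[net$inputs[[i]]], collapse = ";"),
              paste(net$truth_tables[[i]], collapse = ""))
    }, character(1))
  } else {
    lines <- c("targets, factors",
               vapply(seq_len(net$N), function(i) {
                 sprintf("%s, %s", net$node_names[i],
                         table_to_expression(net$node_names[net$inputs[[i]]],
                                             net$truth_tables[[i]]))
               }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}
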