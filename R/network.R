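#' @useDynLib ccgrn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile sd setNames runif
#' @importFrom utils read.csv write.csv head
NULL

# ---- rule expression parsing -------------------------------------------

# Tokenize a Boolean rule expression. Operators are !, &, | and
# parentheses; everything else (including ';', '/', ':') is part of an
# identifier, so gene names like "CYCD3;1" or "MYB3R1/4" are taken
# verbatim.
tokenize_rule <- function(text) {
  chars <- strsplit(text, "")[[1]]
  tokens <- character(0)
  buf <- character(0)
  flush <- function() {
    if (length(buf)) {
      tokens[[length(tokens) + 1L]] <<- paste(buf, collapse = "")
      buf <<- character(0)
    }
  }
  for (ch in chars) {
    if (ch %in% c("!", "&", "|", "(", ")")) {
      flush()
      tokens[[length(tokens) + 1L]] <- ch
    } else if (grepl("^\\s$", ch)) {
      flush()
    } else {
      buf[[length(buf) + 1L]] <- ch
    }
  }
  flush()
  tokens
}

# Recursive-descent parser producing an AST of nested lists:
# list(op = "and"|"or"|"not", args = ...) or list(op = "var", name = x) or
# list(op = "const", value = 0L/1L). Precedence: ! > & > |.
parse_rule_expression <- function(text) {
  tokens <- tokenize_rule(text)
  if (!length(tokens)) stop("empty rule expression", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  parse_or <- function() {
    left <- parse_and()
    while (identical(peek(), "|")) {
      advance()
      left <- list(op = "or", args = list(left, parse_and()))
    }
    left
  }
  parse_and <- function() {
    left <- parse_not()
    while (identical(peek(), "&")) {
      advance()
      left <- list(op = "and", args = list(left, parse_not()))
    }
    left
  }
  parse_not <- function() {
    if (identical(peek(), "!")) {
      advance()
      return(list(op = "not", args = list(parse_not())))
    }
    parse_atom()
  }
  parse_atom <- function() {
    tok <- advance()
    if (is.na(tok)) stop("unexpected end of rule expression", call. = FALSE)
    if (tok == "(") {
      inner <- parse_or()
      if (!identical(advance(), ")"))
        stop("unbalanced parentheses in rule expression", call. = FALSE)
      return(inner)
    }
    if (tok %in% c(")", "&", "|", "!"))
      stop("unexpected token '", tok, "' in rule expression", call. = FALSE)
    if (tok %in% c("0", "1"))
      return(list(op = "const", value = as.integer(tok)))
    list(op = "var", name = tok)
  }
  ast <- parse_or()
  if (pos <= length(tokens))
    stop("trailing tokens in rule expression: ",
         paste(tokens[pos:length(tokens)], collapse = " "), call. = FALSE)
  ast
}

ast_variables <- function(ast) {
  switch(ast$op,
    var = ast$name,
    const = character(0),
    unique(unlist(lapply(ast$args, ast_variables)))
  )
}

# Evaluate an AST over logical vectors bound in `env` (a named list).
eval_ast <- function(ast, env) {
  switch(ast$op,
    var = env[[ast$name]],
    const = rep(ast$value == 1L, length(env[[1]]) %||% 1L),
    not = !eval_ast(ast$args[[1]], env),
    and = eval_ast(ast$args[[1]], env) & eval_ast(ast$args[[2]], env),
    or = eval_ast(ast$args[[1]], env) | eval_ast(ast$args[[2]], env)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deparse an AST back to rule text (fully parenthesized binary ops).
deparse_ast <- function(ast) {
  switch(ast$op,
    var = ast$name,
    const = as.character(ast$value),
    not = paste0("!", wrap_operand(ast$args[[1]])),
    and = paste0(wrap_operand(ast$args[[1]], "and"), " & ",
                 wrap_operand(ast$args[[2]], "and")),
    or = paste0(wrap_operand(ast$args[[1]], "or"), " | ",
                wrap_operand(ast$args[[2]], "or"))
  )
}

wrap_operand <- function(ast, ctx = "not") {
  txt <- deparse_ast(ast)
  needs <- switch(ctx,
    not = ast$op %in% c("and", "or"),
    and = ast$op == "or",
    or = FALSE
  )
  if (needs) paste0("(", txt, ")") else txt
}

# ---- BooleanRule -------------------------------------------------------

#' Compile a Boolean rule to a truth table
#'
#' A rule is a Boolean expression over node identifiers using `!`, `&`,
#' `|` and parentheses. Its truth table has `2^k` rows over the `k`
#' distinct inputs (ordered by first occurrence in the expression); row
#' `j` holds the rule value on the assignment whose bit `i` (low bit =
#' first input) is input `i`'s value.
#'
#' @param target name of the regulated node.
#' @param expression rule text, e.g. `"E2Fa & !RBR"`.
#' @return an object of class `boolean_rule` with elements `target`,
#'   `expression`, `inputs` (character) and `table` (integer, length
#'   `2^k`).
#' @examples
#' r <- boolean_rule("E2Fb", "E2Fa & !RBR")
#' r$table # 0 1 0 0
#' @export
boolean_rule <- function(target, expression) {
  ast <- parse_rule_expression(expression)
  inputs <- ast_variables(ast)
  k <- length(inputs)
  if (k > 0) {
    idx <- 0:(2L^k - 1L)
    env <- setNames(
      lapply(seq_len(k) - 1L, function(b) bitwAnd(bitwShiftR(idx, b), 1L) == 1L),
      inputs
    )
    tab <- as.integer(eval_ast(ast, env))
  } else {
    tab <- as.integer(eval_ast(ast, setNames(list(logical(1)), "..dummy")))
  }
  structure(
    list(target = target, expression = deparse_ast(ast), ast = ast,
         inputs = inputs, table = tab),
    class = "boolean_rule"
  )
}

#' @export
print.boolean_rule <- function(x, ...) {
  cat(x$target, ", ", x$expression, "  [k = ", length(x$inputs), "]\n",
      sep = "")
  invisible(x)
}

# ---- LogicalNetwork ----------------------------------------------------

#' Construct a logical (Boolean) network
#'
#' @param rules named character vector or list mapping each node to its
#'   update expression; the element order fixes node order and hence bit
#'   positions in integer state codes (node 1 = low bit).
#' @param clamps optional named integer vector fixing nodes to 0/1
#'   (overriding their rules), as used for mutant simulation.
#' @return an object of class `boolean_network` with elements `nodes`,
#'   `rules` (list of [boolean_rule()]) and `clamps`.
#' @examples
#' net <- boolean_network(c(A = "!B", B = "!A"))
#' @export
boolean_network <- function(rules, clamps = integer(0)) {
  nodes <- names(rules)
  if (is.null(nodes) || any(!nzchar(nodes)))
    stop("rules must be a named vector/list (one expression per node)",
         call. = FALSE)
  if (anyDuplicated(nodes))
    stop("duplicate node name: ",
         nodes[duplicated(nodes)][1], call. = FALSE)
  compiled <- lapply(nodes, function(nd)
    boolean_rule(nd, as.character(rules[[nd]])))
  names(compiled) <- nodes
  for (r in compiled) {
    unknown <- setdiff(r$inputs, nodes)
    if (length(unknown))
      stop("rule for '", r$target, "' references unknown node '",
           unknown[1], "'", call. = FALSE)
  }
  net <- structure(
    list(nodes = nodes, rules = compiled, clamps = integer(0)),
    class = "boolean_network"
  )
  if (length(clamps)) net <- set_clamps(net, clamps)
  net
}

set_clamps <- function(net, clamps) {
  if (length(clamps)) {
    bad <- setdiff(names(clamps), net$nodes)
    if (length(bad)) stop("unknown node in clamps: ", bad[1], call. = FALSE)
    if (!all(clamps %in% 0:1)) stop("clamp values must be 0 or 1", call. = FALSE)
  }
  net$clamps <- clamps
  net
}

n_nodes <- function(net) length(net$nodes)

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", length(x$nodes), "nodes\n")
  for (r in x$rules) cat("  ", r$target, ", ", r$expression, "\n", sep = "")
  if (length(x$clamps))
    cat("Clamped:", paste(names(x$clamps), "=", x$clamps, collapse = ", "),
        "\n")
  invisible(x)
}

# ---- parse / serialize -------------------------------------------------

#' Parse a rule file in the "targets, factors" dialect
#'
#' The text format has a header line `targets, factors` followed by one
#' `node, expression` line per node. Comment lines start with `#`; blank
#' lines are ignored. Node names may contain `;` and `/`, which are never
#' treated as operators; the first comma on a line separates the target
#' from its expression.
#'
#' @param text character scalar (or vector of lines) with the rule file
#'   contents.
#' @return a [boolean_network()].
#' @examples
#' net <- parse_network("targets, factors\nA, B\nB, !A")
#' @export
parse_network <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty rule file", call. = FALSE)
  header <- tolower(gsub("\\s", "", lines[1]))
  if (header != "targets,factors")
    stop("rule file must start with a 'targets, factors' header line",
         call. = FALSE)
  lines <- lines[-1]
  if (!length(lines)) stop("rule file has no rules", call. = FALSE)
  targets <- character(0)
  exprs <- character(0)
  for (i in seq_along(lines)) {
    comma <- regexpr(",", lines[i], fixed = TRUE)
    if (comma < 0)
      stop("line ", i + 1L, ": expected 'target, expression'", call. = FALSE)
    tg <- trimws(substr(lines[i], 1L, comma - 1L))
    ex <- trimws(substr(lines[i], comma + 1L, nchar(lines[i])))
    if (tg %in% targets)
      stop("line ", i + 1L, ": duplicate target '", tg, "'", call. = FALSE)
    targets <- c(targets, tg)
    exprs <- c(exprs, ex)
  }
  tryCatch(
    boolean_network(setNames(exprs, targets)),
    error = function(e)
      stop("rule file parse error: ", conditionMessage(e), call. = FALSE)
  )
}

#' Read a rule file from disk
#' @param path file path.
#' @return a [boolean_network()].
#' @export
read_network <- function(path) parse_network(readLines(path, warn = FALSE))

#' Serialize a network to "targets, factors" rule text
#' @param net a [boolean_network()].
#' @return character scalar; `parse_network(serialize_network(net))`
#'   reconstructs an identical network (same node order and tables).
#' @export
serialize_network <- function(net) {
  paste(c("targets, factors",
          vapply(net$rules, function(r)
            paste0(r$target, ", ", r$expression), character(1))),
        collapse = "\n")
}

#' Write a network rule file
#' @param net a [boolean_network()].
#' @param path file path.
#' @export
write_network <- function(net, path) {
  writeLines(serialize_network(net), path)
  invisible(path)
}

# ---- interaction graph -------------------------------------------------

#' Signed interaction graph of a network
#'
#' Each (input, target) dependency becomes one edge. The sign is read off
#' the truth table: an input is `activating` if the rule output is
#' non-decreasing in it over all contexts of the other inputs,
#' `inhibiting` if non-increasing, and `dual` if neither (e.g. XOR-type
#' dependence).
#'
#' @param net a [boolean_network()].
#' @return data frame with columns `from`, `to`, `sign`.
#' @export
interaction_graph <- function(net) {
  edges <- do.call(rbind, lapply(net$rules, function(r) {
    k <- length(r$inputs)
    if (k == 0) return(NULL)
    sign <- vapply(seq_len(k), function(j) {
      bitj <- bitwShiftL(1L, j - 1L)
      idx <- 0:(2L^k - 1L)
      lo <- idx[bitwAnd(idx, bitj) == 0L]
      up <- r$table[lo + bitj + 1L] - r$table[lo + 1L]
      if (all(up >= 0) && any(up > 0)) "activating"
      else if (all(up <= 0) && any(up < 0)) "inhibiting"
      else if (all(up == 0)) "none"
      else "dual"
    }, character(1))
    data.frame(from = r$inputs, to = r$target, sign = sign,
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  edges[edges$sign != "none", , drop = FALSE]
}

#' In-degree profile of a network
#' @param net a [boolean_network()].
#' @return named integer vector of per-node rule input counts.
#' @export
in_degree_profile <- function(net) {
  setNames(vapply(net$rules, function(r) length(r$inputs), integer(1)),
           net$nodes)
}

# ---- packaged cell-cycle model ----------------------------------------

#' Load the Arabidopsis thaliana cell-cycle Boolean model
#'
#' The packaged model has 14 nodes (CDKA;1 is not a node: it is treated
#' as constitutively present, so CDK-cyclin complex activity is carried
#' by the cyclin and inhibitor nodes). Under synchronous updating its
#' 2^14 = 16384 states all converge to a single period-11 limit-cycle
#' attractor traversing the G1, S, G2 and M phases.
#'
#' @return a [boolean_network()] with attributes `phase_scheme` (the
#'   cycle-position phase labels and the G1 anchor pattern) and
#'   `provenance` (per-rule notes).
#' @export
load_cc_model <- function() {
  path <- system.file("extdata", "cc_model.txt", package = "ccgrn")
  meta_path <- system.file("extdata", "cc_model_meta.json", package = "ccgrn")
  if (path == "" || meta_path == "")
    stop("packaged cell-cycle model data not found", call. = FALSE)
  net <- read_network(path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(net$nodes, meta$nodes))
    stop("packaged cell-cycle model failed its integrity check", call. = FALSE)
  attr(net, "phase_scheme") <- meta$phase_scheme
  attr(net, "provenance") <- meta$provenance
  net
}
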