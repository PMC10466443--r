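# Query AST --------------------------------------------------------------
#
# Nodes are lists with class "query_expr" and a `kind` field:
#   phrase : terms (list of term patterns), slop (integer >= 0)
#   or/and : children (list of query_expr, length >= 2 after dedup)
#   not    : include, exclude (query_expr); only ever at the root
# A bare term is represented uniformly as a single-term phrase; a term
# pattern is list(stem, wildcard) where wildcard terms match any token whose
# norm starts with the stem.

#' The seven SDOH domains covered by the shipped rules
#' @export
sdoh_domains <- c("social_connections", "employment", "housing", "food",
                  "education", "finance", "stress")

term_pattern <- function(stem, wildcard = FALSE) {
  stopifnot(nzchar(stem))
  list(stem = stem, wildcard = isTRUE(wildcard))
}

qe_phrase <- function(terms, slop = 0L) {
  stopifnot(length(terms) >= 1L, slop >= 0L)
  structure(list(kind = "phrase", terms = terms, slop = as.integer(slop)),
            class = "query_expr")
}

qe_group <- function(kind, children) {
  # flatten same-kind children, deduplicate by canonical form, collapse
  # singletons: (x OR x) is x, (A OR (B OR C)) is (A OR B OR C)
  flat <- list()
  for (ch in children) {
    if (identical(ch$kind, kind)) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  keys <- vapply(flat, render_expr, character(1))
  flat <- flat[!duplicated(keys)]
  if (length(flat) == 1L) return(flat[[1L]])
  structure(list(kind = kind, children = flat), class = "query_expr")
}

qe_or <- function(children) qe_group("or", children)
qe_and <- function(children) qe_group("and", children)

qe_not <- function(include, exclude) {
  structure(list(kind = "not", include = include, exclude = exclude),
            class = "query_expr")
}

# Lexer -------------------------------------------------------------------

lex_error <- function(msg, offset) {
  stop(sprintf("rule parse error at character %d: %s", offset, msg),
       call. = FALSE)
}

# Tokens: list(type, value, wildcard, slop, offset). Offsets are 1-based
# character positions into the (quote-normalized) rule string.
lex_rule <- function(text) {
  s <- normalize_quotes(text)
  n <- nchar(s)
  i <- 1L
  out <- list()
  push <- function(type, value = NULL, wildcard = FALSE, slop = 0L, offset = i) {
    out[[length(out) + 1L]] <<- list(type = type, value = value,
                                     wildcard = wildcard, slop = slop,
                                     offset = offset)
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch, perl = TRUE)) { i <- i + 1L; next }
    if (ch == "(") { push("lparen"); i <- i + 1L; next }
    if (ch == ")") { push("rparen"); i <- i + 1L; next }
    if (ch == ",") { push("comma");  i <- i + 1L; next }
    if (ch == "~") lex_error("proximity '~' may only follow a closing quote", i)
    if (ch == "\"") {
      start <- i
      close <- regexpr("\"", substr(s, i + 1L, n), fixed = TRUE)
      if (close == -1L) lex_error("unbalanced quote", start)
      content <- substr(s, i + 1L, i + close - 1L)
      i <- i + close + 1L
      slop <- 0L
      if (i <= n && substr(s, i, i) == "~") {
        rest <- substr(s, i + 1L, n)
        m <- regexpr("^[0-9]+", rest)
        if (m == -1L) lex_error("expected a number after '~'", i)
        slop <- as.integer(regmatches(rest, m))
        i <- i + 1L + attr(m, "match.length")
        # EMERSE-style ordinal suffix ("~10th") is display sugar for ~10
        if (toupper(substr(s, i, i + 1L)) == "TH") i <- i + 2L
      }
      norms <- token_norms(content)
      if (length(norms) == 0L) lex_error("empty quoted phrase", start)
      push("phrase", value = norms, slop = slop, offset = start)
      next
    }
    m <- regexpr("^[^\\s()\",~]+", substr(s, i, n), perl = TRUE)
    if (m == -1L) lex_error(sprintf("unexpected character '%s'", ch), i)
    word <- regmatches(substr(s, i, n), m)
    start <- i
    i <- i + attr(m, "match.length")
    up <- toupper(word)
    if (up %in% c("OR", "AND", "NOT")) { push(tolower(up), offset = start); next }
    wildcard <- endsWith(word, "*")
    stem <- if (wildcard) substr(word, 1L, nchar(word) - 1L) else word
    norms <- token_norms(stem)
    if (length(norms) != 1L) lex_error(sprintf("malformed term '%s'", word), start)
    push("term", value = norms, wildcard = wildcard, offset = start)
  }
  out
}

# Recursive-descent parser ------------------------------------------------

new_parser_state <- function(tokens, text) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env$eof_offset <- nchar(text) + 1L
  env
}

peek_tok <- function(st) if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL

next_tok <- function(st) { tok <- peek_tok(st); st$i <- st$i + 1L; tok }

tok_offset <- function(st) { tok <- peek_tok(st); if (is.null(tok)) st$eof_offset else tok$offset }

parse_or_expr <- function(st) {
  children <- list(parse_and_expr(st))
  repeat {
    tok <- peek_tok(st)
    if (is.null(tok) || !(tok$type %in% c("or", "comma"))) break
    next_tok(st)
    children <- c(children, list(parse_and_expr(st)))
  }
  if (length(children) == 1L) children[[1L]] else qe_or(children)
}

parse_and_expr <- function(st) {
  children <- list(parse_primary(st))
  repeat {
    tok <- peek_tok(st)
    if (is.null(tok) || tok$type != "and") break
    next_tok(st)
    children <- c(children, list(parse_primary(st)))
  }
  if (length(children) == 1L) children[[1L]] else qe_and(children)
}

parse_primary <- function(st) {
  tok <- peek_tok(st)
  if (is.null(tok)) lex_error("unexpected end of rule", st$eof_offset)
  if (tok$type == "lparen") {
    next_tok(st)
    inner <- parse_or_expr(st)
    closing <- peek_tok(st)
    if (is.null(closing)) lex_error("unbalanced parenthesis", tok$offset)
    if (closing$type != "rparen") {
      lex_error(sprintf("expected ')' but found '%s'", closing$type),
                closing$offset)
    }
    next_tok(st)
    return(inner)
  }
  if (tok$type == "phrase") {
    next_tok(st)
    return(qe_phrase(lapply(tok$value, term_pattern), tok$slop))
  }
  if (tok$type == "term") {
    next_tok(st)
    return(qe_phrase(list(term_pattern(tok$value, tok$wildcard)), 0L))
  }
  lex_error(sprintf("unexpected '%s'", tok$type), tok$offset)
}

#' Parse an SDOH rule into a query expression
#'
#' Accepts the dialect of the shipped rule files: parentheses; quoted phrases
#' (straight or curly quotes); bare terms with an optional trailing `*`
#' wildcard; a `~N` (or `~Nth`) proximity suffix on a closing quote; infix
#' `OR` / `AND` / `NOT` (case-insensitive); and a comma between phrases as a
#' synonym for `OR`. `NOT` splits the rule into an include side and a
#' document-level exclude side and may appear only once, at the top level.
#' Duplicate disjuncts are deduplicated.
#'
#' @param domain SDOH domain name the rule belongs to.
#' @param rule_text the rule as a single string.
#' @return an object of class `sdoh_rule`: a list with `domain`,
#'   `source_text` and the parsed `expr`.
#' @examples
#' r <- parse_rule("food", '("food insecurity" OR "food pantry") NOT "food secure"')
#' render_rule(r)
#' @export
parse_rule <- function(domain, rule_text) {
  stopifnot(is.character(domain), length(domain) == 1L,
            is.character(rule_text), length(rule_text) == 1L)
  st <- new_parser_state(lex_rule(rule_text), rule_text)
  include <- parse_or_expr(st)
  expr <- include
  tok <- peek_tok(st)
  if (!is.null(tok) && tok$type == "not") {
    next_tok(st)
    exclude <- parse_or_expr(st)
    expr <- qe_not(include, exclude)
    tok <- peek_tok(st)
  }
  if (!is.null(tok)) {
    if (tok$type == "not") {
      lex_error("'NOT' may appear only once at the top level", tok$offset)
    }
    lex_error(sprintf("unexpected '%s' after end of rule", tok$type),
              tok$offset)
  }
  structure(list(domain = domain, source_text = rule_text, expr = expr),
            class = "sdoh_rule")
}

# Canonical rendering ------------------------------------------------------

render_term <- function(tp) paste0(tp$stem, if (tp$wildcard) "*")

render_expr <- function(expr) {
  switch(expr$kind,
    phrase = {
      if (length(expr$terms) == 1L && expr$slop == 0L) {
        render_term(expr$terms[[1L]])
      } else {
        paste0("\"", paste(vapply(expr$terms, render_term, character(1)),
                           collapse = " "), "\"",
               if (expr$slop > 0L) paste0("~", expr$slop))
      }
    },
    or = paste0("(", paste(vapply(expr$children, render_expr, character(1)),
                           collapse = " OR "), ")"),
    and = paste0("(", paste(vapply(expr$children, render_expr, character(1)),
                            collapse = " AND "), ")"),
    not = paste(render_expr(expr$include), "NOT", render_expr(expr$exclude)),
    stop("unknown query node kind: ", expr$kind)
  )
}

#' Render a rule back to canonical single-line text
#'
#' The canonical form uses straight quotes, lowercase terms, `OR`/`AND`/`NOT`
#' keywords, `~N` proximity (dropping any ordinal `th` suffix) and
#' parenthesized groups. Reparsing the rendered text yields a structurally
#' identical query expression.
#'
#' @param rule an `sdoh_rule` (or a bare `query_expr`).
#' @return a single character string.
#' @export
render_rule <- function(rule) {
  expr <- if (inherits(rule, "sdoh_rule")) rule$expr else rule
  render_expr(expr)
}

#' @export
print.sdoh_rule <- function(x, ...) {
  cat("<sdoh_rule> domain:", x$domain, "\n")
  cat(" ", render_rule(x), "\n")
  invisible(x)
}

# Rule accounting: number of top-level include / exclude entries, used to
# audit a parsed rule against a hand count of its source table.
rule_entry_counts <- function(rule) {
  expr <- rule$expr
  side_count <- function(e) if (e$kind %in% c("or", "and")) length(e$children) else 1L
  if (expr$kind == "not") {
    c(include = side_count(expr$include), exclude = side_count(expr$exclude))
  } else {
    c(include = side_count(expr), exclude = 0L)
  }
}

#' Load the packaged SDOH rules
#'
#' Reads the seven shipped rule files (one per SDOH domain, as published for
#' the diabetes-cohort documentation study) and parses each into an
#' `sdoh_rule`. The files keep the published typographic quotes; parsing
#' normalizes them to ASCII.
#'
#' @param domains subset of [sdoh_domains] to load.
#' @param path directory containing `<domain>.rule` files; defaults to the
#'   packaged rules.
#' @return named list of `sdoh_rule` objects, one per domain.
#' @export
sdoh_rules <- function(domains = sdoh_domains, path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "rules", package = "sdohscan")
  stopifnot(all(domains %in% sdoh_domains))
  rules <- lapply(domains, function(d) {
    f <- file.path(path, paste0(d, ".rule"))
    if (!file.exists(f)) stop("no rule file for domain '", d, "' in ", path)
    txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " ")
    parse_rule(d, txt)
  })
  names(rules) <- domains
  rules
}
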