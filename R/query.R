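# Boolean semantic queries over the index: quoted names resolve to dictionary
# concepts or terminology classes, [Brackets] force class interpretation,
# bare words are free-text tokens. Precedence NOT > AND > OR; parentheses
# group. Class selection means the whole subtree; NOT is the closed-world
# complement against the index's documents.

query_node <- function(kind, ..., children = list()) {
  structure(list(kind = kind, ..., children = children), class = "query_ast")
}

# ---- tokenizer -------------------------------------------------------------

tokenize_query <- function(text) {
  chars <- stringi::stri_sub(text, seq_len(stringi::stri_length(text)),
                             length = 1)
  toks <- list(); i <- 1L; n <- length(chars)
  push <- function(type, value, pos) toks[[length(toks) + 1L]] <<-
    list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- chars[i]
    if (stringi::stri_detect_regex(ch, "\\s")) { i <- i + 1L; next }
    if (ch %in% c("\"", "'", "‘", "“")) {
      close <- switch(ch, "‘" = "’", "“" = "”", ch)
      j <- i + 1L
      while (j <= n && chars[j] != close) j <- j + 1L
      if (j > n) stop("syntax error at position ", i, ": unbalanced quote")
      push("QUOTED", paste(chars[(i + 1L):(j - 1L)], collapse = ""), i)
      i <- j + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("syntax error at position ", i, ": unbalanced bracket")
      push("CLASSREF", stringi::stri_trim_both(
        paste(chars[(i + 1L):(j - 1L)], collapse = "")), i)
      i <- j + 1L
    } else if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L
    } else if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L
    } else {
      j <- i
      while (j <= n && !stringi::stri_detect_regex(chars[j], "[\\s()\\[\\]\"']"))
        j <- j + 1L
      w <- paste(chars[i:(j - 1L)], collapse = "")
      up <- stringi::stri_trans_toupper(w)
      if (up %in% c("AND", "OR", "NOT")) push(up, w, i) else push("WORD", w, i)
      i <- j
    }
  }
  toks
}

# ---- name resolution -------------------------------------------------------

resolve_quoted <- function(name, term) {
  key <- stringi::stri_trans_casefold(stringi::stri_trim_both(name))
  en <- term$entries
  hits <- en$entry_id[stringi::stri_trans_casefold(en$preferred_name) == key]
  sy <- term$synonyms
  hits <- c(hits, sy$entry_id[stringi::stri_trans_casefold(sy$text) == key])
  hits <- sort(unique(hits))
  cl_hit <- resolve_class(name, term, error = FALSE)
  if (length(hits)) {
    if (!is.na(cl_hit))
      warning("'", name, "' names both a concept and a class; using the concept")
    return(query_node("CONCEPT", entry_id = hits[1]))
  }
  if (!is.na(cl_hit)) return(query_node("CLASS", class_id = cl_hit))
  near <- unique(c(agrep(name, en$preferred_name, value = TRUE,
                         ignore.case = TRUE, max.distance = 0.2),
                   agrep(name, term$classes$name, value = TRUE,
                         ignore.case = TRUE, max.distance = 0.2)))
  stop("unknown-term error: '", name, "' matches no entry or class",
       if (length(near)) paste0("; near matches: ",
                                paste(utils::head(near, 5), collapse = ", ")))
}

resolve_class <- function(name, term, error = TRUE) {
  key <- stringi::stri_trans_casefold(stringi::stri_trim_both(name))
  cl <- term$classes
  hit <- cl$class_id[stringi::stri_trans_casefold(cl$class_id) == key |
                       stringi::stri_trans_casefold(cl$name) == key]
  hit <- sort(unique(hit))
  if (length(hit)) return(hit[1])
  if (error) stop("unknown-term error: no class named '", name, "'")
  NA_character_
}

# ---- recursive-descent parser ---------------------------------------------

#' Parse a Boolean retrieval query
#'
#' Grammar: a quoted string resolves to a dictionary concept if it names an
#' entry (preferred name or synonym), else to a class if it names one (class
#' id or display name), else errors listing near matches; `[Brackets]` force
#' class interpretation; a bare word is a free-text token (a trailing `*`
#' requests prefix matching); `NOT` binds tighter than `AND`, which binds
#' tighter than `OR`; parentheses group. All name resolution is
#' case-insensitive. Example: `"Alzheimer's Disease" AND [Evidence]`.
#'
#' @param text query string.
#' @param term a [terminology] used for name resolution.
#' @return a `query_ast` node; operators have exactly two children (`NOT`
#'   one), leaves none.
#' @export
parse_query <- function(text, term) {
  stopifnot(inherits(term, "terminology"))
  toks <- tokenize_query(text)
  if (!length(toks)) stop("syntax error: empty query")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type)
      stop("syntax error at position ", if (is.null(t)) "end" else t$pos,
           ": expected ", type)
    advance()
  }
  parse_or <- function() {
    left <- parse_and()
    while (!is.null(peek()) && peek()$type == "OR") {
      advance()
      left <- query_node("OR", children = list(left, parse_and()))
    }
    left
  }
  parse_and <- function() {
    left <- parse_not()
    while (!is.null(peek()) && peek()$type == "AND") {
      advance()
      left <- query_node("AND", children = list(left, parse_not()))
    }
    left
  }
  parse_not <- function() {
    if (!is.null(peek()) && peek()$type == "NOT") {
      advance()
      return(query_node("NOT", children = list(parse_not())))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) stop("syntax error at end of query: expected a term")
    if (t$type == "LPAREN") {
      advance()
      inner <- parse_or()
      expect("RPAREN")
      return(inner)
    }
    if (t$type == "QUOTED") { advance(); return(resolve_quoted(t$value, term)) }
    if (t$type == "CLASSREF") {
      advance()
      return(query_node("CLASS", class_id = resolve_class(t$value, term)))
    }
    if (t$type == "WORD") { advance(); return(query_node("TEXT", token = t$value)) }
    stop("syntax error at position ", t$pos, ": unexpected ", t$type)
  }
  ast <- parse_or()
  t <- peek()
  if (!is.null(t))
    stop("syntax error at position ", t$pos, ": trailing input")
  attr(ast, "query_text") <- text
  ast
}

# docs whose title or abstract contains the token, case-insensitive,
# token-bounded; trailing '*' = prefix match
text_token_docs <- function(index, token) {
  prefix <- stringi::stri_endswith_fixed(token, "*")
  if (prefix) token <- stringi::stri_sub(token, 1, -2)
  if (!nzchar(token)) return(character())
  pat <- paste0("(?i)(?<![\\p{L}\\p{N}])", regex_escape(token),
                if (!prefix) "(?![\\p{L}\\p{N}])")
  docs <- index$documents
  hit <- stringi::stri_detect_regex(docs$title, pat) |
    stringi::stri_detect_regex(docs$abstract, pat)
  docs$doc_id[hit %in% TRUE]
}

#' Evaluate a query against an index
#'
#' `CONCEPT` retrieves the entity's posting list; `CLASS` the union over all
#' entries in the class subtree; `TEXT` the documents whose title or abstract
#' contains the token; `AND`/`OR`/`NOT` are set intersection, union, and
#' complement with respect to the index's document set.
#'
#' @param index a `corpus_index`.
#' @param ast a [parse_query()] result (or query string, parsed on the fly).
#' @param term the [terminology] (needed for class subtrees and string
#'   queries).
#' @return object of class `doc_set`: list with sorted `doc_ids` and the
#'   originating `query_text`.
#' @export
evaluate_query <- function(index, ast, term) {
  stopifnot(inherits(index, "corpus_index"), inherits(term, "terminology"))
  if (is.character(ast)) ast <- parse_query(ast, term)
  all_docs <- index$documents$doc_id
  ev <- function(node) {
    switch(node$kind,
      CONCEPT = index$postings_entry[[node$entry_id]] %||% character(),
      CLASS = {
        ids <- entries_in(term, subtree(term, node$class_id))$entry_id
        sort(unique(unlist(index$postings_entry[
          intersect(ids, names(index$postings_entry))], use.names = FALSE)))
      },
      TEXT = text_token_docs(index, node$token),
      AND = intersect(ev(node$children[[1]]), ev(node$children[[2]])),
      OR = union(ev(node$children[[1]]), ev(node$children[[2]])),
      NOT = setdiff(all_docs, ev(node$children[[1]])),
      stop("invalid AST node kind: ", node$kind))
  }
  ids <- sort(unique(ev(ast)))
  structure(list(doc_ids = ids,
                 query_text = attr(ast, "query_text") %||% ""),
            class = "doc_set")
}

#' @export
print.doc_set <- function(x, ...) {
  cat(sprintf("<doc_set: %d documents | %s>\n", length(x$doc_ids),
              x$query_text))
  invisible(x)
}

#' Entity table of a retrieved corpus
#'
#' For every dictionary entry in the subtree of `class_id`, the number of
#' documents of `docset` containing it (document frequency within the
#' selection). Entries occurring in none of the selected documents are
#' omitted. This is the table that ranking operates on, e.g. the recognized
#' genes/proteins of a disease query.
#'
#' @param index a `corpus_index`.
#' @param docset a `doc_set` (or character vector of doc ids).
#' @param class_id class whose subtree defines the entity universe.
#' @param term the [terminology].
#' @return data.frame with columns `entry_id`, `doc_count`, sorted by
#'   `entry_id`.
#' @export
entity_table <- function(index, docset, class_id, term) {
  stopifnot(inherits(index, "corpus_index"))
  ids <- if (inherits(docset, "doc_set")) docset$doc_ids else as.character(docset)
  entries <- entries_in(term, subtree(term, class_id))$entry_id
  counts <- vapply(entries, function(e) {
    length(intersect(index$postings_entry[[e]] %||% character(), ids))
  }, integer(1))
  out <- data.frame(entry_id = entries, doc_count = unname(counts),
                    stringsAsFactors = FALSE)
  out <- out[out$doc_count > 0L, , drop = FALSE]
  out <- out[order(out$entry_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
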