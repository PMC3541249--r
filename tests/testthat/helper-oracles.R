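# Independent oracles, written without the package's regex machinery:
# a segment-walk dictionary matcher, a repeated-selection overlap resolver,
# and a per-document Boolean predicate evaluator. Test fixtures are ASCII,
# so tolower() is an adequate casefold here.

is_alnum_chr <- function(ch) length(ch) == 1 && grepl("[[:alnum:]]", ch)

# all candidate matches of one synonym in one text (0-based half-open spans)
oracle_syn_matches <- function(text, syn_text, case_sensitive) {
  if (!nzchar(text)) return(NULL)
  norm <- function(x) if (case_sensitive) x else tolower(x)
  pieces <- strsplit(syn_text, "[-[:space:]]+")[[1]]
  pieces <- pieces[nzchar(pieces)]
  if (!length(pieces)) return(NULL)
  # segments = maximal runs without hyphen/whitespace, with 1-based offsets
  seg_pos <- gregexpr("[^-[:space:]]+", text)[[1]]
  if (seg_pos[1] == -1) return(NULL)
  seg_start <- as.integer(seg_pos)
  seg_len <- attr(seg_pos, "match.length")
  seg_str <- substring(text, seg_start, seg_start + seg_len - 1)
  n_seg <- length(seg_str)
  chars <- strsplit(text, "")[[1]]
  boundary_ok <- function(pos1) pos1 < 1 || pos1 > length(chars) ||
    !is_alnum_chr(chars[pos1])
  out <- list()
  k <- length(pieces)
  if (k == 1) {
    p <- norm(pieces[1]); pl <- nchar(p)
    for (s in seq_len(n_seg)) {
      hay <- norm(seg_str[s])
      off <- 0
      repeat {
        idx <- regexpr(p, substring(hay, off + 1), fixed = TRUE)
        if (idx == -1) break
        at <- off + as.integer(idx)              # 1-based within segment
        st <- seg_start[s] + at - 1              # 1-based within text
        if (boundary_ok(st - 1) && boundary_ok(st + pl))
          out[[length(out) + 1L]] <- c(st - 1L, st - 1L + pl)
        off <- at
      }
    }
  } else {
    first <- norm(pieces[1]); last <- norm(pieces[k])
    mids <- if (k > 2) norm(pieces[2:(k - 1)]) else character()
    for (s in seq_len(n_seg - k + 1)) {
      segs <- norm(seg_str[s:(s + k - 1)])
      if (!endsWith(segs[1], first)) next
      if (k > 2 && !all(segs[2:(k - 1)] == mids)) next
      if (!startsWith(segs[k], last)) next
      st <- seg_start[s] + seg_len[s] - nchar(first)      # 1-based start
      en <- seg_start[s + k - 1] + nchar(last) - 1        # 1-based end
      if (boundary_ok(st - 1) && boundary_ok(en + 1))
        out[[length(out) + 1L]] <- c(st - 1L, en)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# full naive annotation of one document: scan every synonym, then resolve
# overlaps by repeated selection (min start, then max length, then min entry)
oracle_annotate <- function(term, doc) {
  cand <- list()
  for (field in c("title", "abstract")) {
    text <- doc[[field]]
    if (is.null(text) || is.na(text) || !nzchar(text)) next
    for (i in seq_len(nrow(term$synonyms))) {
      m <- oracle_syn_matches(text, term$synonyms$text[i],
                              term$synonyms$case_sensitive[i])
      if (is.null(m)) next
      eid <- term$synonyms$entry_id[i]
      cid <- term$entries$class_id[term$entries$entry_id == eid]
      for (r in seq_len(nrow(m))) {
        cand[[length(cand) + 1L]] <- data.frame(
          doc_id = doc$doc_id, field = field,
          start = m[r, 1], end = m[r, 2],
          matched_text = substring(text, m[r, 1] + 1, m[r, 2]),
          entry_id = eid, class_id = cid, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(markermine:::empty_annotations())
  cand <- do.call(rbind, cand)
  kept <- list()
  for (field in c("title", "abstract")) {
    pool <- cand[cand$field == field, , drop = FALSE]
    while (nrow(pool)) {
      pool <- pool[order(pool$start, -(pool$end - pool$start), pool$entry_id), ,
                   drop = FALSE]
      pick <- pool[1, , drop = FALSE]
      kept[[length(kept) + 1L]] <- pick
      pool <- pool[pool$start >= pick$end | pool$end <= pick$start, ,
                   drop = FALSE]
    }
  }
  out <- do.call(rbind, kept)
  out <- out[order(match(out$field, c("title", "abstract")), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- query oracle ----------------------------------------------------------

# descendants by exhaustive scan over the parent table
oracle_subtree <- function(term, class_id) {
  res <- class_id
  repeat {
    kids <- term$classes$class_id[!is.na(term$classes$parent_id) &
                                    term$classes$parent_id %in% res]
    new <- setdiff(kids, res)
    if (!length(new)) return(sort(res))
    res <- c(res, new)
  }
}

# per-document truth value of an AST node
oracle_doc_predicate <- function(node, doc, anns, term) {
  mine <- anns[anns$doc_id == doc$doc_id, , drop = FALSE]
  switch(node$kind,
    CONCEPT = node$entry_id %in% mine$entry_id,
    CLASS = {
      cls <- oracle_subtree(term, node$class_id)
      ents <- term$entries$entry_id[term$entries$class_id %in% cls]
      any(ents %in% mine$entry_id)
    },
    TEXT = {
      tok <- tolower(node$token)
      prefix <- endsWith(tok, "*")
      if (prefix) tok <- substr(tok, 1, nchar(tok) - 1)
      runs <- unlist(strsplit(tolower(paste(doc$title, doc$abstract)),
                              "[^[:alnum:]]+"))
      if (prefix) any(startsWith(runs, tok)) else any(runs == tok)
    },
    AND = oracle_doc_predicate(node$children[[1]], doc, anns, term) &&
          oracle_doc_predicate(node$children[[2]], doc, anns, term),
    OR = oracle_doc_predicate(node$children[[1]], doc, anns, term) ||
         oracle_doc_predicate(node$children[[2]], doc, anns, term),
    NOT = !oracle_doc_predicate(node$children[[1]], doc, anns, term),
    stop("bad node"))
}

oracle_evaluate <- function(ast, docs, anns, term) {
  hit <- vapply(seq_len(nrow(docs)), function(i)
    oracle_doc_predicate(ast, docs[i, ], anns, term), logical(1))
  sort(docs$doc_id[hit])
}

# random AST over the fixture vocabulary
random_ast <- function(term, text_tokens, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    kind <- sample(c("CONCEPT", "CLASS", "TEXT"), 1)
    return(switch(kind,
      CONCEPT = markermine:::query_node(
        "CONCEPT", entry_id = sample(term$entries$entry_id, 1)),
      CLASS = markermine:::query_node(
        "CLASS", class_id = sample(term$classes$class_id, 1)),
      TEXT = markermine:::query_node(
        "TEXT", token = sample(text_tokens, 1))))
  }
  op <- sample(c("AND", "OR", "NOT"), 1, prob = c(.4, .4, .2))
  if (op == "NOT")
    markermine:::query_node("NOT", children = list(
      random_ast(term, text_tokens, depth - 1)))
  else
    markermine:::query_node(op, children = list(
      random_ast(term, text_tokens, depth - 1),
      random_ast(term, text_tokens, depth - 1)))
}

# random document generator over a mixed vocabulary (synonyms, near-miss
# words, fillers), used for matcher/query equivalence property tests
random_doc <- function(id, vocab, n_tokens = 12) {
  toks <- sample(vocab, n_tokens, replace = TRUE)
  sep <- sample(c(" ", " ", " ", "-", ", ", ". "), n_tokens - 1, replace = TRUE)
  data.frame(doc_id = id,
             title = paste(sample(vocab, 3, replace = TRUE), collapse = " "),
             abstract = paste0(paste0(toks[-n_tokens], sep, collapse = ""),
                               toks[n_tokens]),
             date = NA_character_, stringsAsFactors = FALSE)
}
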