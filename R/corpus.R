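# Abstract corpora (MEDLINE field-tag text or JSONL) and the inverted
# document-frequency index over their annotations.

empty_documents <- function() {
  data.frame(doc_id = character(), title = character(), abstract = character(),
             date = character(), stringsAsFactors = FALSE)
}

#' Read an abstract corpus
#'
#' Two formats:
#' \describe{
#'   \item{`jsonl`}{one JSON object per line with keys `id`, `title`,
#'     `abstract` and optionally `date`. A missing `abstract` becomes the
#'     empty string with a warning; a missing `id` is a parse error.}
#'   \item{`medline_txt`}{the plain-text MEDLINE field-tag format: a
#'     6-character tag field (`PMID- `, `TI  - `, `AB  - `, `DP  - `),
#'     continuation lines indented six spaces, records separated by blank
#'     lines. Folded values are unfolded with single spaces. Tags other than
#'     PMID/TI/AB/DP are ignored.}
#' }
#'
#' @param path file path.
#' @param format `"jsonl"` or `"medline_txt"`.
#' @return data.frame with columns `doc_id`, `title`, `abstract`, `date`
#'   (ISO-ish `YYYY[-MM[-DD]]` string or NA).
#' @export
read_corpus <- function(path, format = c("jsonl", "medline_txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  switch(format,
         jsonl = read_corpus_jsonl(path),
         medline_txt = read_corpus_medline(path))
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(stringi::stri_trim_both(lines))]
  if (!length(lines)) return(empty_documents())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("parse error at line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(rec$id) || !nzchar(as.character(rec$id)[1]))
      stop("parse error at line ", i, ": record lacks 'id'")
    if (is.null(rec$abstract))
      warning("line ", i, ": record lacks 'abstract'; using empty string")
    recs[[i]] <- data.frame(
      doc_id = as.character(rec$id)[1],
      title = as.character(rec$title %||% "")[1],
      abstract = as.character(rec$abstract %||% "")[1],
      date = if (is.null(rec$date)) NA_character_ else as.character(rec$date)[1],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# lenient MEDLINE DP parser: year required, month/day optional
parse_medline_date <- function(dp) {
  if (is.na(dp) || !nzchar(dp)) return(NA_character_)
  y <- stringi::stri_extract_first_regex(dp, "\\b(1[89]|20)\\d{2}\\b")
  if (is.na(y)) return(NA_character_)
  months <- c(Jan = 1, Feb = 2, Mar = 3, Apr = 4, May = 5, Jun = 6,
              Jul = 7, Aug = 8, Sep = 9, Oct = 10, Nov = 11, Dec = 12)
  mname <- stringi::stri_extract_first_regex(dp, "\\b(Jan|Feb|Mar|Apr|May|Jun|Jul|Aug|Sep|Oct|Nov|Dec)\\b")
  if (is.na(mname)) return(y)
  m <- sprintf("%02d", months[[mname]])
  d <- stringi::stri_extract_first_regex(
    stringi::stri_replace_first_fixed(dp, y, ""), "\\b([0-2]?\\d|3[01])\\b")
  if (is.na(d)) return(paste(y, m, sep = "-"))
  paste(y, m, sprintf("%02d", as.integer(d)), sep = "-")
}

read_corpus_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- list(); cur <- list(); cur_tag <- NA_character_; rec_idx <- 0L

  flush_record <- function(cur, rec_idx) {
    if (!length(cur)) return(NULL)
    if (is.null(cur$PMID))
      stop("parse error in record ", rec_idx, ": missing PMID")
    data.frame(doc_id = cur$PMID,
               title = cur$TI %||% "",
               abstract = cur$AB %||% "",
               date = parse_medline_date(cur$DP %||% NA_character_),
               stringsAsFactors = FALSE)
  }

  for (ln in lines) {
    if (!nzchar(stringi::stri_trim_both(ln))) {          # record separator
      if (length(cur)) {
        rec_idx <- rec_idx + 1L
        recs[[length(recs) + 1L]] <- flush_record(cur, rec_idx)
        cur <- list(); cur_tag <- NA_character_
      }
      next
    }
    m <- stringi::stri_match_first_regex(ln, "^([A-Z][A-Z0-9]{0,3})\\s*- (.*)$")
    if (!is.na(m[1, 1])) {
      cur_tag <- m[1, 2]
      val <- m[1, 3]
      cur[[cur_tag]] <- if (is.null(cur[[cur_tag]])) val
                        else paste(cur[[cur_tag]], val)   # repeated tag
    } else if (stringi::stri_startswith_fixed(ln, "      ") && !is.na(cur_tag)) {
      cur[[cur_tag]] <- paste(cur[[cur_tag]],
                              stringi::stri_trim_both(ln))  # unfold
    } else {
      stop("parse error in record ", rec_idx + 1L, ": unparseable line: ", ln)
    }
  }
  if (length(cur)) {
    rec_idx <- rec_idx + 1L
    recs[[length(recs) + 1L]] <- flush_record(cur, rec_idx)
  }
  if (!length(recs)) return(empty_documents())
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# numeric sort key, larger = more recent; missing parts count as 0
date_sort_key <- function(date) {
  y <- suppressWarnings(as.integer(stringi::stri_sub(date, 1, 4)))
  m <- suppressWarnings(as.integer(stringi::stri_sub(date, 6, 7)))
  d <- suppressWarnings(as.integer(stringi::stri_sub(date, 9, 10)))
  y[is.na(y)] <- 0L; m[is.na(m)] <- 0L; d[is.na(d)] <- 0L
  y * 10000 + m * 100 + d
}

#' Build an inverted document-frequency index
#'
#' The unit throughout is \emph{document frequency}: a document contributes
#' at most once to an entity's posting list regardless of how many mentions
#' it holds. Per-class postings are the union of the postings of the class's
#' entries (the class of each annotation row, as assigned by the matcher).
#'
#' @param docs corpus data.frame (`doc_id`, `title`, `abstract`, `date`).
#' @param anns annotation data.frame as produced by [annotate_corpus()].
#' @return object of class `corpus_index` with fields `documents` (sorted by
#'   `doc_id`), `postings_entry`, `postings_class` (named lists of sorted
#'   unique doc_id vectors) and `n_docs`.
#' @export
build_index <- function(docs, anns = empty_annotations()) {
  if (!nrow(docs)) {
    docs <- empty_documents()
  }
  if (!"date" %in% names(docs)) docs$date <- NA_character_
  if (anyDuplicated(docs$doc_id))
    stop("structural error: duplicate doc_id in corpus")
  orphan <- setdiff(unique(anns$doc_id), docs$doc_id)
  if (length(orphan))
    stop("reference error: annotations for unknown documents: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  docs <- docs[order(docs$doc_id), c("doc_id", "title", "abstract", "date")]
  rownames(docs) <- NULL
  posting <- function(keys) {
    if (!nrow(anns)) return(structure(list(), names = character()))
    p <- lapply(split(anns$doc_id, keys), function(d) sort(unique(d)))
    p[order(names(p))]
  }
  structure(list(documents = docs,
                 postings_entry = posting(anns$entry_id),
                 postings_class = posting(anns$class_id),
                 n_docs = nrow(docs)),
            class = "corpus_index")
}

#' @export
print.corpus_index <- function(x, ...) {
  cat(sprintf("<corpus_index: %d documents, %d entities, %d classes>\n",
              x$n_docs, length(x$postings_entry), length(x$postings_class)))
  invisible(x)
}

#' Per-entity corpus statistics for relative-entropy ranking
#'
#' Counts the documents containing `entry_id` in a selected corpus and in a
#' reference corpus (the stand-in for "all of Medline"). These are the
#' numerators and denominators of the two proportions compared by
#' [relative_entropy()]. An entity unknown to the reference gets
#' `n_ref = 0`.
#'
#' @param index_sel selected corpus, a `corpus_index`.
#' @param index_ref reference corpus, a `corpus_index`.
#' @param entry_id entity id.
#' @return object of class `entity_corpus_stats`: list with `entry_id`,
#'   `n_sel`, `N_sel`, `n_ref`, `N_ref`.
#' @export
entity_stats <- function(index_sel, index_ref, entry_id) {
  stopifnot(inherits(index_sel, "corpus_index"), inherits(index_ref, "corpus_index"))
  n_sel <- length(index_sel$postings_entry[[entry_id]])
  n_ref <- length(index_ref$postings_entry[[entry_id]])
  structure(list(entry_id = entry_id, n_sel = n_sel, N_sel = index_sel$n_docs,
                 n_ref = n_ref, N_ref = index_ref$n_docs),
            class = "entity_corpus_stats")
}

#' Restrict an index to a set of documents
#'
#' Produces the `corpus_index` of a sub-corpus (e.g. a query result), with
#' posting lists intersected against the kept documents. Used to derive
#' `n_sel`/`N_sel` for ranking.
#'
#' @param index a `corpus_index`.
#' @param doc_ids documents to keep.
#' @return a `corpus_index` over the subset.
#' @export
subset_index <- function(index, doc_ids) {
  stopifnot(inherits(index, "corpus_index"))
  keep <- sort(intersect(doc_ids, index$documents$doc_id))
  docs <- index$documents[index$documents$doc_id %in% keep, , drop = FALSE]
  rownames(docs) <- NULL
  trim <- function(postings) {
    p <- lapply(postings, function(d) d[d %in% keep])
    p[vapply(p, length, integer(1)) > 0L]
  }
  structure(list(documents = docs,
                 postings_entry = trim(index$postings_entry),
                 postings_class = trim(index$postings_class),
                 n_docs = nrow(docs)),
            class = "corpus_index")
}

#' Save / load a corpus index as versioned JSON
#'
#' @param index a `corpus_index`.
#' @param path file path.
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   restored `corpus_index`, identical to the saved one.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "corpus_index"))
  payload <- list(format = "markermine-index", version = 1L,
                  n_docs = index$n_docs,
                  documents = index$documents,
                  postings_entry = index$postings_entry,
                  postings_class = index$postings_class)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                                simplifyVector = TRUE)
  if (!identical(payload$format, "markermine-index"))
    stop("not a markermine index file: ", path)
  docs <- as.data.frame(payload$documents, stringsAsFactors = FALSE)
  if (!nrow(docs)) docs <- empty_documents()
  docs$date <- as.character(docs$date)
  fix <- function(p) {
    if (is.null(p) || !length(p)) return(structure(list(), names = character()))
    lapply(p, as.character)
  }
  structure(list(documents = docs,
                 postings_entry = fix(payload$postings_entry),
                 postings_class = fix(payload$postings_class),
                 n_docs = as.integer(payload$n_docs)),
            class = "corpus_index")
}
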