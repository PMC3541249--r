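# Deterministic dictionary matching of terminology synonyms in titles and
# abstracts. Matches are token-bounded (flanked by non-alphanumerics or the
# string edge), honour each synonym's case policy, and treat runs of hyphens
# and whitespace as a single separator, so "Kaplan Meier" matches
# "Kaplan-Meier". Overlaps are resolved leftmost-longest.

ANNOTATION_FIELDS <- c("title", "abstract")

empty_annotations <- function() {
  data.frame(doc_id = character(), field = character(), start = integer(),
             end = integer(), matched_text = character(),
             entry_id = character(), class_id = character(),
             stringsAsFactors = FALSE)
}

# escape everything ICU regex treats specially (hyphen excluded: synonyms are
# split on hyphen runs before escaping)
regex_escape <- function(x) {
  stringi::stri_replace_all_regex(x, "([\\\\.\\[\\]\\{\\}\\(\\)\\*\\+\\?\\^\\$\\|\\=\\!\\<\\>\\:\\#\\&\\~])",
                                  "\\\\$1")
}

synonym_pattern <- function(text, case_sensitive) {
  pieces <- stringi::stri_split_regex(text, "[\\-\\s]+")[[1]]
  pieces <- pieces[nzchar(pieces)]
  body <- paste(regex_escape(pieces), collapse = "[\\-\\s]+")
  paste0(if (case_sensitive) "" else "(?i)",
         "(?<![\\p{L}\\p{N}])", body, "(?![\\p{L}\\p{N}])")
}

#' Compile a terminology into a dictionary matcher
#'
#' Builds one anchored ICU regular expression per synonym. The matcher's
#' behaviour is extensionally defined: for every synonym, every occurrence in
#' the text that respects the case policy and token boundaries is a
#' candidate; [resolve_overlaps()] then selects the reported subset.
#'
#' @param term a [terminology].
#' @return an opaque object of class `matcher`.
#' @export
compile_matcher <- function(term) {
  validate_terminology(term)
  sy <- term$synonyms
  if (!nrow(sy)) {
    warning("empty terminology: matcher will match nothing")
    pats <- data.frame(pattern = character(), entry_id = character(),
                       class_id = character(), stringsAsFactors = FALSE)
  } else {
    cls <- term$entries$class_id[match(sy$entry_id, term$entries$entry_id)]
    pats <- data.frame(
      pattern = vapply(seq_len(nrow(sy)),
                       function(i) synonym_pattern(sy$text[i], sy$case_sensitive[i]),
                       character(1)),
      entry_id = sy$entry_id, class_id = cls, stringsAsFactors = FALSE)
  }
  structure(list(patterns = pats, terminology_name = term$name),
            class = "matcher")
}

#' @export
print.matcher <- function(x, ...) {
  cat(sprintf("<matcher over '%s': %d synonym patterns>\n",
              x$terminology_name, nrow(x$patterns)))
  invisible(x)
}

# all candidate matches (possibly overlapping) for a corpus; internal
match_candidates <- function(matcher, docs) {
  out <- list()
  for (field in ANNOTATION_FIELDS) {
    texts <- as.character(docs[[field]])
    texts[is.na(texts)] <- ""
    for (i in seq_len(nrow(matcher$patterns))) {
      loc <- stringi::stri_locate_all_regex(texts, matcher$patterns$pattern[i],
                                            omit_no_match = TRUE)
      hit <- which(vapply(loc, nrow, integer(1)) > 0L)
      for (d in hit) {
        m <- loc[[d]]
        out[[length(out) + 1L]] <- data.frame(
          doc_id = docs$doc_id[d], field = field,
          start = m[, 1] - 1L, end = m[, 2],           # 0-based half-open
          matched_text = stringi::stri_sub(texts[d], m[, 1], m[, 2]),
          entry_id = matcher$patterns$entry_id[i],
          class_id = matcher$patterns$class_id[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_annotations())
  do.call(rbind, out)
}

# greedy leftmost-longest selection within one (doc, field); assumes input
# belongs to a single doc_id+field
select_leftmost_longest <- function(cand) {
  o <- order(cand$start, -(cand$end - cand$start), cand$entry_id)
  cand <- cand[o, , drop = FALSE]
  keep <- logical(nrow(cand))
  cur_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= cur_end) {
      keep[i] <- TRUE
      cur_end <- cand$end[i]
    }
  }
  cand[keep, , drop = FALSE]
}

resolve_overlaps_all <- function(candidates) {
  if (!nrow(candidates)) return(empty_annotations())
  key <- paste(candidates$doc_id, candidates$field, sep = "\r")
  parts <- lapply(split(candidates, key), select_leftmost_longest)
  out <- do.call(rbind, parts)
  fo <- match(out$field, ANNOTATION_FIELDS)
  out <- out[order(out$doc_id, fo, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping candidate annotations (single document)
#'
#' Greedy leftmost-longest, single pass: candidates are scanned by start
#' offset; at equal starts the longer span wins; at identical spans the
#' lexicographically smallest `entry_id` wins. The survivors are
#' non-overlapping within each field and sorted by (field, start), title
#' before abstract.
#'
#' @param candidates annotation data.frame (columns as [empty_annotations()]),
#'   all rows from one document.
#' @return the resolved annotation data.frame.
#' @export
resolve_overlaps <- function(candidates) {
  if (!nrow(candidates)) return(empty_annotations())
  if (length(unique(candidates$doc_id)) > 1L)
    stop("input error: candidates span multiple doc_ids")
  resolve_overlaps_all(candidates)
}

#' Annotate a corpus of documents
#'
#' Applies the compiled matcher to the `title` and `abstract` fields of each
#' document and resolves overlaps. Offsets are 0-based, half-open, per field.
#'
#' @param matcher a [compile_matcher()] result.
#' @param docs corpus data.frame with columns `doc_id`, `title`, `abstract`.
#' @return annotation data.frame with columns `doc_id`, `field`, `start`,
#'   `end`, `matched_text`, `entry_id`, `class_id`.
#' @export
annotate_corpus <- function(matcher, docs) {
  stopifnot(inherits(matcher, "matcher"))
  if (!nrow(docs)) return(empty_annotations())
  resolve_overlaps_all(match_candidates(matcher, docs))
}

#' Annotate a single document
#'
#' @param matcher a [compile_matcher()] result.
#' @param doc one-row corpus data.frame, or a list with `doc_id`, `title`,
#'   `abstract`.
#' @return annotation data.frame; see [annotate_corpus()].
#' @export
annotate_document <- function(matcher, doc) {
  if (!is.data.frame(doc))
    doc <- data.frame(doc_id = doc$doc_id %||% "doc",
                      title = doc$title %||% "",
                      abstract = doc$abstract %||% "",
                      stringsAsFactors = FALSE)
  annotate_corpus(matcher, doc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
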