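# Hierarchical biomarker terminologies: entity classes arranged in a forest,
# each class holding dictionary entries (e.g. gene symbols, clinical concepts)
# with one or more surface synonyms.

#' Acronym threshold for default case policy
#'
#' Synonyms shorter than this many characters are matched case-sensitively
#' unless the terminology file states a policy explicitly. Short tokens such
#' as "MS" or "AD" are acronyms whose lower-case forms are common words, so a
#' conservative default avoids spurious matches.
#' @keywords internal
ACRONYM_THRESHOLD <- 5L

#' Construct a terminology object
#'
#' A terminology is a forest of entity classes plus dictionary entries.
#' Classes form the navigable hierarchy (e.g. the six biomarker retrieval
#' classes: Clinical Management, Diagnostics, Prognosis, Statistics,
#' Evidence, Antecedent); entries are the concepts that can be mentioned in
#' text, each carrying at least one synonym with a case policy.
#'
#' @param classes data.frame with columns `class_id`, `name`, `parent_id`
#'   (NA for roots), `description`.
#' @param entries data.frame with columns `entry_id`, `class_id`,
#'   `preferred_name`.
#' @param synonyms data.frame with columns `entry_id`, `text`,
#'   `case_sensitive` (logical; NA means "apply the acronym default").
#' @param name,version free-text identification of the terminology.
#' @return An object of class `terminology`.
#' @export
terminology <- function(classes = empty_classes(), entries = empty_entries(),
                        synonyms = empty_synonyms(), name = "terminology",
                        version = "0") {
  classes <- as.data.frame(classes, stringsAsFactors = FALSE)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  synonyms <- as.data.frame(synonyms, stringsAsFactors = FALSE)
  synonyms$text <- stringi::stri_trim_both(
    stringi::stri_replace_all_regex(as.character(synonyms$text), "\\s+", " "))
  if (nrow(synonyms)) {
    cs <- as.logical(synonyms$case_sensitive)
    cs[is.na(cs)] <- stringi::stri_length(synonyms$text[is.na(cs)]) < ACRONYM_THRESHOLD
    synonyms$case_sensitive <- cs
  }
  obj <- structure(
    list(classes = classes, entries = entries, synonyms = synonyms,
         name = name, version = version),
    class = "terminology")
  validate_terminology(obj)
  obj
}

empty_classes <- function() {
  data.frame(class_id = character(), name = character(),
             parent_id = character(), description = character(),
             stringsAsFactors = FALSE)
}
empty_entries <- function() {
  data.frame(entry_id = character(), class_id = character(),
             preferred_name = character(), stringsAsFactors = FALSE)
}
empty_synonyms <- function() {
  data.frame(entry_id = character(), text = character(),
             case_sensitive = logical(), stringsAsFactors = FALSE)
}

#' Validate a terminology against its structural invariants
#'
#' Checks id uniqueness, parent resolution, acyclicity of the class forest,
#' entry-class referential integrity, and that every entry has at least one
#' non-empty synonym.
#'
#' @param term a `terminology`.
#' @return `term`, invisibly; stops with an informative error otherwise.
#' @export
validate_terminology <- function(term) {
  stopifnot(inherits(term, "terminology"))
  cl <- term$classes; en <- term$entries; sy <- term$synonyms
  dup <- cl$class_id[duplicated(cl$class_id)]
  if (length(dup))
    stop("structural error: duplicate class_id: ", paste(unique(dup), collapse = ", "))
  dup <- en$entry_id[duplicated(en$entry_id)]
  if (length(dup))
    stop("structural error: duplicate entry_id: ", paste(unique(dup), collapse = ", "))
  parent <- cl$parent_id
  known <- !is.na(parent) & parent != ""
  bad <- parent[known][!(parent[known] %in% cl$class_id)]
  if (length(bad))
    stop("reference error: unresolved parent_id: ", paste(unique(bad), collapse = ", "))
  # cycle detection: follow parents from each class
  pmap <- stats::setNames(parent, cl$class_id)
  for (c0 in cl$class_id) {
    seen <- character()
    cur <- c0
    while (!is.na(cur) && cur != "") {
      if (cur %in% seen)
        stop("cycle error: class parent links form a cycle: ",
             paste(c(seen[which(seen == cur):length(seen)], cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- pmap[[cur]]
      if (is.null(cur)) cur <- NA_character_
    }
  }
  if (nrow(en)) {
    bad <- en$class_id[!(en$class_id %in% cl$class_id)]
    if (length(bad))
      stop("reference error: entry class_id not in classes: ",
           paste(unique(bad), collapse = ", "))
  }
  if (nrow(sy)) {
    bad <- sy$entry_id[!(sy$entry_id %in% en$entry_id)]
    if (length(bad))
      stop("reference error: synonym entry_id not in entries: ",
           paste(unique(bad), collapse = ", "))
    if (any(!nzchar(sy$text)))
      stop("structural error: empty synonym text after whitespace normalization")
  }
  no_syn <- setdiff(en$entry_id, sy$entry_id)
  if (length(no_syn))
    stop("structural error: entries without synonyms: ",
         paste(no_syn, collapse = ", "))
  invisible(term)
}

#' Read a terminology from its tab-separated native format
#'
#' The format is UTF-8 TSV; lines starting with `#` are comments. Two record
#' types, keyed by the first column:
#' \preformatted{
#' C <TAB> class_id <TAB> name <TAB> parent_id_or_- <TAB> description
#' S <TAB> entry_id <TAB> class_id <TAB> preferred_name <TAB> synonym <TAB> cs|ci|-
#' }
#' One synonym per `S` line; `-` in the parent column marks a root class; `-`
#' in the case column requests the acronym default (see
#' [ACRONYM_THRESHOLD]). The result is independent of line order.
#'
#' @param path file path.
#' @param format only `"tsv"` is supported.
#' @return a [terminology] object.
#' @export
load_terminology <- function(path, format = "tsv") {
  format <- match.arg(format, "tsv")
  if (!file.exists(path)) stop("terminology file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(stringi::stri_trim_both(lines)) &
                  !stringi::stri_startswith_fixed(lines, "#"))
  cl <- list(); sy <- list()
  tname <- basename(path); tversion <- "0"
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    kind <- f[1]
    if (kind == "T") {           # optional metadata line: T name version
      if (length(f) >= 2) tname <- f[2]
      if (length(f) >= 3) tversion <- f[3]
    } else if (kind == "C") {
      if (length(f) < 4)
        stop("parse error at line ", i, ": C record needs 4+ fields")
      cl[[length(cl) + 1L]] <- data.frame(
        class_id = f[2], name = f[3],
        parent_id = if (f[4] %in% c("-", "")) NA_character_ else f[4],
        description = if (length(f) >= 5) f[5] else "",
        line = i, stringsAsFactors = FALSE)
    } else if (kind == "S") {
      if (length(f) < 5)
        stop("parse error at line ", i, ": S record needs 5+ fields")
      cs_field <- if (length(f) >= 6) f[6] else "-"
      cs <- switch(cs_field, cs = TRUE, ci = FALSE, "-" = NA, NA)
      sy[[length(sy) + 1L]] <- data.frame(
        entry_id = f[2], class_id = f[3], preferred_name = f[4],
        text = f[5], case_sensitive = cs, line = i, stringsAsFactors = FALSE)
    } else {
      stop("parse error at line ", i, ": unknown record type '", kind, "'")
    }
  }
  cl <- if (length(cl)) do.call(rbind, cl) else cbind(empty_classes(), line = integer())
  sy <- if (length(sy)) do.call(rbind, sy) else
    cbind(data.frame(entry_id = character(), class_id = character(),
                     preferred_name = character(), text = character(),
                     case_sensitive = logical(), stringsAsFactors = FALSE),
          line = integer())
  if (anyDuplicated(cl$class_id)) {
    d <- cl[duplicated(cl$class_id), , drop = FALSE]
    stop("structural error at line ", d$line[1], ": duplicate class_id '",
         d$class_id[1], "'")
  }
  # entry table: one row per entry_id; consistency of class/preferred name
  if (nrow(sy)) {
    first <- !duplicated(sy$entry_id)
    en <- sy[first, c("entry_id", "class_id", "preferred_name"), drop = FALSE]
    chk <- merge(sy, en, by = "entry_id", suffixes = c("", ".first"))
    bad <- chk[chk$class_id != chk$class_id.first |
                 chk$preferred_name != chk$preferred_name.first, , drop = FALSE]
    if (nrow(bad))
      stop("structural error at line ", bad$line[1], ": entry '", bad$entry_id[1],
           "' redeclared with a different class or preferred name")
  } else {
    en <- empty_entries()
  }
  # canonical order: ids sorted, so the result is independent of line order
  cl <- cl[order(cl$class_id), c("class_id", "name", "parent_id", "description")]
  en <- en[order(en$entry_id), , drop = FALSE]
  sy <- sy[order(sy$entry_id, sy$text), c("entry_id", "text", "case_sensitive")]
  rownames(cl) <- rownames(en) <- rownames(sy) <- NULL
  terminology(classes = cl, entries = en, synonyms = sy,
              name = tname, version = tversion)
}

#' Write a terminology to the native TSV format
#'
#' Inverse of [load_terminology()]: `load_terminology(write_terminology(t))`
#' reproduces `t` field-for-field.
#'
#' @param term a [terminology].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_terminology <- function(term, path) {
  validate_terminology(term)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste("T", term$name, term$version, sep = "\t"), con)
  cl <- term$classes
  if (nrow(cl)) {
    writeLines(paste("C", cl$class_id, cl$name,
                     ifelse(is.na(cl$parent_id), "-", cl$parent_id),
                     cl$description, sep = "\t"), con)
  }
  if (nrow(term$synonyms)) {
    sy <- merge(term$synonyms, term$entries, by = "entry_id", sort = FALSE)
    sy <- sy[order(sy$entry_id, sy$text), , drop = FALSE]
    writeLines(paste("S", sy$entry_id, sy$class_id, sy$preferred_name, sy$text,
                     ifelse(sy$case_sensitive, "cs", "ci"), sep = "\t"), con)
  }
  invisible(path)
}

#' Class subtree
#'
#' All class ids reachable downwards from `class_id`, including itself.
#' Selecting a class in a query means selecting its whole subtree, so an
#' internal node stands for itself plus all transitive descendants.
#'
#' @param term a [terminology].
#' @param class_id root of the subtree.
#' @return character vector of class ids (sorted).
#' @export
subtree <- function(term, class_id) {
  stopifnot(inherits(term, "terminology"))
  if (!(class_id %in% term$classes$class_id))
    stop("lookup error: unknown class_id '", class_id, "'")
  out <- character(); frontier <- class_id
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- term$classes$class_id[!is.na(term$classes$parent_id) &
                                        term$classes$parent_id %in% frontier]
  }
  sort(unique(out))
}

#' Entries belonging to a set of classes
#'
#' @param term a [terminology].
#' @param class_ids character vector of class ids (not expanded to subtrees;
#'   combine with [subtree()] when tree semantics are wanted).
#' @return the `entries` data.frame rows whose class is in `class_ids`.
#' @export
entries_in <- function(term, class_ids) {
  stopifnot(inherits(term, "terminology"))
  unknown <- setdiff(class_ids, term$classes$class_id)
  if (length(unknown))
    stop("lookup error: unknown class_id: ", paste(unknown, collapse = ", "))
  out <- term$entries[term$entries$class_id %in% class_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two terminologies
#'
#' Classes and entries are unioned. When both sides declare the same
#' `entry_id`, the synonym lists are unioned with set semantics on
#' `(text, case_sensitive)`; the base terminology's class assignment and
#' preferred name win. The same `class_id` declared with two different
#' parents is a conflict error, since it would change the hierarchy shape.
#' Typical use: extending the Diagnostics class for a new disease area.
#'
#' @param base,extension [terminology] objects.
#' @return the merged [terminology].
#' @export
merge_terminology <- function(base, extension) {
  stopifnot(inherits(base, "terminology"), inherits(extension, "terminology"))
  shared <- intersect(base$classes$class_id, extension$classes$class_id)
  if (length(shared)) {
    pb <- base$classes$parent_id[match(shared, base$classes$class_id)]
    pe <- extension$classes$parent_id[match(shared, extension$classes$class_id)]
    bad <- shared[ifelse(is.na(pb) | is.na(pe), !(is.na(pb) & is.na(pe)), pb != pe)]
    if (length(bad))
      stop("conflict error: class declared with different parents: ",
           paste(bad, collapse = ", "))
  }
  cl <- rbind(base$classes,
              extension$classes[!(extension$classes$class_id %in% shared), ,
                                drop = FALSE])
  en <- rbind(base$entries,
              extension$entries[!(extension$entries$entry_id %in%
                                    base$entries$entry_id), , drop = FALSE])
  sy <- rbind(base$synonyms, extension$synonyms)
  sy <- sy[!duplicated(sy[c("entry_id", "text", "case_sensitive")]), , drop = FALSE]
  cl <- cl[order(cl$class_id), , drop = FALSE]
  en <- en[order(en$entry_id), , drop = FALSE]
  sy <- sy[order(sy$entry_id, sy$text), , drop = FALSE]
  rownames(cl) <- rownames(en) <- rownames(sy) <- NULL
  terminology(classes = cl, entries = en, synonyms = sy,
              name = base$name, version = base$version)
}

#' Terminology size statistics
#'
#' @param term a [terminology].
#' @return list with `n_classes`, `n_entries`, `n_synonyms`; the synonym
#'   count is over distinct `(entry_id, text)` pairs, i.e. the same surface
#'   string attached to two entries counts twice, matching how dictionary
#'   size is usually reported for per-concept synonym lists.
#' @export
term_stats <- function(term) {
  stopifnot(inherits(term, "terminology"))
  list(n_classes = nrow(term$classes),
       n_entries = nrow(term$entries),
       n_synonyms = nrow(unique(term$synonyms[c("entry_id", "text")])))
}

#' @export
print.terminology <- function(x, ...) {
  s <- term_stats(x)
  cat(sprintf("<terminology '%s' v%s: %d classes, %d entries, %d synonyms>\n",
              x$name, x$version, s$n_classes, s$n_entries, s$n_synonyms))
  invisible(x)
}
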