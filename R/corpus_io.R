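# Reading raw metadata tables and normalizing free text into token streams.

# Compact English stopword list. Tokens on this list carry no tissue/disease
# signal and are stripped during preprocessing (configurable).
.stopwords <- c(
  "a", "about", "above", "after", "again", "against", "all", "also", "am",
  "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "could", "did",
  "do", "does", "doing", "down", "during", "each", "few", "for", "from",
  "further", "had", "has", "have", "having", "he", "her", "here", "hers",
  "him", "his", "how", "i", "if", "in", "into", "is", "it", "its", "itself",
  "just", "me", "more", "most", "my", "no", "nor", "not", "now", "of", "off",
  "on", "once", "only", "or", "other", "our", "out", "over", "own", "per",
  "please", "same", "see", "she", "should", "so", "some", "such", "than",
  "that", "the", "their", "them", "then", "there", "these", "they", "this",
  "those", "through", "to", "too", "under", "until", "up", "upon", "using",
  "very", "was", "we", "were", "what", "when", "where", "which", "while",
  "who", "whom", "why", "will", "with", "would", "you", "your"
)

#' Default metadata fields per description level
#'
#' Sample-level records (per-specimen descriptions, tissue-rich) and
#' study-level records (per-experiment summaries, disease-rich) carry their
#' information in different named fields. These defaults name the GEO-style
#' fields most likely to describe the biological source; they can be
#' overridden wherever a `field_selection` argument is accepted.
#'
#' @param level `"sample"` or `"study"`.
#' @return Character vector of field names, in concatenation order.
#' @export
default_fields <- function(level = c("sample", "study")) {
  level <- match.arg(level)
  switch(level,
    sample = c("title", "source_name", "characteristics", "description"),
    study  = c("title", "summary", "overall_design")
  )
}

#' Load a metadata table
#'
#' Reads one record per sample or study from a TSV file (header row names the
#' fields; the first column is the instance identifier) or a JSON array of
#' objects (each object must carry an `instance_id` key). Only the selected
#' fields are retained, in the given order; a selected field absent from a
#' record becomes empty text (reported via [message()]), never an error.
#'
#' @param path Path to a TSV (`.tsv`/`.txt`) or JSON (`.json`) file.
#' @param field_selection Character vector of field names to keep, in order.
#' @param level Description level of every record: `"sample"` or `"study"`.
#' @return A list of raw metadata records; each is a list with elements
#'   `instance_id`, `level`, and `fields` (named character vector).
#' @export
load_metadata_table <- function(path, field_selection = NULL,
                                level = c("sample", "study")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("metadata file not found: ", path)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (is_json) {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.list(recs)) stop("JSON metadata must be an array of objects")
    ids <- vapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      if (is.null(r$instance_id)) {
        stop("malformed JSON metadata: record ", i, " lacks instance_id")
      }
      as.character(r$instance_id)
    }, character(1))
    rows <- lapply(recs, function(r) {
      f <- r[setdiff(names(r), "instance_id")]
      vapply(f, function(v) paste(as.character(v), collapse = " "), character(1))
    })
  } else {
    tab <- utils::read.delim(path, colClasses = "character",
                             check.names = FALSE, quote = "",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 1) stop("malformed TSV metadata: no columns in ", path)
    ids <- tab[[1]]
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      v <- as.character(tab[i, -1, drop = TRUE])
      names(v) <- colnames(tab)[-1]
      v
    })
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate instance_id in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (is.null(field_selection)) field_selection <- default_fields(level)
  n_missing <- 0L
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    avail <- rows[[i]]
    sel <- vapply(field_selection, function(f) {
      if (f %in% names(avail)) avail[[f]] else NA_character_
    }, character(1))
    n_missing <- n_missing + sum(is.na(sel))
    sel[is.na(sel)] <- ""
    names(sel) <- field_selection
    out[[i]] <- list(instance_id = ids[i], level = level, fields = sel)
  }
  if (n_missing > 0) {
    message("load_metadata_table: ", n_missing,
            " selected field value(s) missing; treated as empty text")
  }
  out
}

.url_pattern <- "(?i)\\b(?:[a-z][a-z0-9+.-]*://\\S+|www\\.\\S+)"

#' Normalize free text into tokens
#'
#' Applies the package's canonical text normalization: URL spans are removed
#' first, remaining text is lowercased, and maximal runs of `[a-z0-9]` become
#' tokens (every other character is a separator). Common English stopwords
#' are then dropped. No stemming or lemmatization is applied.
#'
#' @param text Character vector; elements are concatenated with single spaces.
#' @param remove_stopwords Drop built-in English stopwords (default `TRUE`).
#' @return Character vector of lowercase tokens (possibly empty).
#' @export
tokenize_text <- function(text, remove_stopwords = TRUE) {
  txt <- paste(text, collapse = " ")
  txt <- gsub(.url_pattern, " ", txt, perl = TRUE)
  txt <- tolower(txt)
  toks <- regmatches(txt, gregexpr("[a-z0-9]+", txt))[[1]]
  if (remove_stopwords && length(toks)) toks <- toks[!(toks %in% .stopwords)]
  toks
}

#' Preprocess a raw metadata record into a document
#'
#' Concatenates the record's fields in selection order (single space between
#' fields) and normalizes the text with [tokenize_text()]. Empty input yields
#' an empty document, never an error.
#'
#' @param raw A raw metadata record as returned by [load_metadata_table()],
#'   or any list with `instance_id`, `level`, and a character `fields`.
#' @param remove_stopwords Passed to [tokenize_text()].
#' @return A `metadoc` object: list with `instance_id`, `level`, `tokens`
#'   (ordered lowercase tokens) and `text` (space-joined tokens).
#' @export
preprocess <- function(raw, remove_stopwords = TRUE) {
  toks <- tokenize_text(unname(raw$fields), remove_stopwords = remove_stopwords)
  structure(
    list(instance_id = raw$instance_id,
         level = if (is.null(raw$level)) "sample" else raw$level,
         tokens = toks,
         text = paste(toks, collapse = " ")),
    class = "metadoc"
  )
}

#' Build a document directly from tokens
#'
#' Convenience constructor used by the synthetic-corpus generator and tests.
#'
#' @param instance_id Identifier string.
#' @param tokens Character vector of lowercase tokens.
#' @param level `"sample"` or `"study"`.
#' @return A `metadoc` object.
#' @export
document <- function(instance_id, tokens, level = "sample") {
  structure(
    list(instance_id = instance_id, level = level,
         tokens = as.character(tokens),
         text = paste(tokens, collapse = " ")),
    class = "metadoc"
  )
}

#' @method print metadoc
#' @export
print.metadoc <- function(x, ...) {
  cat("<metadoc ", x$instance_id, " (", x$level, "): ",
      length(x$tokens), " tokens>\n", sep = "")
  invisible(x)
}

#' Preprocess a full metadata table into a document corpus
#'
#' @param raws List of raw metadata records ([load_metadata_table()] output).
#' @param remove_stopwords Passed to [preprocess()].
#' @return List of `metadoc` objects, in input order.
#' @export
preprocess_corpus <- function(raws, remove_stopwords = TRUE) {
  lapply(raws, preprocess, remove_stopwords = remove_stopwords)
}
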