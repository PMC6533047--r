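#' Normalize query text for matching
#'
#' Lowercases, strips punctuation to spaces, and collapses whitespace. Both
#' the lexicon matcher and seed-query aggregation use this normalization so
#' that "AA Meeting, near me!" and "aa meeting near me" are the same query.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- as.character(x)
  # normalize unique strings once: logs repeat a small query vocabulary
  uq <- unique(x)
  norm <- trimws(gsub("[^a-z0-9]+", " ", tolower(uq)))
  norm[match(x, uq)]
}

#' Load a symptom synonym lexicon
#'
#' The lexicon maps canonical medical symptom names to colloquial synonym
#' phrases, so that e.g. a query for "sweating" is counted under the clinical
#' descriptor "diaphoresis". The file is two-column tab-separated with header
#' `canonical_symptom<TAB>synonym`, one synonym per row. Every canonical name
#' is added to its own synonym list if absent, duplicate rows are dropped with
#' a warning, and a synonym mapped to two different canonicals is an error
#' (contingency counting requires an unambiguous symptom indicator).
#'
#' @param path path to the lexicon file.
#' @return an object of class `symptom_lexicon`: a list with `entries`
#'   (named list of synonym character vectors, names = canonical symptoms)
#'   and `size` (number of canonical symptoms).
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) {
    stop("lexicon file does not exist: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL)
  if (!all(c("canonical_symptom", "synonym") %in% names(tab))) {
    stop("lexicon file must have columns canonical_symptom and synonym",
         call. = FALSE)
  }
  if (nrow(tab) == 0) {
    stop("empty lexicon file: ", path, call. = FALSE)
  }
  symptom_lexicon(stats::setNames(tab$synonym, tab$canonical_symptom))
}

#' Construct a symptom lexicon from (canonical, synonym) pairs
#'
#' @param pairs named character vector: names are canonical symptoms, values
#'   synonym phrases (repeat a name for several synonyms), or a named list of
#'   synonym character vectors.
#' @return a `symptom_lexicon`; see [read_lexicon()].
#' @export
symptom_lexicon <- function(pairs) {
  if (is.list(pairs)) {
    canonical <- rep(names(pairs), lengths(pairs))
    synonym <- unlist(pairs, use.names = FALSE)
  } else {
    canonical <- names(pairs)
    synonym <- unname(pairs)
  }
  if (is.null(canonical) || any(is.na(canonical)) || any(canonical == "")) {
    stop("every synonym needs a canonical symptom name", call. = FALSE)
  }
  canonical <- normalize_text(canonical)
  synonym <- normalize_text(synonym)
  if (any(synonym == "")) {
    stop("synonym phrases must be non-empty", call. = FALSE)
  }
  n_user_dup <- sum(duplicated(paste(canonical, synonym, sep = "\r")))
  if (n_user_dup > 0) {
    warning(n_user_dup, " duplicate (canonical, synonym) row(s) dropped",
            call. = FALSE)
  }
  # self-match: the canonical name is always one of its own synonyms
  canon_all <- c(canonical, unique(canonical))
  syn_all <- c(synonym, unique(canonical))
  keep <- !duplicated(paste(canon_all, syn_all, sep = "\r"))
  canon_all <- canon_all[keep]
  syn_all <- syn_all[keep]
  amb <- tapply(canon_all, syn_all, function(z) length(unique(z)))
  if (any(amb > 1)) {
    stop("ambiguous lexicon: synonym(s) mapped to multiple canonicals: ",
         paste(names(amb)[amb > 1], collapse = ", "), call. = FALSE)
  }
  entries <- split(syn_all, canon_all)
  entries <- entries[unique(canon_all)]
  structure(list(entries = entries, size = length(entries)),
            class = "symptom_lexicon")
}

#' @export
print.symptom_lexicon <- function(x, ...) {
  cat(sprintf("<symptom_lexicon> %d canonical symptoms, %d synonym phrases\n",
              x$size, sum(lengths(x$entries))))
  invisible(x)
}

#' Canonical symptoms of a lexicon
#' @param lexicon a `symptom_lexicon`.
#' @return character vector of canonical symptom names.
#' @export
lexicon_symptoms <- function(lexicon) {
  stopifnot(inherits(lexicon, "symptom_lexicon"))
  names(lexicon$entries)
}

# Pad with spaces so fixed-string containment is whole-word phrase
# containment: synonym " dry mouth " matches query " cure dry mouth " but
# "rash" does not match "crash".
pad <- function(x) paste0(" ", x, " ")

#' Map one query to canonical symptoms
#'
#' A query matches a symptom when one of the symptom's synonym phrases occurs
#' as a contiguous whole-word token sequence in the query, case-insensitively
#' and ignoring punctuation. Returns the set of all matching canonical
#' symptoms (possibly empty).
#'
#' @param query_text a single query string.
#' @param lexicon a [symptom_lexicon()].
#' @return character vector of canonical symptoms (sorted, no duplicates).
#' @export
match_query <- function(query_text, lexicon) {
  stopifnot(length(query_text) == 1)
  hits <- match_query_table(query_text, lexicon)
  sort(unique(hits$symptom))
}

#' Match many query strings against a lexicon
#'
#' Vectorized matcher: returns one row per (query, canonical symptom) hit.
#' Duplicate query strings are matched once and the result recycled, so large
#' synthetic logs with small vocabularies annotate quickly.
#'
#' @param query_text character vector of query strings.
#' @param lexicon a [symptom_lexicon()].
#' @return tibble with columns `index` (position in `query_text`) and
#'   `symptom`.
#' @export
match_query_table <- function(query_text, lexicon) {
  stopifnot(inherits(lexicon, "symptom_lexicon"))
  norm <- normalize_text(query_text)
  uq <- unique(norm)
  padded <- pad(uq)
  canon <- rep(names(lexicon$entries), lengths(lexicon$entries))
  syns <- pad(unlist(lexicon$entries, use.names = FALSE))
  hit_q <- integer(0)
  hit_s <- character(0)
  for (j in seq_along(syns)) {
    h <- which(grepl(syns[j], padded, fixed = TRUE))
    if (length(h) > 0) {
      hit_q <- c(hit_q, h)
      hit_s <- c(hit_s, rep(canon[j], length(h)))
    }
  }
  per_uq <- tibble(uqi = hit_q, symptom = hit_s)
  per_uq <- dplyr::distinct(per_uq)
  idx <- tibble(index = seq_along(norm), uqi = match(norm, uq))
  out <- dplyr::inner_join(idx, per_uq, by = "uqi", relationship = "many-to-many")
  tibble(index = out$index, symptom = out$symptom)
}

#' Annotate every event of a log with its matched symptoms
#'
#' Applies [match_query()] to each event. Matching is deterministic and
#' independent across events.
#'
#' @param log a [search_log()].
#' @param lexicon a [symptom_lexicon()].
#' @return tibble with one row per event, in log order: the four log columns
#'   plus a list-column `symptoms` of canonical symptom character vectors.
#' @export
annotate_log <- function(log, lexicon) {
  stopifnot(inherits(log, "search_log"))
  ev <- log$events
  hits <- match_query_table(ev$query_text, lexicon)
  symptoms <- rep(list(character(0)), nrow(ev))
  if (nrow(hits) > 0) {
    hits <- hits[order(hits$index, hits$symptom), ]
    grouped <- split(hits$symptom, hits$index)
    symptoms[as.integer(names(grouped))] <- grouped
  }
  ev$symptoms <- symptoms
  ev
}

#' Long-format symptom hits of an event table
#'
#' Internal-leaning helper used by the screens: one row per (event, symptom)
#' match, carrying the event's user and timestamp.
#'
#' @param events event tibble (log columns).
#' @param lexicon a [symptom_lexicon()].
#' @return tibble with columns `user_id`, `timestamp`, `symptom`.
#' @export
symptom_hits <- function(events, lexicon) {
  hits <- match_query_table(events$query_text, lexicon)
  tibble(
    user_id = events$user_id[hits$index],
    timestamp = events$timestamp[hits$index],
    symptom = hits$symptom
  )
}

#' Path to the packaged fixture lexicon
#'
#' A ~35-symptom stand-in lexicon covering the symptom vocabulary used in the
#' package's examples and simulations. Real analyses should supply their own,
#' larger lexicon file.
#'
#' @return file path.
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "symptom_lexicon.tsv", package = "symptomlag",
              mustWork = TRUE)
}
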