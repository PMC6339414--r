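#' Load the cue configuration for finding extraction
#'
#' Cue lexicons are editable data, not code: a YAML file lists negation cues,
#' ability / frequency / course qualifier cues, the token window within which
#' a cue can govern a term, and sentence-break punctuation.
#'
#' @param path YAML file; defaults to the packaged configuration.
#' @return a list with elements `window`, `negation_cues`, `ability_cues`,
#'   `frequency_cues`, `course_cues`, `sentence_breaks`.
#' @export
extraction_config <- function(path = NULL) {
  if (is.null(path)) path <- ccfo_extdata("cues.yaml")
  cfg <- yaml::read_yaml(path)
  stopifnot(is.numeric(cfg$window), cfg$window >= 1)
  cfg
}

#' Normalize clinical text
#'
#' Lowercases, collapses whitespace runs to single spaces, and keeps
#' punctuation as token boundaries. Returns an offset map back into the
#' original string so that matches on the normalized text can be reported as
#' spans of the source document.
#'
#' @param text a single string.
#' @return list with `text` (normalized) and `map` (integer vector: for each
#'   character of the normalized text, its 1-based position in the original).
#' @export
normalize_text <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(list(text = "", map = integer()))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_ws <- grepl("^\\s$", chars)
  keep <- logical(length(chars))
  out <- character(0)
  map <- integer(0)
  prev_ws <- TRUE    # leading whitespace dropped
  for (i in seq_along(chars)) {
    if (is_ws[i]) {
      if (!prev_ws) {
        out <- c(out, " ")
        map <- c(map, i)
        prev_ws <- TRUE
      }
    } else {
      out <- c(out, tolower(chars[i]))
      map <- c(map, i)
      prev_ws <- FALSE
    }
  }
  # drop a trailing space
  if (length(out) > 0 && out[length(out)] == " ") {
    out <- out[-length(out)]
    map <- map[-length(map)]
  }
  list(text = paste(out, collapse = ""), map = map)
}

# Tokenize text into words with original character offsets (0-based,
# half-open) and sentence ids. Words may contain internal hyphens, slashes
# and apostrophes ("bed-ridden", "w/c").
tokenize <- function(text, sentence_breaks = c(".", ";", "\n")) {
  lowered <- tolower(text)
  m <- gregexpr("[a-z0-9]+(?:[-/'][a-z0-9]+)*", lowered, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      sentence = integer(), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tokens <- substring(lowered, starts, starts + lens - 1)
  brk_re <- paste0("[", gsub("([.;\\\\])", "\\\\\\1",
                             paste(sentence_breaks, collapse = "")), "]")
  brks <- gregexpr(brk_re, lowered)[[1]]
  brks <- if (brks[1] == -1) integer() else as.integer(brks)
  sentence <- vapply(starts, function(s) sum(brks < s), integer(1)) + 1L
  data.frame(token = tokens, start = starts - 1L, end = starts + lens - 1L,
             sentence = sentence, stringsAsFactors = FALSE)
}

split_tokens <- function(surface) {
  strsplit(gsub("[^a-z0-9/'-]+", " ", tolower(surface)), " +")[[1]]
}

# Positions (token indices) at which any cue of `cues` occurs; cues may be
# multi-token. Returns data.frame(pos_start, pos_end, cue).
cue_positions <- function(tokens, cues) {
  out <- list()
  for (cue in cues) {
    ct <- split_tokens(cue)
    n <- length(ct)
    if (n == 0 || length(tokens) < n) next
    for (i in seq_len(length(tokens) - n + 1)) {
      if (all(tokens[i:(i + n - 1)] == ct)) {
        out[[length(out) + 1]] <- data.frame(pos_start = i, pos_end = i + n - 1,
                                             cue = cue, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    data.frame(pos_start = integer(), pos_end = integer(), cue = character())
  } else do.call(rbind, out)
}

# Level of the nearest cue (over a named list level -> cue vector) outside the
# match span [s, e], within `window` tokens, same sentence assumed upstream.
# Preceding cue wins on an exact distance tie.
nearest_cue_level <- function(tokens, s, e, cue_sets, window) {
  best_level <- NA_character_
  best_dist <- Inf
  best_precedes <- FALSE
  for (level in names(cue_sets)) {
    cp <- cue_positions(tokens, cue_sets[[level]])
    for (i in seq_len(nrow(cp))) {
      if (cp$pos_start[i] <= e && cp$pos_end[i] >= s) next  # inside the match
      if (cp$pos_end[i] < s) {
        d <- s - cp$pos_end[i]
        precedes <- TRUE
      } else {
        d <- cp$pos_start[i] - e
        precedes <- FALSE
      }
      if (d > window) next
      if (d < best_dist || (d == best_dist && precedes && !best_precedes)) {
        best_dist <- d
        best_level <- level
        best_precedes <- precedes
      }
    }
  }
  best_level
}

# A cue level intrinsic to the matched surface itself ("unable to run").
intrinsic_level <- function(surface_tokens, cue_sets) {
  for (level in names(cue_sets)) {
    if (nrow(cue_positions(surface_tokens, cue_sets[[level]])) > 0) return(level)
  }
  NA_character_
}

build_lexicon <- function(ont) {
  surf <- setdiff(ont$terms$surface, ont$excluded_terms)
  toks <- lapply(surf, split_tokens)
  data.frame(surface = surf,
             ccfo_id = ont$terms$ccfo_id[match(surf, ont$terms$surface)],
             n_tokens = lengths(toks), stringsAsFactors = FALSE) ->
    lex
  lex$tokens <- toks
  lex
}

#' Match lexicon terms in text
#'
#' Greedy longest-match, left to right, at word boundaries; matches are
#' non-overlapping and never cross a sentence break; excluded ambiguous
#' surfaces never match. Offsets are 0-based half-open spans of the original
#' text.
#'
#' @param ont a validated `ccfo_ontology`.
#' @param text document text.
#' @param config cue configuration (for sentence breaks), see
#'   [extraction_config()].
#' @return data.frame with columns `surface`, `ccfo_id`, `start`, `end`,
#'   `sentence`, sorted by `start`.
#' @export
match_terms <- function(ont, text, config = extraction_config()) {
  tk <- tokenize(text, config$sentence_breaks)
  lex <- build_lexicon(ont)
  out <- list()
  i <- 1
  n <- nrow(tk)
  max_len <- if (nrow(lex) > 0) max(lex$n_tokens) else 0
  lex_key <- vapply(lex$tokens, function(t) paste(t, collapse = " "), "")
  while (i <= n && max_len > 0) {
    matched <- FALSE
    for (len in seq(min(max_len, n - i + 1), 1)) {
      if (len > 1 && tk$sentence[i + len - 1] != tk$sentence[i]) next
      cand <- paste(tk$token[i:(i + len - 1)], collapse = " ")
      hit <- which(lex$n_tokens == len & lex_key == cand)
      if (length(hit) > 0) {
        out[[length(out) + 1]] <- data.frame(
          surface = lex$surface[hit[[1]]], ccfo_id = lex$ccfo_id[hit[[1]]],
          start = tk$start[i], end = tk$end[i + len - 1],
          sentence = tk$sentence[i], tok_start = i, tok_end = i + len - 1,
          stringsAsFactors = FALSE)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1
  }
  if (length(out) == 0) {
    return(data.frame(surface = character(), ccfo_id = character(),
                      start = integer(), end = integer(), sentence = integer(),
                      tok_start = integer(), tok_end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Resolve qualifier and course for a term match
#'
#' The qualifier cue nearest to the match inside the same sentence (within the
#' configured token window) is mapped onto the concept's permitted axis; a cue
#' intrinsic to the matched surface itself ("unable to run") overrides
#' contextual cues. Concepts whose score table has a single "only-level" row
#' take the fixed qualifier `"only-level"`. Course cues (chronic / transient /
#' sudden) resolve on an independent axis for any finding.
#'
#' @param ont a validated `ccfo_ontology`.
#' @param match one row from [match_terms()].
#' @param text the document the match came from.
#' @param config cue configuration.
#' @return list with `qualifier` (level or `"unqualified"` / `"only-level"`)
#'   and `course` (level or `NA`).
#' @export
resolve_qualifier <- function(ont, match, text, config = extraction_config()) {
  tk <- tokenize(text, config$sentence_breaks)
  sent <- tk[tk$sentence == match$sentence, , drop = FALSE]
  s <- match$tok_start - min(which(tk$sentence == match$sentence)) + 1
  e <- match$tok_end - min(which(tk$sentence == match$sentence)) + 1
  axis <- concept_axis(ont, match$ccfo_id)
  course <- nearest_cue_level(sent$token, s, e, config$course_cues, config$window)
  if (axis == "only-level") {
    return(list(qualifier = "only-level", course = course))
  }
  cue_sets <- if (axis == "ability-interpretation") config$ability_cues else
    config$frequency_cues
  q <- intrinsic_level(split_tokens(match$surface), cue_sets)
  if (is.na(q)) q <- nearest_cue_level(sent$token, s, e, cue_sets, config$window)
  if (is.na(q)) q <- "unqualified"
  list(qualifier = q, course = course)
}

#' Assertion status of a term match
#'
#' A match is negated iff a negation cue precedes it within the same sentence
#' and within the configured token window; otherwise it is asserted. Cues
#' occurring inside the matched surface do not negate it.
#'
#' @inheritParams resolve_qualifier
#' @return `"asserted"` or `"negated"`.
#' @export
detect_assertion <- function(ont, match, text, config = extraction_config()) {
  tk <- tokenize(text, config$sentence_breaks)
  idx <- which(tk$sentence == match$sentence)
  sent <- tk[idx, , drop = FALSE]
  s <- match$tok_start - min(idx) + 1
  cp <- cue_positions(sent$token, config$negation_cues)
  cp <- cp[cp$pos_end < s & (s - cp$pos_end) <= config$window, , drop = FALSE]
  if (nrow(cp) > 0) "negated" else "asserted"
}

#' Extract frailty findings from a document
#'
#' Composition of tokenization, longest-match term lookup, qualifier/course
#' resolution and assertion detection. Deterministic for a fixed document and
#' configuration. For frequency-axis concepts a preceding negation cue
#' produces a negated finding carrying the `absent` qualifier (denied
#' symptoms are scoreable absence evidence); for ability and status concepts
#' negation affects assertion only.
#'
#' @param ont a validated `ccfo_ontology`.
#' @param document a single document string.
#' @param config cue configuration, see [extraction_config()].
#' @return data.frame of findings: `concept_id`, `qualifier`, `course`,
#'   `assertion`, `start`, `end`, `surface`.
#' @export
extract_findings <- function(ont, document, config = extraction_config()) {
  empty <- data.frame(concept_id = character(), qualifier = character(),
                      course = character(), assertion = character(),
                      start = integer(), end = integer(), surface = character(),
                      stringsAsFactors = FALSE)
  if (is.na(document) || !nzchar(document)) return(empty)
  matches <- match_terms(ont, document, config)
  if (nrow(matches) == 0) return(empty)
  rows <- lapply(seq_len(nrow(matches)), function(i) {
    m <- matches[i, , drop = FALSE]
    qc <- resolve_qualifier(ont, m, document, config)
    assertion <- detect_assertion(ont, m, document, config)
    qualifier <- qc$qualifier
    if (assertion == "negated" &&
        concept_axis(ont, m$ccfo_id) == "frequency") {
      qualifier <- "absent"
    }
    data.frame(concept_id = m$ccfo_id, qualifier = qualifier,
               course = ifelse(is.na(qc$course), NA_character_, qc$course),
               assertion = assertion, start = m$start, end = m$end,
               surface = m$surface, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Construct a finding record by hand
#'
#' Convenience constructor for building finding sets directly (for scoring or
#' tests) without running text extraction.
#'
#' @param concept_id CCFOID of the finding's concept.
#' @param qualifier qualifier level, `"unqualified"`, or `"only-level"`.
#' @param course course level or `NA`.
#' @param assertion `"asserted"` or `"negated"`.
#' @return one-row findings data.frame.
#' @export
finding <- function(concept_id, qualifier = "unqualified", course = NA,
                    assertion = "asserted") {
  stopifnot(assertion %in% c("asserted", "negated"))
  data.frame(concept_id = as.character(concept_id), qualifier = qualifier,
             course = as.character(course), assertion = assertion,
             start = NA_integer_, end = NA_integer_, surface = NA_character_,
             stringsAsFactors = FALSE)
}

#' Bind finding records into one finding set
#'
#' @param ... one-row data.frames from [finding()] or finding data.frames.
#' @return findings data.frame.
#' @export
findings <- function(...) {
  do.call(rbind, list(...))
}

#' Write findings as JSON lines
#'
#' One JSON object per finding, with a `doc_id` field.
#'
#' @param fnd findings data.frame.
#' @param path output file.
#' @param doc_id document identifier recorded on every line.
#' @return `path`, invisibly.
#' @export
write_findings_jsonl <- function(fnd, path, doc_id = "doc1") {
  lines <- vapply(seq_len(nrow(fnd)), function(i) {
    rec <- c(list(doc_id = doc_id), as.list(fnd[i, , drop = FALSE]))
    jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read findings from JSON lines
#'
#' @param path JSONL file written by [write_findings_jsonl()].
#' @return findings data.frame (with `doc_id` column).
#' @export
read_findings_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[vapply(rec, is.null, logical(1))] <- NA
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
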