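#' Published interpretation criteria for ten frailty instruments
#'
#' Criteria are shipped as a TSV data file: instrument key, recognized
#' aliases, scale bounds, and ordered closed integer intervals with their
#' category labels, frailty indication and scale direction. Rows whose
#' printed criteria are internally inconsistent or direction-only carry a
#' `caution` flag and are stored verbatim rather than silently corrected.
#'
#' @param path optional alternative criteria TSV.
#' @return data.frame of criteria rows.
#' @export
instrument_criteria <- function(path = NULL) {
  if (is.null(path)) path <- ccfo_extdata("instrument_criteria.tsv")
  df <- read.delim(path, sep = "\t", colClasses = "character", quote = "",
                   fill = TRUE, fileEncoding = "UTF-8")
  for (col in c("scale_min", "scale_max", "lo", "hi")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$caution <- toupper(trimws0(df$caution)) == "TRUE"
  if (!"notes" %in% names(df)) df$notes <- NA_character_
  df
}

criteria_for <- function(instrument, criteria = instrument_criteria()) {
  key <- tolower(trimws(instrument))
  rows <- criteria[tolower(criteria$instrument) == key, , drop = FALSE]
  if (nrow(rows) == 0) {
    # try aliases
    hit <- vapply(criteria$aliases, function(a) {
      key %in% tolower(trimws(strsplit(a, ";", fixed = TRUE)[[1]]))
    }, logical(1))
    rows <- criteria[hit, , drop = FALSE]
  }
  if (nrow(rows) == 0) stop("unknown instrument: ", instrument)
  rows
}

#' Scale metadata for an instrument
#'
#' @param instrument instrument key or alias (case-insensitive).
#' @param criteria criteria table, see [instrument_criteria()].
#' @return list with `instrument`, `min`, `max`, `thresholds` (data.frame of
#'   intervals and labels) and `notes`.
#' @export
scale_metadata <- function(instrument, criteria = instrument_criteria()) {
  rows <- criteria_for(instrument, criteria)
  list(instrument = rows$instrument[[1]],
       min = rows$scale_min[[1]], max = rows$scale_max[[1]],
       thresholds = rows[, c("lo", "hi", "label", "indication")],
       notes = unique(rows$notes[!is.na(rows$notes)]))
}

#' Interpret a raw instrument score
#'
#' Maps a raw score onto the published category for its interval, and derives
#' a frailty indication (frail-indicative / intermediate /
#' not-frail-indicative / unmapped) from the instrument's direction.
#'
#' @param instrument instrument key or alias.
#' @param raw numeric raw score, inside the instrument's scale bounds.
#' @param criteria criteria table.
#' @return list of class `ccfo_interpreted_score`: `instrument`, `raw`,
#'   `category`, `indication`, `caution`.
#' @export
interpret_score <- function(instrument, raw, criteria = instrument_criteria()) {
  rows <- criteria_for(instrument, criteria)
  lo <- rows$scale_min[[1]]
  hi <- rows$scale_max[[1]]
  if (is.na(raw) || raw < lo || raw > hi) {
    stop(sprintf("score %s out of bounds [%s, %s] for instrument '%s'",
                 format(raw), format(lo), format(hi), rows$instrument[[1]]))
  }
  hit <- which(rows$lo <= raw & raw <= rows$hi)
  if (length(hit) == 0) {
    res <- list(instrument = rows$instrument[[1]], raw = raw,
                category = NA_character_, indication = "unmapped",
                caution = any(rows$caution))
  } else {
    r <- rows[hit[[1]], , drop = FALSE]
    res <- list(instrument = r$instrument, raw = raw, category = r$label,
                indication = r$indication, caution = r$caution)
  }
  structure(res, class = "ccfo_interpreted_score")
}

#' @export
print.ccfo_interpreted_score <- function(x, ...) {
  cat(sprintf("<%s %s> %s (%s)%s\n", x$instrument, format(x$raw),
              ifelse(is.na(x$category), "unmapped score", x$category),
              x$indication,
              ifelse(isTRUE(x$caution), " [interpret with caution]", "")))
  invisible(x)
}

#' Find instrument score mentions in text
#'
#' Recognizes instrument names and aliases followed by a numeric value inside
#' that instrument's scale bounds (e.g. "Braden scale: 14", "FIM 7 today").
#' Out-of-bounds numbers are not reported as mentions.
#'
#' @param text a string.
#' @param criteria criteria table.
#' @return data.frame with columns `instrument`, `raw`, `alias`, `start`.
#' @export
parse_instrument_mention <- function(text, criteria = instrument_criteria()) {
  out <- data.frame(instrument = character(), raw = numeric(),
                    alias = character(), start = integer(),
                    stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(out)
  alias_tab <- unique(do.call(rbind, lapply(
    unique(criteria$instrument), function(ins) {
      rows <- criteria[criteria$instrument == ins, , drop = FALSE]
      aliases <- unique(c(ins, trimws(strsplit(rows$aliases[[1]], ";",
                                               fixed = TRUE)[[1]])))
      data.frame(instrument = ins, alias = aliases, stringsAsFactors = FALSE)
    })))
  # longest alias first so "Morse fall scale" beats "Morse"
  alias_tab <- alias_tab[order(-nchar(alias_tab$alias)), , drop = FALSE]
  taken <- rep(FALSE, nchar(text))
  for (i in seq_len(nrow(alias_tab))) {
    alias <- alias_tab$alias[i]
    pattern <- paste0("(?i)\\b", gsub("([][(){}.*+?^$\\\\|])", "\\\\\\1", alias),
                      "\\b[[:space:]:=-]{0,3}(?:score of |score |total )?",
                      "([0-9]+(?:\\.[0-9]+)?)")
    m <- gregexpr(pattern, text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    cap_starts <- attr(m, "capture.start")[, 1]
    cap_lens <- attr(m, "capture.length")[, 1]
    for (j in seq_along(starts)) {
      span <- starts[j]:(starts[j] + lens[j] - 1)
      if (any(taken[span])) next
      raw <- as.numeric(substring(text, cap_starts[j],
                                  cap_starts[j] + cap_lens[j] - 1))
      md <- scale_metadata(alias_tab$instrument[i], criteria)
      if (raw < md$min || raw > md$max) next
      taken[span] <- TRUE
      out <- rbind(out, data.frame(instrument = alias_tab$instrument[i],
                                   raw = raw, alias = alias,
                                   start = starts[j] - 1L,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$start), , drop = FALSE]
}

#' Rockwood band for an interpreted instrument score
#'
#' Instrument categories relate to the 9-level Rockwood clinical frailty scale
#' by band: the least-frail category maps to the 1-3 band, intermediate
#' categories to 4-6, and the most-frail category to 7-9. Exact within-band
#' placement is not claimed.
#'
#' @param interpreted a `ccfo_interpreted_score` from [interpret_score()].
#' @return `"low"`, `"middle"`, `"high"`, or `NA` for unmapped categories,
#'   with attribute `rockwood_range` giving the band's bounds.
#' @export
map_to_rockwood <- function(interpreted) {
  stopifnot(inherits(interpreted, "ccfo_interpreted_score"))
  band <- switch(interpreted$indication,
                 `not-frail-indicative` = "low",
                 intermediate = "middle",
                 `frail-indicative` = "high",
                 NA_character_)
  if (!is.na(band)) {
    attr(band, "rockwood_range") <- switch(band, low = c(1, 3),
                                           middle = c(4, 6), high = c(7, 9))
  }
  band
}
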