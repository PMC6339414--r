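#' Rockwood frailty score for a concept-qualifier pairing
#'
#' Looks up the published concept-level Rockwood rating (1 = very fit to 9 =
#' terminally ill, averaged across raters, kept fractional). Concepts with a
#' single severity level match any qualifier through their "only-level"
#' record. Pairings without a published rating return `"unscored"` rather
#' than an error or an interpolation.
#'
#' @param ont a validated `ccfo_ontology`.
#' @param concept_id CCFOID.
#' @param qualifier qualifier level (or `"only-level"` / `"unqualified"`).
#' @return numeric Rockwood score, or the string `"unscored"`.
#' @export
rockwood_for <- function(ont, concept_id, qualifier = "only-level") {
  concept_id <- as.character(concept_id)
  if (!concept_id %in% ont$concepts$ccfo_id) {
    stop("unknown ccfo_id: ", concept_id)
  }
  rows <- ont$scores[ont$scores$ccfo_id == concept_id, , drop = FALSE]
  if (nrow(rows) == 0) return("unscored")
  hit <- rows[rows$level == qualifier, , drop = FALSE]
  if (nrow(hit) == 0 && all(rows$level == "only-level")) {
    hit <- rows   # single-level concept: any qualifier hits the only level
  }
  if (nrow(hit) == 0 || is.na(hit$rockwood[[1]])) return("unscored")
  hit$rockwood[[1]]
}

#' Cardiac-relevance profile of a concept
#'
#' Returns the concept's rated likelihood that a cardiac intervention fixes
#' the problem (`will_fix`), its rated relevance to cardiac decision-making
#' (`relevance`) -- both low/medium/high, with rater ties kept verbatim as tie
#' codes -- and a derived `cardiac_specific` flag, true iff both ratings are
#' high.
#'
#' @param ont a validated `ccfo_ontology`.
#' @param concept_id CCFOID.
#' @return list with `will_fix`, `relevance`, `cardiac_specific`; or the
#'   string `"unscored"` for concepts without a score record.
#' @export
concept_relevance <- function(ont, concept_id) {
  concept_id <- as.character(concept_id)
  if (!concept_id %in% ont$concepts$ccfo_id) {
    stop("unknown ccfo_id: ", concept_id)
  }
  rows <- ont$scores[ont$scores$ccfo_id == concept_id, , drop = FALSE]
  if (nrow(rows) == 0) return("unscored")
  wf <- rows$will_fix[[1]]
  rel <- rows$relevance[[1]]
  list(will_fix = wf, relevance = rel,
       cardiac_specific = isTRUE(!is.na(wf) & !is.na(rel) &
                                   wf == "H" & rel == "H"))
}

#' Aggregate findings into a patient-level frailty profile
#'
#' Groups asserted findings by ontology subtree (professional-services,
#' physical examination, activity/exercise, mobility, activities of daily
#' living, eating/feeding/drinking, social history) and takes the maximum
#' Rockwood score within each group; groups without scored findings report no
#' evidence. The per-group maxima and their overall maximum form the feature
#' row used downstream of the extraction pipeline.
#'
#' @param fnd findings data.frame.
#' @param ont a validated `ccfo_ontology` with a group map.
#' @return list of class `ccfo_frailty_profile`: `groups` (data.frame with
#'   `group`, `max_rockwood`, `n_findings`), `overall` (max over groups with
#'   evidence, or `NA`).
#' @export
aggregate_profile <- function(fnd, ont) {
  groups <- unique(as.character(ont$group_map$group))
  tab <- data.frame(group = groups, max_rockwood = NA_real_,
                    n_findings = 0L, stringsAsFactors = FALSE)
  if (!is.null(fnd) && nrow(fnd) > 0) {
    fnd <- fnd[fnd$assertion == "asserted", , drop = FALSE]
    for (i in seq_len(nrow(fnd))) {
      g <- group_of(ont, fnd$concept_id[i])
      if (is.na(g)) next
      r <- rockwood_for(ont, fnd$concept_id[i], fnd$qualifier[i])
      if (identical(r, "unscored")) next
      j <- match(g, tab$group)
      tab$n_findings[j] <- tab$n_findings[j] + 1L
      tab$max_rockwood[j] <- max(tab$max_rockwood[j], r, na.rm = TRUE)
    }
  }
  overall <- if (all(is.na(tab$max_rockwood))) NA_real_ else
    max(tab$max_rockwood, na.rm = TRUE)
  structure(list(groups = tab, overall = overall),
            class = "ccfo_frailty_profile")
}

#' @export
print.ccfo_frailty_profile <- function(x, ...) {
  cat("<frailty profile> per-group maximum Rockwood score:\n")
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  %-40s %s (n=%d)\n", x$groups$group[i],
                ifelse(is.na(x$groups$max_rockwood[i]), "no evidence",
                       format(x$groups$max_rockwood[i])),
                x$groups$n_findings[i]))
  }
  cat(sprintf("  overall: %s\n",
              ifelse(is.na(x$overall), "no evidence", format(x$overall))))
  invisible(x)
}

#' Write frailty profiles as CSV feature rows
#'
#' @param profiles named list of `ccfo_frailty_profile` (names are doc ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(names(profiles), function(id) {
    g <- profiles[[id]]$groups
    data.frame(doc_id = id, group = g$group, max_rockwood = g$max_rockwood,
               n_findings = g$n_findings, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}
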