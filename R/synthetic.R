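# Rendering cues used by the note templates. These stay inside the
# extractor's cue lexicon so template notes are exactly recoverable.
RENDER_CUES <- c(able = "can", `with-difficulty` = "needs help with",
                 unable = "cannot", `high-frequency` = "often",
                 `mid-frequency` = "occasionally", absent = "denies")
RENDER_COURSE <- c(chronic = "chronic", `short-duration` = "transient",
                   `sudden-onset` = "acute")

# Distractor sentences built around excluded ambiguous surfaces: they contain
# no lexicon term, so they must contribute zero findings.
DISTRACTORS <- c("dressing changed daily",
                 "pt resting supine in bed",
                 "pt working with staff on discharge goals",
                 "eating arrangements reviewed with family")

#' Specification for one synthetic note
#'
#' Either an explicit list of planned findings or a sampling profile:
#' `independent` renders the full high-functioning activities-of-daily-living
#' evidence set (all Katz items satisfied), `frail` samples from a pool of
#' dependency findings, `mixed` samples any renderable document-expected
#' concept.
#'
#' @param profile `"independent"`, `"frail"` or `"mixed"`.
#' @param planned optional data.frame (`concept_id`, `qualifier`, `course`,
#'   `assertion`) of findings to render verbatim, overriding the profile.
#' @param n_findings number of findings sampled for `frail` / `mixed` notes.
#' @param negation_rate probability that a renderable finding is negated.
#' @param distractor_rate probability of appending a distractor sentence
#'   containing an excluded ambiguous term.
#' @param seed integer seed fixing all sampling for this note.
#' @return list of class `ccfo_note_spec`.
#' @export
note_spec <- function(profile = c("mixed", "independent", "frail"),
                      planned = NULL, n_findings = 2, negation_rate = 0.1,
                      distractor_rate = 0.2, seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(negation_rate >= 0, negation_rate <= 1,
            distractor_rate >= 0, distractor_rate <= 1, n_findings >= 0)
  structure(list(profile = profile, planned = planned,
                 n_findings = n_findings, negation_rate = negation_rate,
                 distractor_rate = distractor_rate, seed = as.integer(seed)),
            class = "ccfo_note_spec")
}

# Qualifier levels renderable for a concept: intrinsic levels carried by its
# terms, plus (when a cue-free term exists) every level of its axis.
renderable_levels <- function(ont, concept_id, config) {
  axis <- concept_axis(ont, concept_id)
  surfaces <- ont$terms$surface[ont$terms$ccfo_id == concept_id]
  surfaces <- setdiff(surfaces, ont$excluded_terms)
  if (length(surfaces) == 0) return(NULL)
  if (axis == "only-level") {
    neutral <- surfaces[is.na(vapply(surfaces, function(s)
      intrinsic_level(split_tokens(s), config$ability_cues), ""))]
    return(list(axis = axis, levels = "only-level", neutral = neutral,
                by_level = list()))
  }
  cue_sets <- if (axis == "ability-interpretation") config$ability_cues else
    config$frequency_cues
  intr <- vapply(surfaces, function(s)
    intrinsic_level(split_tokens(s), cue_sets), "")
  neutral <- surfaces[is.na(intr)]
  by_level <- split(surfaces[!is.na(intr)], intr[!is.na(intr)])
  axis_levels <- if (axis == "ability-interpretation") {
    c(ABILITY_LEVELS, "unqualified")
  } else {
    c(FREQUENCY_LEVELS, "unqualified")
  }
  levels <- union(names(by_level),
                  if (length(neutral) > 0) axis_levels else character())
  list(axis = axis, levels = levels, neutral = neutral, by_level = by_level)
}

render_sentence <- function(ont, concept_id, qualifier, course, assertion,
                            config) {
  rl <- renderable_levels(ont, concept_id, config)
  if (is.null(rl)) {
    stop("concept ", concept_id, " has no lexicon terms; cannot render")
  }
  cue <- ""
  if (rl$axis == "only-level") {
    term <- rl$neutral[[1]]
    if (assertion == "negated") cue <- "not"
  } else if (qualifier %in% names(rl$by_level)) {
    term <- rl$by_level[[qualifier]][[1]]   # intrinsic cue inside the term
  } else {
    if (length(rl$neutral) == 0 || !qualifier %in% rl$levels) {
      stop("concept ", concept_id, " cannot be rendered with qualifier ",
           qualifier)
    }
    term <- rl$neutral[[1]]
    if (assertion == "negated") {
      cue <- if (rl$axis == "frequency") "denies" else "not"
    } else if (qualifier != "unqualified") {
      cue <- RENDER_CUES[[qualifier]]
    }
  }
  words <- c("pt", if (nzchar(cue)) cue, term)
  sentence <- paste(words, collapse = " ")
  term_start <- nchar(sentence) - nchar(term)
  if (!is.na(course)) {
    sentence <- paste0(sentence, " , ", RENDER_COURSE[[course]])
  }
  sentence <- paste0(sentence, " .")
  list(sentence = sentence, term = term, term_start = term_start)
}

#' Generate one synthetic note with gold annotations
#'
#' Renders each planned finding as a template sentence built from a lexicon
#' term plus qualifier / course / negation cues consistent with the concept's
#' axis, and records the gold finding (concept, qualifier, course, assertion,
#' character span) that a correct extractor must recover. Reproducible under
#' a fixed spec seed.
#'
#' @param spec a [note_spec()].
#' @param ont a validated `ccfo_ontology`.
#' @param config cue configuration, see [extraction_config()].
#' @return list of class `ccfo_gold_note`: `text`, `gold` (findings
#'   data.frame), `spec`.
#' @export
generate_note <- function(spec, ont, config = extraction_config()) {
  stopifnot(inherits(spec, "ccfo_note_spec"))
  with_seed(spec$seed, generate_note_impl(spec, ont, config))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

independent_plan <- function() {
  data.frame(
    concept_id = c("112441", "112442", "112444", "112445", "1122",
                   "112721", "112722"),
    qualifier = c("able", "able", "able", "able", "able",
                  "unqualified", "unqualified"),
    course = NA_character_, assertion = "asserted", stringsAsFactors = FALSE)
}

frail_pool <- function() {
  data.frame(
    concept_id = c("1121221", "1121223", "112442", "112441", "132222",
                   "11214", "11213", "112711", "112712", "134"),
    qualifier = c("only-level", "only-level", "unable", "unable",
                  "high-frequency", "unable", "unable", "unqualified",
                  "unqualified", "unqualified"),
    course = NA_character_, assertion = "asserted", stringsAsFactors = FALSE)
}

plan_findings <- function(spec, ont, config) {
  if (!is.null(spec$planned)) {
    plan <- spec$planned
    plan$course <- if ("course" %in% names(plan)) as.character(plan$course) else
      NA_character_
    if (!"assertion" %in% names(plan)) plan$assertion <- "asserted"
    return(plan)
  }
  if (spec$profile == "independent") return(independent_plan())
  if (spec$profile == "frail") {
    pool <- frail_pool()
    k <- min(spec$n_findings, nrow(pool))
    return(pool[sample.int(nrow(pool), k), , drop = FALSE])
  }
  # mixed: any renderable document-expected concept
  doc <- ont$concepts$ccfo_id[ont$concepts$role == "document-expected"]
  doc <- doc[doc %in% ont$terms$ccfo_id]
  k <- min(spec$n_findings, length(doc))
  ids <- sample(doc, k)
  rows <- lapply(ids, function(id) {
    rl <- renderable_levels(ont, id, config)
    level <- if (length(rl$levels) == 1) rl$levels else sample(rl$levels, 1)
    # the absent qualifier is rendered with a denial cue, so it is negated
    negated <- level == "absent"
    course <- NA_character_
    if (!negated && !level %in% names(rl$by_level) && length(rl$neutral) > 0) {
      # cue-free renderings can take negation and a course
      negated <- stats::runif(1) < spec$negation_rate
      if (stats::runif(1) < 0.25) course <- sample(COURSE_LEVELS, 1)
    }
    if (negated) {
      level <- if (rl$axis == "frequency") "absent" else
        if (rl$axis == "only-level") "only-level" else "unqualified"
    }
    data.frame(concept_id = id, qualifier = level, course = course,
               assertion = ifelse(negated, "negated", "asserted"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

generate_note_impl <- function(spec, ont, config) {
  plan <- plan_findings(spec, ont, config)
  plan <- plan[!duplicated(plan$concept_id), , drop = FALSE]
  sentences <- character()
  gold <- list()
  offset <- 0L
  lead <- "seen in clinic today ."
  sentences <- c(sentences, lead)
  offset <- offset + nchar(lead) + 1L
  for (i in seq_len(nrow(plan))) {
    r <- render_sentence(ont, plan$concept_id[i], plan$qualifier[i],
                         plan$course[i], plan$assertion[i], config)
    gold[[length(gold) + 1]] <- data.frame(
      concept_id = plan$concept_id[i], qualifier = plan$qualifier[i],
      course = plan$course[i], assertion = plan$assertion[i],
      start = offset + r$term_start,
      end = offset + r$term_start + nchar(r$term),
      surface = r$term, stringsAsFactors = FALSE)
    sentences <- c(sentences, r$sentence)
    offset <- offset + nchar(r$sentence) + 1L
  }
  if (stats::runif(1) < spec$distractor_rate) {
    sentences <- c(sentences, paste0(sample(DISTRACTORS, 1), " ."))
  }
  gold <- if (length(gold) > 0) do.call(rbind, gold) else
    data.frame(concept_id = character(), qualifier = character(),
               course = character(), assertion = character(),
               start = integer(), end = integer(), surface = character(),
               stringsAsFactors = FALSE)
  structure(list(text = paste(sentences, collapse = " "), gold = gold,
                 spec = spec),
            class = "ccfo_gold_note")
}

#' Generate a corpus of synthetic notes
#'
#' @param n number of notes.
#' @param ont a validated `ccfo_ontology`.
#' @param seed master seed; per-note seeds are derived from it, so the corpus
#'   is reproducible as a whole.
#' @param profile sampling profile for every note, see [note_spec()].
#' @param n_findings,negation_rate,distractor_rate per-note parameters.
#' @param config cue configuration.
#' @return list with `notes` (list of gold notes) and `gold_summary`
#'   (data.frame of gold finding counts per concept).
#' @export
generate_corpus <- function(n, ont, seed = 1L, profile = "mixed",
                            n_findings = 2, negation_rate = 0.1,
                            distractor_rate = 0.2,
                            config = extraction_config()) {
  stopifnot(n >= 0)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  notes <- lapply(seq_len(n), function(i) {
    generate_note(note_spec(profile = profile, n_findings = n_findings,
                            negation_rate = negation_rate,
                            distractor_rate = distractor_rate,
                            seed = seeds[i]),
                  ont, config)
  })
  gold_all <- do.call(rbind, c(lapply(notes, function(x) x$gold),
                               make.row.names = FALSE))
  summary <- if (!is.data.frame(gold_all) || nrow(gold_all) == 0) {
    data.frame(concept_id = character(), n = integer())
  } else {
    as.data.frame(table(concept_id = gold_all$concept_id),
                  responseName = "n", stringsAsFactors = FALSE)
  }
  list(notes = notes, gold_summary = summary)
}

#' Write a corpus to disk as text files plus gold JSONL
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory; notes are written as `note_<i>.txt` and gold
#'   annotations as `gold.jsonl`.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lines <- character()
  for (i in seq_along(corpus$notes)) {
    note <- corpus$notes[[i]]
    id <- sprintf("note_%04d", i)
    writeLines(note$text, file.path(dir, paste0(id, ".txt")), useBytes = TRUE)
    g <- note$gold
    if (nrow(g) > 0) {
      lines <- c(lines, vapply(seq_len(nrow(g)), function(j) {
        jsonlite::toJSON(c(list(doc_id = id), as.list(g[j, , drop = FALSE])),
                         auto_unbox = TRUE, na = "null")
      }, ""))
    }
  }
  writeLines(lines, file.path(dir, "gold.jsonl"), useBytes = TRUE)
  invisible(dir)
}
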