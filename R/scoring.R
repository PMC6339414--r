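#' Load a packaged instrument rule table
#'
#' Rules are shipped as TSV so they are inspectable and testable independently
#' of code. A rule row states: instrument item, question block, block weight
#' (number of instrument questions the block stands for), the points the block
#' is worth when the row's antecedent is satisfied, and an antecedent of one
#' or two clauses. A clause names a concept, a scope (`subtree`: the concept
#' or any descendant; `self`: the concept only; `cont-both` /
#' `incont-either`: the continence idioms), an allowed qualifier set
#' (pipe-separated levels, `unqualified`, or `any`), and an optional required
#' course. Rows of one block with equal points are alternatives (OR); two
#' clauses in one row are a conjunction (AND).
#'
#' @param instrument `"katz"`, `"barthel"` or `"sf36"`.
#' @return data.frame of rules.
#' @export
scoring_rules <- function(instrument = c("katz", "barthel", "sf36")) {
  instrument <- match.arg(instrument)
  if (!is.null(.rules_cache[[instrument]])) return(.rules_cache[[instrument]])
  df <- read.delim(ccfo_extdata(paste0(instrument, "_rules.tsv")),
                   sep = "\t", colClasses = "character", fill = TRUE,
                   quote = "", fileEncoding = "UTF-8")
  df$weight <- as.numeric(df$weight)
  df$points <- as.numeric(df$points)
  for (col in c("c1_course", "c2_concept", "c2_scope", "c2_qualifier")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]][!nzchar(trimws0(df[[col]]))] <- NA_character_
  }
  .rules_cache[[instrument]] <- df
  df
}

.rules_cache <- new.env(parent = emptyenv())

# Findings usable as scoring evidence: asserted findings, plus negated
# findings that carry the absent qualifier (a denied symptom is evidence of
# absence, which several published rules score).
eligible_findings <- function(fnd) {
  if (is.null(fnd)) {
    fnd <- data.frame(concept_id = character(), qualifier = character(),
                      course = character(), assertion = character(),
                      stringsAsFactors = FALSE)
  }
  if (nrow(fnd) == 0) {
    return(fnd[, c("concept_id", "qualifier", "course", "assertion")])
  }
  fnd <- unique(fnd[, c("concept_id", "qualifier", "course", "assertion")])
  fnd[fnd$assertion == "asserted" |
        (fnd$assertion == "negated" & fnd$qualifier == "absent"), ,
      drop = FALSE]
}

qualifier_matches <- function(finding_q, rule_q) {
  if (rule_q == "any") return(TRUE)
  finding_q %in% strsplit(rule_q, "|", fixed = TRUE)[[1]]
}

# Does any eligible finding satisfy a clause?
clause_satisfied <- function(fnd, ont, concept, scope, qualifier, course = NA) {
  if (nrow(fnd) == 0) return(FALSE)
  if (scope == "cont-both") return(continence_both(fnd, ont))
  if (scope == "incont-either") return(incontinence_either(fnd, ont))
  ids <- if (scope == "self") concept else descendant_ids(ont, concept)
  cand <- fnd[fnd$concept_id %in% ids, , drop = FALSE]
  if (nrow(cand) == 0) return(FALSE)
  ok <- vapply(cand$qualifier, qualifier_matches, logical(1), rule_q = qualifier)
  if (!is.na(course)) ok <- ok & !is.na(cand$course) & cand$course == course
  any(ok)
}

# "Continence ... of both kinds": for each kind (urinary, bowel) there is an
# unqualified/able continence finding or an absent-qualified incontinence
# finding of that kind.
continence_both <- function(fnd, ont) {
  kinds <- list(c(cont = "112721", incont = "112711"),
                c(cont = "112722", incont = "112712"))
  all(vapply(kinds, function(k) {
    any(fnd$concept_id == k[["cont"]] &
          fnd$qualifier %in% c("unqualified", "able", "high-frequency")) ||
      any(fnd$concept_id == k[["incont"]] & fnd$qualifier == "absent")
  }, logical(1)))
}

# "Incontinence finding of either kind" (unqualified).
incontinence_either <- function(fnd, ont) {
  ids <- descendant_ids(ont, "11271")
  any(fnd$concept_id %in% ids &
        fnd$qualifier %in% c("unqualified", "high-frequency", "only-level"))
}

# Evaluate one instrument's rule table against a finding set. Block value is
# the minimum points over all satisfied rows of the block (conflicting
# evidence resolves to the worst, most dependent reading); a block with no
# satisfied row is uncovered.
evaluate_rules <- function(rules, fnd, ont) {
  fnd <- eligible_findings(fnd)
  sat <- vapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, , drop = FALSE]
    ok <- clause_satisfied(fnd, ont, r$c1_concept, r$c1_scope, r$c1_qualifier,
                           r$c1_course)
    if (ok && !is.na(r$c2_concept)) {
      ok <- clause_satisfied(fnd, ont, r$c2_concept, r$c2_scope, r$c2_qualifier)
    }
    ok
  }, logical(1))
  blocks <- unique(rules[, c("item", "block", "weight")])
  blocks$points <- vapply(seq_len(nrow(blocks)), function(i) {
    rows <- sat & rules$block == blocks$block[i]
    if (!any(rows)) NA_real_ else min(rules$points[rows])
  }, numeric(1))
  blocks$covered <- !is.na(blocks$points)
  blocks
}

new_instrument_result <- function(instrument, total, scale_min, scale_max,
                                  coverage, blocks, sections = NULL) {
  structure(list(instrument = instrument, total = total,
                 scale_min = scale_min, scale_max = scale_max,
                 coverage = coverage, blocks = blocks, sections = sections),
            class = "ccfo_instrument_result")
}

#' @export
print.ccfo_instrument_result <- function(x, ...) {
  cat(sprintf("<%s> ", x$instrument))
  if (!is.null(x$sections)) {
    cat("section scores (0-100, higher = better health):\n")
    for (nm in names(x$sections)) {
      cat(sprintf("  %-22s %s\n", nm,
                  ifelse(is.na(x$sections[[nm]]), "no evidence",
                         format(round(x$sections[[nm]], 1)))))
    }
  } else {
    cat(sprintf("total %s on scale [%s, %s]\n", format(x$total),
                format(x$scale_min), format(x$scale_max)))
  }
  cat(sprintf("  item coverage %.2f\n", x$coverage))
  invisible(x)
}

#' Katz ADL score from findings
#'
#' Counts satisfied activity items: one point per able-qualified personal-care
#' activity among bathing, dressing, toileting and feeding; one point for an
#' able-qualified transfer-location finding; one point when continence of both
#' kinds is evidenced (unqualified continence or absent-qualified
#' incontinence per kind). Unable-qualified and asserted-incontinence
#' evidence contributes zero. 6 = high functioning, 0 = low functioning.
#'
#' @param fnd findings data.frame ([finding()] or [extract_findings()]).
#' @param ont a validated `ccfo_ontology`.
#' @return a `ccfo_instrument_result` with `total` in \code{[0, 6]}.
#' @export
score_katz <- function(fnd, ont) {
  blocks <- evaluate_rules(scoring_rules("katz"), fnd, ont)
  total <- sum(blocks$points[blocks$covered])
  new_instrument_result("katz", total, 0, 6,
                        mean(blocks$covered), blocks)
}

#' Barthel index from findings
#'
#' Applies the published rule set: continence of both kinds (0 or 2),
#' per-child personal-care activities (0/1/2 each, unqualified counts as
#' able), transfer (0 or 2), the mobility ladder (independent mobilization or
#' walking without aid = 3, with difficulty or walking-aid use = 2,
#' wheelchair-bound = 1, unable or bed-ridden = 0) and stairs (0 or 2). The
#' total is the raw rule sum; the published scale bounds (0 and 20) are
#' reported as metadata without rescaling (the printed rules' maximum sum is
#' 19 under the both-kinds continence reading, 21 under the per-kind one).
#'
#' @inheritParams score_katz
#' @param continence_per_kind if `TRUE`, score continence as 2 points per
#'   evidenced kind instead of 2 points total for both kinds.
#' @return a `ccfo_instrument_result`.
#' @export
score_barthel <- function(fnd, ont, continence_per_kind = FALSE) {
  blocks <- evaluate_rules(scoring_rules("barthel"), fnd, ont)
  if (continence_per_kind) {
    el <- eligible_findings(fnd)
    kinds <- list(c(cont = "112721", incont = "112711"),
                  c(cont = "112722", incont = "112712"))
    n_ok <- sum(vapply(kinds, function(k) {
      any(el$concept_id == k[["cont"]] &
            el$qualifier %in% c("unqualified", "able", "high-frequency")) ||
        any(el$concept_id == k[["incont"]] & el$qualifier == "absent")
    }, logical(1)))
    idx <- blocks$block == "continence"
    incont <- incontinence_either(el, ont)
    blocks$points[idx] <- if (incont) 0 else if (n_ok > 0) 2 * n_ok else NA_real_
    blocks$covered[idx] <- !is.na(blocks$points[idx])
  }
  total <- sum(blocks$points[blocks$covered])
  new_instrument_result("barthel", total, 0, 20,
                        mean(blocks$covered), blocks)
}

#' SF-36 section scores from findings
#'
#' Maps findings onto the question blocks of the eight SF-36 sections
#' (general health, pain, physical functioning, role limitations due to
#' physical health, role limitations due to emotional problems, energy and
#' fatigue, emotional well-being, social functioning). Each covered block
#' contributes its points with a weight equal to the number of instrument
#' questions it stands for; a section score is the weighted average over its
#' covered blocks, on a 0-100 scale where higher means better health. Blocks
#' without evidence are excluded from the average and reduce coverage;
#' sections with no covered block are `NA` ("no evidence").
#'
#' @inheritParams score_katz
#' @return a `ccfo_instrument_result` whose `sections` is a named numeric
#'   vector of the eight section scores.
#' @export
score_sf36 <- function(fnd, ont) {
  blocks <- evaluate_rules(scoring_rules("sf36"), fnd, ont)
  sections <- vapply(unique(blocks$item), function(sec) {
    b <- blocks[blocks$item == sec & blocks$covered, , drop = FALSE]
    if (nrow(b) == 0) return(NA_real_)
    sum(b$points) / sum(b$weight)
  }, numeric(1))
  names(sections) <- unique(blocks$item)
  new_instrument_result("sf36", NA_real_, 0, 100, mean(blocks$covered),
                        blocks, sections = sections)
}
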