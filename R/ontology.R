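#' Construct an ontology object
#'
#' Assembles and checks a `ccfo_ontology` from its component tables. The
#' ontology is the package's central container: a concept hierarchy (CCFOID,
#' optional SNOMED-CT id, name, parent, role), an indicator-term lexicon
#' (surface strings that suggest an author was thinking of a concept -- not
#' synonyms), per concept-level Rockwood/will-fix/relevance score records, a
#' list of ambiguous surfaces excluded from matching, and a mapping from
#' subtree roots to frailty aggregation groups.
#'
#' @param concepts data.frame with columns `ccfo_id`, `sctid`, `name`,
#'   `parent_id`, `role`.
#' @param terms data.frame with columns `surface`, `ccfo_id`.
#' @param scores data.frame with columns `ccfo_id`, `level`, `rockwood`,
#'   `will_fix`, `relevance`.
#' @param excluded_terms character vector of surfaces never matched.
#' @param group_map data.frame with columns `root_id`, `group`.
#' @param validate if `TRUE` (default) stop on any integrity violation.
#' @return An object of class `ccfo_ontology`.
#' @seealso [load_ontology()], [validate_ontology()]
#' @export
new_ontology <- function(concepts, terms, scores,
                         excluded_terms = character(),
                         group_map = data.frame(root_id = character(),
                                                group = character()),
                         validate = TRUE) {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  for (col in c("ccfo_id", "sctid", "name", "parent_id", "role")) {
    if (!col %in% names(concepts)) stop("concepts is missing column '", col, "'")
    concepts[[col]] <- as.character(concepts[[col]])
  }
  concepts$sctid[!nzchar(trimws0(concepts$sctid))] <- NA_character_
  concepts$parent_id[!nzchar(trimws0(concepts$parent_id))] <- NA_character_
  terms$surface <- tolower(trimws(as.character(terms$surface)))
  terms$ccfo_id <- as.character(terms$ccfo_id)
  scores$ccfo_id <- as.character(scores$ccfo_id)
  scores$level <- as.character(scores$level)
  scores$rockwood <- suppressWarnings(as.numeric(scores$rockwood))
  for (col in c("will_fix", "relevance")) {
    v <- if (col %in% names(scores)) as.character(scores[[col]]) else NA_character_
    v[!nzchar(trimws0(v))] <- NA_character_
    scores[[col]] <- v
  }
  ont <- structure(
    list(concepts = concepts, terms = terms, scores = scores,
         excluded_terms = tolower(trimws(excluded_terms)),
         group_map = as.data.frame(group_map, stringsAsFactors = FALSE)),
    class = "ccfo_ontology")
  if (validate) {
    report <- validate_ontology(ont)
    if (nrow(report) > 0) {
      stop("ontology integrity error:\n",
           paste(sprintf("  [%s] %s: %s", report$rule, report$id, report$message),
                 collapse = "\n"))
    }
  }
  ont
}

trimws0 <- function(x) {
  x[is.na(x)] <- ""
  trimws(x)
}

#' @export
print.ccfo_ontology <- function(x, ...) {
  sc <- summary_counts(x)
  cat(sprintf(paste0("<ccfo_ontology> %d concepts (%d document-expected, ",
                     "%d qualifier values), %d terms, %d score records\n"),
              sc$n_concepts, sc$n_document_expected, sc$n_qualifier_values,
              sc$n_terms, nrow(x$scores)))
  invisible(x)
}

#' Validate ontology integrity
#'
#' Checks every structural invariant of the ontology and returns violations
#' as data, not exceptions: unique CCFOIDs, existing parents, an acyclic
#' hierarchy, qualifier-value concepts under the qualifier-values root,
#' referential integrity of terms and scores, term surfaces that collide with
#' the excluded-ambiguous list, Rockwood scores inside [1, 9], and Rockwood
#' monotonicity over able / with-difficulty / unable levels.
#'
#' @param ont a `ccfo_ontology` (built with `validate = FALSE` if it may be
#'   broken).
#' @return data.frame with columns `rule`, `id`, `message`; zero rows iff the
#'   ontology is valid.
#' @export
validate_ontology <- function(ont) {
  viol <- list()
  add <- function(rule, id, message) {
    viol[[length(viol) + 1]] <<- data.frame(rule = rule, id = as.character(id),
                                            message = message,
                                            stringsAsFactors = FALSE)
  }
  cc <- ont$concepts
  if (nrow(cc) == 0) {
    add("no-root", NA, "ontology has no concepts (no root)")
    return(do.call(rbind, viol))
  }
  dup <- unique(cc$ccfo_id[duplicated(cc$ccfo_id)])
  for (d in dup) add("duplicate-id", d, "ccfo_id occurs more than once")
  bad_role <- cc$ccfo_id[!cc$role %in% CONCEPT_ROLES]
  for (b in bad_role) add("unknown-role", b, "role not one of the permitted roles")
  known <- cc$ccfo_id
  dangling <- cc$ccfo_id[!is.na(cc$parent_id) & !cc$parent_id %in% known]
  for (d in dangling) add("dangling-parent", d, "parent_id does not exist")
  if (!any(is.na(cc$parent_id))) add("no-root", NA, "no concept without a parent")

  # cycle detection by iterative parent-chasing
  parent <- setNames(cc$parent_id, cc$ccfo_id)
  for (id in cc$ccfo_id) {
    seen <- character()
    cur <- id
    while (!is.na(cur) && cur %in% names(parent)) {
      if (cur %in% seen) {
        add("cycle", id, "parent chain contains a cycle")
        break
      }
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }

  # qualifier values must descend from the qualifier-values root
  qroot <- cc$ccfo_id[is.na(cc$parent_id) & grepl("qualifier", cc$name)]
  for (id in cc$ccfo_id[cc$role == "qualifier-value"]) {
    anc <- ancestor_ids(ont, id)
    if (length(qroot) == 0 || !any(anc %in% qroot)) {
      add("qualifier-placement", id,
          "qualifier-value concept does not descend from the qualifier-values root")
    }
  }

  tt <- ont$terms
  if (nrow(tt) > 0) {
    empty <- which(!nzchar(tt$surface))
    for (e in empty) add("empty-surface", tt$ccfo_id[e], "term surface is empty")
    for (id in unique(tt$ccfo_id[!tt$ccfo_id %in% known])) {
      add("dangling-term", id, "term references unknown ccfo_id")
    }
    dup <- unique(tt$surface[duplicated(tt$surface)])
    for (d in dup) add("ambiguous-term", d, "surface maps to more than one concept")
    confl <- intersect(tt$surface, ont$excluded_terms)
    for (s in confl) {
      add("excluded-term-conflict", s,
          "surface is both a lexicon term and an excluded ambiguous term")
    }
  }

  ss <- ont$scores
  if (nrow(ss) > 0) {
    for (id in unique(ss$ccfo_id[!ss$ccfo_id %in% known])) {
      add("dangling-score", id, "score record references unknown ccfo_id")
    }
    bad <- ss$ccfo_id[!is.na(ss$rockwood) & (ss$rockwood < 1 | ss$rockwood > 9)]
    for (b in unique(bad)) add("rockwood-range", b, "rockwood outside [1, 9]")
    # monotone: able <= with-difficulty <= unable
    for (id in unique(ss$ccfo_id)) {
      rows <- ss[ss$ccfo_id == id & ss$level %in% ABILITY_LEVELS &
                   !is.na(ss$rockwood), , drop = FALSE]
      if (nrow(rows) >= 2) {
        r <- setNames(rows$rockwood, rows$level)
        lv <- c("able", "with-difficulty", "unable")
        present <- lv[lv %in% names(r)]
        if (is.unsorted(r[present])) {
          add("rockwood-monotonicity", id,
              "rockwood decreases from able towards unable")
        }
      }
    }
  }

  gm <- ont$group_map
  if (nrow(gm) > 0) {
    for (id in unique(as.character(gm$root_id)[!as.character(gm$root_id) %in% known])) {
      add("dangling-group-root", id, "group root references unknown ccfo_id")
    }
  }

  if (length(viol) == 0) {
    data.frame(rule = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, viol)
  }
}

ancestor_ids <- function(ont, ccfo_id) {
  parent <- setNames(ont$concepts$parent_id, ont$concepts$ccfo_id)
  out <- character()
  cur <- parent[[ccfo_id]]
  while (!is.na(cur)) {
    if (cur %in% out) break   # guard against cycles in unvalidated input
    out <- c(out, cur)
    cur <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
  }
  out
}

#' Look up the concept indicated by a term surface
#'
#' @param ont a validated `ccfo_ontology`.
#' @param surface a normalized (lowercase, trimmed) surface string.
#' @return one-row data.frame for the concept, or `NULL` when the surface is
#'   unknown, empty, or on the excluded-ambiguous list.
#' @export
concept_for_term <- function(ont, surface) {
  surface <- tolower(trimws(surface))
  if (!nzchar(surface) || surface %in% ont$excluded_terms) return(NULL)
  hit <- ont$terms$ccfo_id[ont$terms$surface == surface]
  if (length(hit) == 0) return(NULL)
  ont$concepts[ont$concepts$ccfo_id == hit[[1]], , drop = FALSE]
}

#' Ancestors of a concept, nearest parent first
#'
#' @param ont a `ccfo_ontology`.
#' @param ccfo_id concept identifier.
#' @return data.frame of ancestor concepts ordered parent to root; zero rows
#'   for a root.
#' @export
ancestors <- function(ont, ccfo_id) {
  ccfo_id <- as.character(ccfo_id)
  if (!ccfo_id %in% ont$concepts$ccfo_id) {
    stop("unknown ccfo_id: ", ccfo_id)
  }
  ids <- ancestor_ids(ont, ccfo_id)
  ont$concepts[match(ids, ont$concepts$ccfo_id), , drop = FALSE]
}

#' Concept ids in a subtree (root included)
#'
#' @param ont a `ccfo_ontology`.
#' @param ccfo_id subtree root.
#' @return character vector of ccfo_ids.
#' @export
descendant_ids <- function(ont, ccfo_id) {
  ccfo_id <- as.character(ccfo_id)
  out <- ccfo_id
  frontier <- ccfo_id
  cc <- ont$concepts
  while (length(frontier) > 0) {
    kids <- cc$ccfo_id[!is.na(cc$parent_id) & cc$parent_id %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Summary counts of an ontology
#'
#' @param ont a validated `ccfo_ontology`.
#' @return list with `n_concepts`, `n_terms`, `n_document_expected`,
#'   `n_qualifier_values`, and `terms_per_concept_histogram` (a table over
#'   document-expected concepts, named by term count).
#' @export
summary_counts <- function(ont) {
  cc <- ont$concepts
  doc <- cc$ccfo_id[cc$role == "document-expected"]
  per_concept <- table(factor(ont$terms$ccfo_id, levels = doc))
  hist <- table(as.integer(per_concept))
  list(n_concepts = nrow(cc),
       n_terms = nrow(ont$terms),
       n_document_expected = length(doc),
       n_qualifier_values = sum(cc$role == "qualifier-value"),
       terms_per_concept_histogram = hist)
}

#' Qualifier axis of a concept
#'
#' Document-expected concepts take qualifiers from one axis: ability concepts
#' (names starting "able"/"ability") take able / with-difficulty / unable;
#' concepts whose printed frailty score has a single "only-level" row are
#' unqualified status findings; everything else (activities, mental states,
#' symptoms) takes frequency qualifiers (high / mid / absent). Any finding may
#' additionally carry a course.
#'
#' @param ont a `ccfo_ontology`.
#' @param ccfo_id concept identifier.
#' @return one of `"ability-interpretation"`, `"frequency"`, `"only-level"`.
#' @export
concept_axis <- function(ont, ccfo_id) {
  ccfo_id <- as.character(ccfo_id)
  sr <- ont$scores[ont$scores$ccfo_id == ccfo_id, , drop = FALSE]
  nm <- ont$concepts$name[ont$concepts$ccfo_id == ccfo_id]
  if (length(nm) == 0) stop("unknown ccfo_id: ", ccfo_id)
  if (grepl("^(able|ability)", nm)) return("ability-interpretation")
  # a status concept has actual Rockwood ratings on levels outside the
  # ability/frequency scales (bed-ridden, wheelchair bound, paralysis);
  # relevance-only records (no Rockwood) do not make a concept single-level
  off_axis <- !sr$level %in% c(ABILITY_LEVELS, FREQUENCY_LEVELS)
  if (any(off_axis & !is.na(sr$rockwood))) return("only-level")
  "frequency"
}

#' Polarity of a document-expected concept
#'
#' Whether the concept describes a capacity / positive state (more frequent or
#' more able is better: fit and well, calm, enjoys exercise ...) or a deficit
#' (more frequent is worse: pain, lack of energy, incontinence ...). Used by
#' the synthetic-note generator and monotonicity checks to order qualifier
#' levels from worst to best.
#'
#' @param ont a `ccfo_ontology`.
#' @param ccfo_id concept identifier.
#' @return `"positive"` or `"deficit"`.
#' @export
concept_polarity <- function(ont, ccfo_id) {
  ccfo_id <- as.character(ccfo_id)
  nm <- ont$concepts$name[ont$concepts$ccfo_id == ccfo_id]
  if (length(nm) == 0) stop("unknown ccfo_id: ", ccfo_id)
  positive <- c("fit and well", "calm", "happy", "enjoys", "continence",
                "good", "sustain", "no aid", "steady", "well-being")
  if (concept_axis(ont, ccfo_id) == "ability-interpretation" ||
      any(vapply(positive, grepl, logical(1), x = nm, fixed = TRUE))) {
    "positive"
  } else {
    "deficit"
  }
}

#' Aggregation group of a concept
#'
#' @param ont a `ccfo_ontology` with a group map.
#' @param ccfo_id concept identifier.
#' @return the group name, or `NA_character_` if the concept lies in no
#'   mapped subtree. When subtrees nest, the nearest (deepest) root wins.
#' @export
group_of <- function(ont, ccfo_id) {
  ccfo_id <- as.character(ccfo_id)
  gm <- ont$group_map
  if (nrow(gm) == 0) return(NA_character_)
  chain <- c(ccfo_id, ancestor_ids(ont, ccfo_id))
  hit <- match(chain, as.character(gm$root_id))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) NA_character_ else as.character(gm$group[hit[[1]]])
}
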