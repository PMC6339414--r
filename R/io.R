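#' Load an ontology from disk
#'
#' The fixture of record is plain tabular UTF-8 TSV: a directory holding
#' `concepts.tsv` (ccfo_id, sctid, name, parent_id, role), `terms.tsv`
#' (surface, ccfo_id), `scores.tsv` (ccfo_id, level, rockwood, will_fix,
#' relevance) and optionally `excluded_terms.txt` and `groups.tsv`. OWL
#' (RDF/XML, as published on BioPortal) is an import/export dialect around the
#' same model.
#'
#' @param fixture_path directory (tabular) or file (owl) to read.
#' @param format one of `"tabular"`, `"owl"`, `"xlsx-supplement"`.
#' @param validate stop on integrity violations (default `TRUE`).
#' @return a `ccfo_ontology`.
#' @export
load_ontology <- function(fixture_path, format = c("tabular", "owl",
                                                   "xlsx-supplement"),
                          validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(fixture_path)) stop("no such file or directory: ", fixture_path)
  switch(format,
    tabular = load_ontology_tabular(fixture_path, validate = validate),
    owl = load_ontology_owl(fixture_path, validate = validate),
    `xlsx-supplement` = stop(
      "no XLSX reader is available; export the supplement sheets to TSV ",
      "(concepts.tsv, terms.tsv, scores.tsv) and load with format = 'tabular'"))
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("missing fixture table: ", path)
  df <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, quote = "",
               colClasses = "character", fill = TRUE, fileEncoding = "UTF-8",
               check.names = TRUE, blank.lines.skip = TRUE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("parse error in ", path, " (header line 1): missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df
}

load_ontology_tabular <- function(dir, validate = TRUE) {
  if (!dir.exists(dir)) {
    stop("tabular fixtures are a directory of TSV files; got a file: ", dir)
  }
  concepts <- read_tsv_checked(file.path(dir, "concepts.tsv"),
                               c("ccfo_id", "sctid", "name", "parent_id", "role"))
  if (nrow(concepts) == 0) stop("ontology integrity error: empty fixture (no root)")
  terms <- read_tsv_checked(file.path(dir, "terms.tsv"), c("surface", "ccfo_id"))
  scores <- read_tsv_checked(file.path(dir, "scores.tsv"),
                             c("ccfo_id", "level", "rockwood"))
  excl_path <- file.path(dir, "excluded_terms.txt")
  excluded <- if (file.exists(excl_path)) {
    readLines(excl_path, encoding = "UTF-8", warn = FALSE)
  } else character()
  excluded <- excluded[nzchar(trimws(excluded))]
  gm_path <- file.path(dir, "groups.tsv")
  group_map <- if (file.exists(gm_path)) {
    read_tsv_checked(gm_path, c("root_id", "group"))
  } else data.frame(root_id = character(), group = character())
  new_ontology(concepts, terms, scores, excluded, group_map, validate = validate)
}

#' The packaged core ontology fixture
#'
#' Loads the partial CCFO fixture that ships with the package: every concept,
#' SNOMED-CT id, indicator term, and score record documented in the published
#' ontology description itself (hierarchy top layers, central-concept term
#' lists, the nine scored concepts, instrument-rule concepts), with the
#' published excluded-ambiguous terms and the seven frailty aggregation
#' groups.
#'
#' @return a validated `ccfo_ontology`.
#' @export
ccfo_core_ontology <- function() {
  load_ontology(ccfo_extdata(), format = "tabular")
}

#' Export an ontology to disk
#'
#' Export followed by [load_ontology()] reproduces an ontology with identical
#' concept, term, and score sets (round-trip identity).
#'
#' @param ont a validated `ccfo_ontology`.
#' @param path output directory (tabular) or file (owl).
#' @param format `"tabular"` or `"owl"`.
#' @return `path`, invisibly.
#' @export
export_ontology <- function(ont, path, format = c("tabular", "owl")) {
  format <- match.arg(format)
  if (nrow(ont$concepts) == 0) {
    stop("ontology integrity error: refusing to export an empty ontology")
  }
  if (format == "tabular") export_ontology_tabular(ont, path)
  else export_ontology_owl(ont, path)
  invisible(path)
}

export_ontology_tabular <- function(ont, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, file) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  wt(ont$concepts, "concepts.tsv")
  wt(ont$terms, "terms.tsv")
  wt(ont$scores, "scores.tsv")
  writeLines(ont$excluded_terms, file.path(dir, "excluded_terms.txt"),
             useBytes = TRUE)
  wt(ont$group_map, "groups.tsv")
}

CCFO_NS <- "http://purl.bioontology.org/ontology/CCFO#"

owl_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

export_ontology_owl <- function(ont, file) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#"',
    sprintf('         xmlns:ccfo="%s">', CCFO_NS),
    sprintf('  <owl:Ontology rdf:about="%sontology">', CCFO_NS))
  for (s in ont$excluded_terms) {
    lines <- c(lines, sprintf('    <ccfo:excludedTerm>%s</ccfo:excludedTerm>',
                              owl_escape(s)))
  }
  gm <- ont$group_map
  if (nrow(gm) > 0) {
    for (i in seq_len(nrow(gm))) {
      lines <- c(lines, sprintf('    <ccfo:group>%s|%s</ccfo:group>',
                                owl_escape(as.character(gm$root_id[i])),
                                owl_escape(as.character(gm$group[i]))))
    }
  }
  lines <- c(lines, '  </owl:Ontology>')
  cc <- ont$concepts
  for (i in seq_len(nrow(cc))) {
    id <- cc$ccfo_id[i]
    lines <- c(lines, sprintf('  <owl:Class rdf:about="%sCCFO_%s">', CCFO_NS, id),
               sprintf('    <rdfs:label>%s</rdfs:label>', owl_escape(cc$name[i])),
               sprintf('    <ccfo:role>%s</ccfo:role>', cc$role[i]))
    if (!is.na(cc$parent_id[i])) {
      lines <- c(lines, sprintf(
        '    <rdfs:subClassOf rdf:resource="%sCCFO_%s"/>', CCFO_NS, cc$parent_id[i]))
    }
    if (!is.na(cc$sctid[i])) {
      lines <- c(lines, sprintf('    <ccfo:sctid>%s</ccfo:sctid>', cc$sctid[i]))
    }
    for (s in ont$terms$surface[ont$terms$ccfo_id == id]) {
      lines <- c(lines, sprintf('    <ccfo:indicatorTerm>%s</ccfo:indicatorTerm>',
                                owl_escape(s)))
    }
    sr <- ont$scores[ont$scores$ccfo_id == id, , drop = FALSE]
    for (j in seq_len(nrow(sr))) {
      lines <- c(lines, sprintf(
        '    <ccfo:scoreRecord>%s|%s|%s|%s</ccfo:scoreRecord>',
        owl_escape(sr$level[j]),
        ifelse(is.na(sr$rockwood[j]), "", format(sr$rockwood[j])),
        ifelse(is.na(sr$will_fix[j]), "", owl_escape(sr$will_fix[j])),
        ifelse(is.na(sr$relevance[j]), "", owl_escape(sr$relevance[j]))))
    }
    lines <- c(lines, '  </owl:Class>')
  }
  lines <- c(lines, '</rdf:RDF>')
  writeLines(lines, file, useBytes = TRUE)
}

load_ontology_owl <- function(file, validate = TRUE) {
  doc <- tryCatch(xml2::read_xml(file),
                  error = function(e) stop("parse error in ", file, ": ",
                                           conditionMessage(e)))
  ns <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#",
          owl = "http://www.w3.org/2002/07/owl#",
          ccfo = CCFO_NS)
  strip_iri <- function(x) sub(paste0("^", CCFO_NS, "CCFO_"), "", x)
  classes <- xml2::xml_find_all(doc, ".//owl:Class", ns)
  if (length(classes) == 0) stop("ontology integrity error: no classes (no root)")
  txt1 <- function(node, xp) {
    n <- xml2::xml_find_first(node, xp, ns)
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_text(n)
  }
  concepts <- terms <- scores <- list()
  for (cl in classes) {
    id <- strip_iri(xml2::xml_attr(cl, "about"))
    parent <- xml2::xml_find_first(cl, "./rdfs:subClassOf", ns)
    parent_id <- if (inherits(parent, "xml_missing")) NA_character_ else
      strip_iri(xml2::xml_attr(parent, "resource"))
    concepts[[length(concepts) + 1]] <- data.frame(
      ccfo_id = id, sctid = txt1(cl, "./ccfo:sctid"),
      name = txt1(cl, "./rdfs:label"), parent_id = parent_id,
      role = txt1(cl, "./ccfo:role"), stringsAsFactors = FALSE)
    for (s in xml2::xml_text(xml2::xml_find_all(cl, "./ccfo:indicatorTerm", ns))) {
      terms[[length(terms) + 1]] <- data.frame(surface = s, ccfo_id = id,
                                               stringsAsFactors = FALSE)
    }
    for (s in xml2::xml_text(xml2::xml_find_all(cl, "./ccfo:scoreRecord", ns))) {
      parts <- strsplit(s, "|", fixed = TRUE)[[1]]
      parts <- c(parts, rep("", 4 - length(parts)))
      scores[[length(scores) + 1]] <- data.frame(
        ccfo_id = id, level = parts[1], rockwood = parts[2],
        will_fix = parts[3], relevance = parts[4], stringsAsFactors = FALSE)
    }
  }
  bind0 <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  excluded <- xml2::xml_text(xml2::xml_find_all(
    doc, ".//owl:Ontology/ccfo:excludedTerm", ns))
  gm <- xml2::xml_text(xml2::xml_find_all(doc, ".//owl:Ontology/ccfo:group", ns))
  gm <- if (length(gm)) {
    parts <- strsplit(gm, "|", fixed = TRUE)
    data.frame(root_id = vapply(parts, `[`, "", 1),
               group = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
  } else data.frame(root_id = character(), group = character())
  new_ontology(
    bind0(concepts, data.frame(ccfo_id = character(), sctid = character(),
                               name = character(), parent_id = character(),
                               role = character())),
    bind0(terms, data.frame(surface = character(), ccfo_id = character())),
    bind0(scores, data.frame(ccfo_id = character(), level = character(),
                             rockwood = character(), will_fix = character(),
                             relevance = character())),
    excluded, gm, validate = validate)
}
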