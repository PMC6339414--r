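#' Synthetic reconstruction of the full CCFO fixture
#'
#' The packaged core fixture carries only the concepts, terms and scores that
#' are individually documented in the published ontology description. The full
#' ontology release (156 concepts) is distributed as a supplement that cannot
#' be redistributed here, so this builder produces a synthetic stand-in: it
#' starts from the core fixture and pads it, deterministically, with clearly
#' labelled synthetic concepts and terms until every published aggregate count
#' is reached -- 156 concepts, of which 86 are document-expected and 12 are
#' qualifier values, and a terms-per-concept distribution over the
#' document-expected concepts of 24/29/7/8/6/5/0/3/4 concepts carrying
#' 1/2/3/4/5/6/7/8/>8 terms (the four >8 concepts carry 12, 9, 9 and 9 terms;
#' the 12-term concept is lack of energy finding).
#'
#' Note the published aggregate term total (246) is arithmetically
#' incompatible with that published distribution, whose minimum is 258 terms;
#' the reconstruction follows the distribution, so it holds 258 terms.
#'
#' @return a validated `ccfo_ontology` with 156 concepts.
#' @export
synthetic_full_ontology <- function() {
  ont <- ccfo_core_ontology()
  cc <- ont$concepts
  tt <- ont$terms

  target_bins <- c(`1` = 24, `2` = 29, `3` = 7, `4` = 8, `5` = 6, `6` = 5,
                   `7` = 0, `8` = 3)
  over8 <- c(12, 9, 9, 9)

  doc <- cc$ccfo_id[cc$role == "document-expected"]
  per_concept <- table(factor(tt$ccfo_id, levels = doc))
  have_bins <- sapply(names(target_bins), function(k) {
    sum(per_concept == as.integer(k))
  })
  have_over8 <- sort(as.integer(per_concept[per_concept > 8]), decreasing = TRUE)

  deficit <- target_bins - have_bins
  if (any(deficit < 0)) {
    stop("core fixture overshoots the published terms-per-concept bins: ",
         paste(names(target_bins)[deficit < 0], collapse = ", "))
  }
  pad_over8 <- over8
  for (h in have_over8) {
    i <- match(h, pad_over8)
    if (is.na(i)) stop("core fixture has an unexpected >8-term concept (",
                       h, " terms)")
    pad_over8 <- pad_over8[-i]
  }

  new_concepts <- list()
  new_terms <- list()
  k <- 0
  add_doc_concept <- function(n_terms) {
    k <<- k + 1
    id <- sprintf("9%03d", k)
    new_concepts[[length(new_concepts) + 1]] <<- data.frame(
      ccfo_id = id, sctid = NA_character_,
      name = sprintf("synthetic frailty concept %03d", k),
      parent_id = "9", role = "document-expected", stringsAsFactors = FALSE)
    if (n_terms > 0) {
      new_terms[[length(new_terms) + 1]] <<- data.frame(
        surface = sprintf("synthterm %s %02d", id, seq_len(n_terms)),
        ccfo_id = id, stringsAsFactors = FALSE)
    }
  }

  # synthetic subtree root, so padding stays out of the real hierarchy
  new_concepts[[1]] <- data.frame(
    ccfo_id = "9", sctid = NA_character_,
    name = "synthetic padding finding", parent_id = "1",
    role = "hierarchical-group", stringsAsFactors = FALSE)
  for (bin in names(target_bins)) {
    for (i in seq_len(deficit[[bin]])) add_doc_concept(as.integer(bin))
  }
  for (n in pad_over8) add_doc_concept(n)

  # pad hierarchical groups up to the 156-concept total
  n_now <- nrow(cc) + length(new_concepts)
  n_groups_needed <- 156 - n_now
  if (n_groups_needed < 0) stop("core fixture larger than the published total")
  for (i in seq_len(n_groups_needed)) {
    new_concepts[[length(new_concepts) + 1]] <- data.frame(
      ccfo_id = sprintf("95%03d", i), sctid = NA_character_,
      name = sprintf("synthetic hierarchical group %03d", i),
      parent_id = "9", role = "hierarchical-group", stringsAsFactors = FALSE)
  }

  new_ontology(rbind(cc, do.call(rbind, new_concepts)),
               rbind(tt, do.call(rbind, new_terms)),
               ont$scores, ont$excluded_terms, ont$group_map)
}
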