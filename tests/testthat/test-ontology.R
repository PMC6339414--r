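test_that("core fixture loads, validates cleanly, and knows its key concepts", {
  ont <- test_ont()
  expect_s3_class(ont, "ccfo_ontology")
  expect_identical(nrow(validate_ontology(ont)), 0L)
  expect_identical(concept_name(ont, "1121221"), "bed-ridden finding")
  expect_identical(concept_name(ont, "1121223"), "wheelchair bound finding")
  # the twelve qualifier values, with the three printed ability levels
  expect_identical(summary_counts(ont)$n_qualifier_values, 12L)
  ability <- ont$concepts[ont$concepts$parent_id %in% "41", ]
  expect_setequal(ability$name,
                  c("able qualifier value", "able with difficulty qualifier value",
                    "unable qualifier value"))
  # the highest-term concept carries exactly its twelve published terms
  expect_identical(sum(ont$terms$ccfo_id == "132222"), 12L)
  expect_true(all(c("fatigue", "tired", "weary") %in%
                    ont$terms$surface[ont$terms$ccfo_id == "132222"]))
})

test_that("term lookup honors the lexicon and the exclusion list", {
  ont <- test_ont()
  hit <- concept_for_term(ont, "wheelchair")
  expect_identical(hit$name, "wheelchair bound finding")
  expect_null(concept_for_term(ont, "dressing"))   # excluded ambiguous term
  expect_null(concept_for_term(ont, ""))
  expect_null(concept_for_term(ont, "no such phrase"))
  expect_identical(concept_for_term(ont, "  W/C  ")$ccfo_id, "1121223")
})

test_that("ancestors walks to the correct root and rejects unknown ids", {
  ont <- test_ont()
  anc <- ancestors(ont, "134")
  expect_identical(anc$name,
                   c("physical examination finding", "clinical finding"))
  expect_identical(nrow(ancestors(ont, "1")), 0L)
  anc_q <- ancestors(ont, "412")
  expect_identical(anc_q$name,
                   c("ability interpretation qualifier value", "qualifier values"))
  expect_error(ancestors(ont, "999999"), "unknown ccfo_id")
})

test_that("validation reports violations as data", {
  ont <- test_ont()
  # dangling parent
  broken <- ont
  broken$concepts$parent_id[broken$concepts$ccfo_id == "134"] <- "888888"
  rep1 <- validate_ontology(broken)
  expect_true(any(rep1$rule == "dangling-parent" & rep1$id == "134"))
  # duplicate id
  broken2 <- ont
  broken2$concepts <- rbind(broken2$concepts, broken2$concepts[5, ])
  expect_true(any(validate_ontology(broken2)$rule == "duplicate-id"))
  # term surface equal to an excluded term ("supine" both listed and excluded)
  broken3 <- ont
  broken3$terms <- rbind(broken3$terms,
                         data.frame(surface = "supine", ccfo_id = "1121221"))
  rep3 <- validate_ontology(broken3)
  expect_true(any(rep3$rule == "excluded-term-conflict" & rep3$id == "supine"))
  # rockwood must not decrease towards unable
  broken4 <- ont
  i <- which(broken4$scores$ccfo_id == "11213" & broken4$scores$level == "able")
  broken4$scores$rockwood[i] <- 8
  expect_true(any(validate_ontology(broken4)$rule == "rockwood-monotonicity"))
  # cycles are detected
  broken5 <- ont
  broken5$concepts$parent_id[broken5$concepts$ccfo_id == "1"] <- "134"
  expect_true(any(validate_ontology(broken5)$rule == "cycle"))
})

test_that("loading rejects malformed fixtures with informative errors", {
  dir <- withr::local_tempdir()
  writeLines("ccfo_id\tsctid\tname\tparent_id\trole", file.path(dir, "concepts.tsv"))
  writeLines("surface\tccfo_id", file.path(dir, "terms.tsv"))
  writeLines("ccfo_id\tlevel\trockwood", file.path(dir, "scores.tsv"))
  expect_error(load_ontology(dir, "tabular"), "no root")

  ont <- test_ont()
  dir2 <- withr::local_tempdir()
  export_ontology(ont, dir2, "tabular")
  cc <- read.delim(file.path(dir2, "concepts.tsv"), colClasses = "character")
  write.table(rbind(cc, cc[1, ]), file.path(dir2, "concepts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_ontology(dir2, "tabular"), "duplicate-id")

  expect_error(load_ontology(ccfo_extdata("concepts.tsv"), "xlsx-supplement"),
               "TSV")
  expect_error(load_ontology(file.path(dir, "nowhere"), "tabular"),
               "no such file")
})

test_that("tabular and OWL round-trips preserve concepts, terms and scores", {
  ont <- test_ont()
  for (fmt in c("tabular", "owl")) {
    path <- if (fmt == "tabular") withr::local_tempdir() else
      withr::local_tempfile(fileext = ".owl")
    export_ontology(ont, path, fmt)
    back <- load_ontology(path, fmt)
    sort_df <- function(df) {
      df <- df[do.call(order, df), , drop = FALSE]
      rownames(df) <- NULL
      df
    }
    expect_equal(sort_df(back$concepts), sort_df(ont$concepts))
    expect_equal(sort_df(back$terms), sort_df(ont$terms))
    expect_equal(sort_df(back$scores), sort_df(ont$scores))
    expect_setequal(back$excluded_terms, ont$excluded_terms)
    s1 <- summary_counts(ont)
    s2 <- summary_counts(back)
    expect_identical(s1$n_concepts, s2$n_concepts)
    expect_identical(s1$n_terms, s2$n_terms)
    expect_equal(s1$terms_per_concept_histogram, s2$terms_per_concept_histogram)
  }
  empty <- test_ont()
  empty$concepts <- empty$concepts[0, ]
  expect_error(export_ontology(empty, tempfile(), "tabular"), "empty ontology")
})

test_that("SCTID annotations follow the published assignments", {
  ont <- test_ont()
  cc <- ont$concepts
  sct <- function(id) cc$sctid[cc$ccfo_id == id]
  expect_identical(sct("134"), "31031000119102")  # physical deconditioning
  expect_identical(sct("131"), "60845006")        # dyspnea on exertion
  expect_identical(sct("412"), "371150009")       # able qualifier value
  # concepts the published description deliberately leaves unmapped
  expect_true(is.na(sct("1")))    # clinical finding
  expect_true(is.na(sct("112")))  # physical function finding
  expect_true(is.na(sct("11")))   # clinical history finding
  # every SCTID-bearing concept also has a CCFOID (by construction of the table)
  expect_true(all(nzchar(cc$ccfo_id[!is.na(cc$sctid)])))
})

test_that("synthetic full fixture reproduces the published aggregate counts", {
  full <- test_full_ont()
  expect_identical(nrow(validate_ontology(full)), 0L)
  sc <- summary_counts(full)
  expect_identical(sc$n_concepts, 156L)
  expect_identical(sc$n_document_expected, 86L)
  expect_identical(sc$n_qualifier_values, 12L)
  hist <- sc$terms_per_concept_histogram
  bins <- setNames(rep(0L, 8), as.character(1:8))
  bins[names(hist)[names(hist) %in% names(bins)]] <-
    as.integer(hist[names(hist) %in% names(bins)])
  expect_identical(unname(bins), c(24L, 29L, 7L, 8L, 6L, 5L, 0L, 3L))
  over8 <- as.integer(names(hist))[as.integer(names(hist)) > 8]
  expect_identical(sum(hist[as.character(over8)]), 4L)
  expect_identical(max(over8), 12L)  # lack of energy keeps the most terms
  expect_identical(sum(as.integer(names(hist)) * as.integer(hist)), sc$n_terms)
})
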