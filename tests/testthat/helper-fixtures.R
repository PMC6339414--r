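# Shared fixtures, loaded once per test run.
.fixture_env <- new.env(parent = emptyenv())

test_ont <- function() {
  if (is.null(.fixture_env$ont)) .fixture_env$ont <- ccfo_core_ontology()
  .fixture_env$ont
}

test_full_ont <- function() {
  if (is.null(.fixture_env$full)) .fixture_env$full <- synthetic_full_ontology()
  .fixture_env$full
}

test_config <- function() {
  if (is.null(.fixture_env$cfg)) .fixture_env$cfg <- extraction_config()
  .fixture_env$cfg
}

concept_name <- function(ont, id) {
  ont$concepts$name[ont$concepts$ccfo_id == id]
}

# The fully independent Katz evidence set: four able personal-care activities,
# an able transfer, and continence evidence of both kinds.
independent_katz_set <- function() {
  findings(finding("112441", "able"), finding("112442", "able"),
           finding("112444", "able"), finding("112445", "able"),
           finding("1122", "able"),
           finding("112721"), finding("112722"))
}

# The fully dependent set: incontinence of both kinds, every personal-care
# child unable, absent transfer, bed-ridden, unable stairs.
dependent_set <- function() {
  findings(finding("112711"), finding("112712"),
           finding("112441", "unable"), finding("112442", "unable"),
           finding("112443", "unable"), finding("112444", "unable"),
           finding("112445", "unable"),
           finding("1122", "absent"),
           finding("1121221", "only-level"),
           finding("1124713", "unable"))
}

# Independent reimplementation of the printed Katz counting rule, used as an
# oracle against the generic rule engine. Takes abstract slot states instead
# of findings.
katz_oracle <- function(bathing, dressing, toileting, feeding, transfer,
                        continence) {
  pc <- c(bathing, dressing, toileting, feeding)
  sum(pc == "able") +
    as.integer(transfer == "able") +
    as.integer(continence == "both-continent")
}

# Build the finding set realizing abstract Katz slot states.
katz_findings <- function(bathing, dressing, toileting, feeding, transfer,
                          continence) {
  out <- list()
  slots <- c(bathing = "112441", dressing = "112442", toileting = "112444",
             feeding = "112445", transfer = "1122")
  states <- c(bathing, dressing, toileting, feeding, transfer)
  for (i in seq_along(slots)) {
    if (states[i] != "none") out[[length(out) + 1]] <- finding(slots[i], states[i])
  }
  if (continence == "both-continent") {
    out <- c(out, list(finding("112721"), finding("112722")))
  } else if (continence == "both-incontinent") {
    out <- c(out, list(finding("112711"), finding("112712")))
  } else if (continence == "one-continent") {
    out <- c(out, list(finding("112721")))
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}
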