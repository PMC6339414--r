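test_that("Katz counting matches the published worked examples", {
  ont <- test_ont()
  expect_equal(score_katz(independent_katz_set(), ont)$total, 6)

  dependent <- findings(finding("112441", "unable"), finding("112442", "unable"),
                        finding("112444", "unable"), finding("112445", "unable"),
                        finding("1122", "unable"),
                        finding("112711"), finding("112712"))
  expect_equal(score_katz(dependent, ont)$total, 0)

  # only both-kind continence evidence, nothing else
  cont_only <- findings(finding("112721"), finding("112722"))
  r <- score_katz(cont_only, ont)
  expect_equal(r$total, 1)
  expect_equal(r$coverage, 1 / 6)

  # absent-qualified incontinence is continence evidence
  via_absent <- findings(finding("112711", "absent", assertion = "negated"),
                         finding("112712", "absent", assertion = "negated"))
  expect_equal(score_katz(via_absent, ont)$total, 1)
})

test_that("Katz equals a brute-force interpretation of the printed rules", {
  ont <- test_ont()
  states <- c("able", "unable", "none")
  cont_states <- c("both-continent", "both-incontinent", "one-continent", "none")
  for (bathing in states) for (dressing in states) for (toileting in states) {
    for (feeding in states) for (transfer in states) for (cont in cont_states) {
      fnd <- katz_findings(bathing, dressing, toileting, feeding, transfer, cont)
      got <- score_katz(fnd, ont)$total
      want <- katz_oracle(bathing, dressing, toileting, feeding, transfer, cont)
      expect_equal(got, want,
                   info = paste(bathing, dressing, toileting, feeding,
                                transfer, cont))
    }
  }
})

test_that("Barthel applies every printed rule", {
  ont <- test_ont()
  expect_equal(score_barthel(dependent_set(), ont)$total, 0)

  # wheelchair-bound alone contributes mobility = 1
  r <- score_barthel(finding("1121223", "only-level"), ont)
  expect_equal(r$blocks$points[r$blocks$item == "mobility"], 1)
  expect_equal(r$total, 1)

  # unqualified personal-care children count as able: 5 children x 2 points
  pc <- findings(finding("112441"), finding("112442"), finding("112443"),
                 finding("112444"), finding("112445"))
  rp <- score_barthel(pc, ont)
  expect_equal(sum(rp$blocks$points[grepl("personal_care", rp$blocks$item)]), 10)

  # best case under the printed rules sums to 19 on the published 0-20 scale
  best <- findings(finding("112721"), finding("112722"),
                   finding("112441", "able"), finding("112442", "able"),
                   finding("112443", "able"), finding("112444", "able"),
                   finding("112445", "able"), finding("1122", "able"),
                   finding("112121", "able"), finding("1124713", "able"))
  rb <- score_barthel(best, ont)
  expect_equal(rb$total, 19)
  expect_equal(rb$scale_min, 0)
  expect_equal(rb$scale_max, 20)
  # the per-kind continence reading reaches 21
  expect_equal(score_barthel(best, ont, continence_per_kind = TRUE)$total, 21)

  # conflicting evidence resolves to the worst reading
  conflict <- findings(finding("112121", "able"), finding("1121221", "only-level"))
  rc <- score_barthel(conflict, ont)
  expect_equal(rc$blocks$points[rc$blocks$item == "mobility"], 0)
})

test_that("SF-36 sections average covered question blocks", {
  ont <- test_ont()
  # best-case general health: high-frequency fit-and-well, plus the same with
  # sudden-onset course for the second question block
  gh_best <- findings(finding("1323", "high-frequency"),
                      finding("1323", "high-frequency", course = "sudden-onset"))
  s <- score_sf36(gh_best, ont)$sections
  expect_equal(unname(s["general_health"]), 100)
  expect_true(all(is.na(s[setdiff(names(s), "general_health")])))

  # worst-case: high-frequency generally-unwell covers both blocks at 0
  gh_worst <- score_sf36(finding("1324", "high-frequency"), ont)$sections
  expect_equal(unname(gh_worst["general_health"]), 0)

  # mid-frequency pain: question 21 = 50, question 22 uncovered
  r <- score_sf36(finding("1111", "mid-frequency"), ont)
  expect_equal(unname(r$sections["pain"]), 50)
  expect_false(r$blocks$covered[r$blocks$block == "pain_q22"])

  # multi-question blocks carry their question count as weight
  pf <- score_sf36(findings(finding("112471", "able"),       # 3 questions, 300
                            finding("1124713", "unable")),   # 2 questions, 0
                   ont)
  expect_equal(unname(pf$sections["physical_functioning"]), 300 / 5)

  # compound rule: pain relief with able daily routine
  q22 <- score_sf36(findings(finding("1111", "absent", assertion = "negated"),
                             finding("11245", "able")), ont)
  expect_equal(unname(q22$sections["pain"]), 100)
})

test_that("duplicate and irrelevant findings do not change totals", {
  ont <- test_ont()
  base <- independent_katz_set()
  dup <- rbind(base, base[1, ], base[1, ])
  expect_equal(score_katz(dup, ont)$total, score_katz(base, ont)$total)
  expect_equal(score_barthel(dup, ont)$total, score_barthel(base, ont)$total)
  plus_calm <- rbind(base, finding("113331", "high-frequency"))
  expect_equal(score_katz(plus_calm, ont)$total, score_katz(base, ont)$total)
  expect_equal(score_barthel(plus_calm, ont)$total, score_barthel(base, ont)$total)
})

# Qualifier ladders from worst to best, per concept, for the monotonicity
# property. Ability concepts improve unable -> with-difficulty -> able;
# deficit-frequency concepts improve high -> mid -> absent; positive-frequency
# concepts improve absent -> mid -> high.
ladder_for <- function(ont, id) {
  axis <- concept_axis(ont, id)
  if (axis == "ability-interpretation") {
    c("unable", "with-difficulty", "able")
  } else if (concept_polarity(ont, id) == "deficit") {
    c("high-frequency", "mid-frequency", "absent")
  } else {
    c("absent", "mid-frequency", "high-frequency")
  }
}

test_that("instrument totals are monotone under qualifier improvement", {
  ont <- test_ont()
  pool <- c("112441", "112442", "112443", "112444", "112445", "1122",
            "112121", "1124713", "11211", "112471", "11245",
            "1111", "1324", "1323", "132222", "113331", "113334")
  set.seed(421)
  for (rep in 1:40) {
    ids <- sample(pool, sample(3:8, 1))
    lv <- vapply(ids, function(id) {
      l <- ladder_for(ont, id)
      sample(seq_along(l), 1)
    }, integer(1))
    mk <- function(ids, lv) {
      do.call(rbind, lapply(seq_along(ids), function(i) {
        finding(ids[i], ladder_for(ont, ids[i])[lv[i]])
      }))
    }
    before <- mk(ids, lv)
    # improve one finding that is not already at the top of its ladder
    cand <- which(lv < 3)
    if (length(cand) == 0) next
    j <- cand[sample.int(length(cand), 1)]
    lv2 <- lv
    lv2[j] <- lv[j] + 1
    after <- mk(ids, lv2)

    expect_gte(score_katz(after, ont)$total, score_katz(before, ont)$total)
    expect_gte(score_barthel(after, ont)$total, score_barthel(before, ont)$total)
    s_before <- score_sf36(before, ont)$sections
    s_after <- score_sf36(after, ont)$sections
    both <- !is.na(s_before) & !is.na(s_after)
    expect_true(all(s_after[both] >= s_before[both] - 1e-9),
                info = paste(ids, collapse = ","))
  }
})

test_that("rule tables are loadable data with intact antecedents", {
  ont <- test_ont()
  for (ins in c("katz", "barthel", "sf36")) {
    rules <- scoring_rules(ins)
    expect_true(all(rules$points >= 0))
    concepts <- unique(c(rules$c1_concept, rules$c2_concept))
    concepts <- concepts[!is.na(concepts)]
    expect_true(all(concepts %in% ont$concepts$ccfo_id))
  }
})
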