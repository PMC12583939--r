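test_that("rule text from the conditional-scheduling syntax parses clause by clause", {
  rs <- parse_rule_set(
    "{'interactions_exist': ['IS', 'V1','V2']}, {'interactions_not_exist': ['V3', 'V4', 'V5', 'V6', 'IF']}")
  expect_length(rs$clauses, 2L)
  expect_equal(rs$clauses[[1]]$fun, "interactions_exist")
  expect_equal(rs$clauses[[1]]$arg, c("IS", "V1", "V2"))
  expect_equal(rs$clauses[[2]]$fun, "interactions_not_exist")
  expect_equal(rs$clauses[[2]]$arg, c("V3", "V4", "V5", "V6", "IF"))

  # typographic quotes and a trailing comma, as found in protocol prose
  rs3 <- parse_rule_set(
    "{“studyPhase”:”onStudy”}, {“sampleObtained”:”true”}, {“geneticTestingConsent”:”true”},")
  expect_length(rs3$clauses, 3L)
  expect_equal(rs3$clauses[[1]]$arg, "onStudy")
  expect_true(isTRUE(rs3$clauses[[2]]$arg))  # "true" coerced to logical

  expect_length(parse_rule_set("")$clauses, 0L)
  expect_length(parse_rule_set(NA)$clauses, 0L)
})

test_that("malformed rule text is rejected", {
  expect_error(parse_rule_set("{'a': 1, 'b': 2}"), "single")
  expect_error(parse_rule_set("{'unclosed': "), "malformed")
  expect_error(rule_clause("n_cycles", "about six"), "malformed comparison")
  expect_error(rule_clause("maxRepeats", "many"), "integer")
  expect_error(rule_clause("interactions_exist", 3), "aliases")
})

test_that("parse/serialize round trip is structurally loss-free", {
  set.seed(401)
  for (i in 1:50) {
    rs <- random_rule_set()
    txt <- serialize_rule_set(rs)
    expect_equal(parse_rule_set(txt), rs, label = paste("case", i, txt))
  }
  # canonical form uses double quotes regardless of input dialect
  expect_equal(serialize_rule_set(parse_rule_set("{'maxRepeats':4}")),
               "{\"maxRepeats\": 4}")
})

test_that("history clauses follow membership semantics", {
  ctx <- soa_context(history = c("IS", "V1", "V2"), days = c(0, 1, 8))
  ed <- dummy_edge()
  expect_true(evaluate_clause(rule_clause("interactions_exist",
                                          c("IS", "V1", "V2")), ctx, ed))
  expect_false(evaluate_clause(rule_clause("interactions_exist",
                                           c("IS", "V3")), ctx, ed))
  expect_false(evaluate_clause(
    rule_clause("interactions_not_exist", c("V3", "V4", "V5", "V6", "IF")),
    soa_context(history = c("IS", "V1", "V2", "V3")), ed))
  # vacuous truth on the empty list and the empty history
  expect_true(evaluate_clause(rule_clause("interactions_exist", character()),
                              soa_context(), ed))
})

test_that("maxRepeats compares the target's execution count with strict less-than", {
  ed <- dummy_edge("BP")
  for (count in 0:5) {
    ctx <- soa_context(counts = setNames(as.integer(count), "BP"))
    expect_equal(
      evaluate_clause(rule_clause("maxRepeats", 4L), ctx, ed,
                      target_alias = "BP"),
      count < 4,                      # independent enumeration oracle
      label = paste("count", count))
  }
})

test_that("n_cycles compares the prospective cycle index", {
  ed <- dummy_edge()
  # "<6" caps completed cycles at five: prospective cycle 6 is refused
  for (done in 0:7) {
    ctx <- soa_context(completed_cycles = done)
    expect_equal(evaluate_clause(rule_clause("n_cycles", "<6"), ctx, ed),
                 done + 1 < 6, label = paste("completed", done))
  }
  ctx2 <- soa_context(completed_cycles = 2L)
  expect_true(evaluate_clause(rule_clause("n_cycles", "=3"), ctx2, ed))
  expect_true(evaluate_clause(rule_clause("n_cycles", ">=3"), ctx2, ed))
  expect_false(evaluate_clause(rule_clause("n_cycles", ">3"), ctx2, ed))
  expect_true(evaluate_clause(rule_clause("n_cycles", "<=3"), ctx2, ed))
})

test_that("flag clauses use the open vocabulary with true/false coercion", {
  ed <- dummy_edge()
  ctx <- soa_context(flags = list(consentObtained = TRUE,
                                  sampleObtained = "true",
                                  studyPhase = "onStudy"))
  expect_true(evaluate_clause(rule_clause("consentObtained", TRUE), ctx, ed))
  expect_true(evaluate_clause(rule_clause("sampleObtained", "TRUE"), ctx, ed))
  expect_true(evaluate_clause(rule_clause("studyPhase", "onStudy"), ctx, ed))
  expect_false(evaluate_clause(rule_clause("studyPhase", "screening"), ctx, ed))
  # missing flag: lenient FALSE with a warning, strict error
  expect_warning(res <- evaluate_clause(rule_clause("record_AE", TRUE), ctx, ed),
                 "missing")
  expect_false(res)
  expect_error(evaluate_clause(rule_clause("record_AE", TRUE), ctx, ed,
                               strict = TRUE), "missing")
})

test_that("rule sets are the conjunction of their clauses (truth-table oracle)", {
  ed <- dummy_edge()
  # exhaustive truth table over four independent flag clauses
  flags <- c("f1", "f2", "f3", "f4")
  rs <- rule_set(lapply(flags, function(f) rule_clause(f, TRUE)))
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), 4))
  for (r in seq_len(nrow(grid))) {
    ctx <- soa_context(flags = setNames(as.list(unlist(grid[r, ])), flags))
    expect_equal(evaluate_rule_set(rs, ctx, ed),
                 all(unlist(grid[r, ])),        # brute-force oracle
                 label = paste(unlist(grid[r, ]), collapse = ","))
  }
  # the three-clause genetic-testing example
  gen <- parse_rule_set(
    '{"studyPhase":"onStudy"}, {"sampleObtained":"true"}, {"geneticTestingConsent":"true"}')
  ok <- soa_context(flags = list(studyPhase = "onStudy",
                                 sampleObtained = TRUE,
                                 geneticTestingConsent = TRUE))
  expect_true(evaluate_rule_set(gen, ok, ed))
  no <- ok; no$flags$geneticTestingConsent <- FALSE
  expect_false(evaluate_rule_set(gen, no, ed))
  expect_true(evaluate_rule_set(rule_set(), soa_context(), ed))
})

test_that("rule-set evaluation equals the AND-fold of clause evaluations", {
  set.seed(402)
  for (i in 1:60) {
    rs <- random_rule_set()
    ctx <- random_context()
    per_clause <- vapply(rs$clauses, function(cl)
      suppressWarnings(evaluate_clause(cl, ctx, target_alias = "V1")), TRUE)
    expect_equal(suppressWarnings(
      evaluate_rule_set(rs, ctx, target_alias = "V1")),
      all(per_clause), label = paste("case", i))
  }
})

test_that("adding a clause never turns a false rule set true (monotonicity)", {
  set.seed(403)
  for (i in 1:40) {
    rs <- random_rule_set()
    ctx <- random_context()
    base <- suppressWarnings(evaluate_rule_set(rs, ctx, target_alias = "V1"))
    extra <- random_rule_set(1L)
    if (length(extra$clauses) == 0L) next
    grown <- rule_set(c(rs$clauses, extra$clauses))
    res <- suppressWarnings(evaluate_rule_set(grown, ctx, target_alias = "V1"))
    if (!base) expect_false(res, label = paste("case", i))
  }
})
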