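# CUI mapping, ensemble-by-union, pipeline driver.

cui_df <- function(start, end, cui, surface) {
  data.frame(start = start, end = end, cui = cui, surface = surface,
             stringsAsFactors = FALSE)
}

test_that("CUI annotations map through ontology xrefs", {
  # unique xref -> one annotation
  one <- map_cui_to_hpo(cui_df(0L, 5L, "UMLS:C1306620", "renal"), mini_onto)
  expect_equal(one$hpo_id, "HP:5000006")
  expect_equal(one$engine, "metamap")

  # unmapped CUI -> dropped with a reported count
  expect_message(
    none <- map_cui_to_hpo(cui_df(0L, 5L, "UMLS:C9999999", "mystery"),
                           mini_onto),
    "no HPO xref")
  expect_equal(nrow(none), 0L)

  # shared xref -> two same-span annotations
  two <- map_cui_to_hpo(cui_df(3L, 8L, "UMLS:C0015967", "fever"), mini_onto)
  expect_equal(nrow(two), 2L)
  expect_setequal(two$hpo_id, c("HP:5000007", "HP:5000008"))
  expect_equal(unique(two$start), 3L)
})

test_that("ensemble union merges disjoint, duplicate, and conflicting results", {
  text <- "alpha beta gamma delta kappa"
  a2 <- make_annotations(text, c("alpha", "beta"), c("HP:1", "HP:2"))
  a3 <- make_annotations(text, c("gamma", "delta", "kappa"),
                         c("HP:3", "HP:4", "HP:5"))
  r1 <- engine_result("dict", a2, text)
  r2 <- engine_result("mock", a3, text)

  u <- ensemble_union(list(r1, r2))
  expect_equal(nrow(u), 5L)                       # disjoint union
  expect_true(all(u$engine == "ensemble"))

  dup <- ensemble_union(list(r1, engine_result("mock", a2, text)))
  expect_equal(nrow(dup), 2L)                     # exact duplicates collapse

  # all four negation combinations on the same (span, concept)
  for (flags in list(c(FALSE, FALSE), c(TRUE, FALSE),
                     c(FALSE, TRUE), c(TRUE, TRUE))) {
    x <- make_annotations(text, "alpha", "HP:1", negated = flags[1])
    y <- make_annotations(text, "alpha", "HP:1", negated = flags[2])
    m <- ensemble_union(list(engine_result("a", x, text),
                             engine_result("b", y, text)))
    expect_equal(m$negated, all(flags))
  }
})

test_that("documents of differing length cannot be unioned", {
  a <- engine_result("a", empty_annotations(), "short")
  b <- engine_result("b", empty_annotations(), "a much longer document")
  expect_error(ensemble_union(list(a, b)), "differing length")
})

test_that("the union is a superset of every engine, idempotent, order-invariant", {
  set.seed(33)
  for (i in 1:40) {
    text <- random_text(40L)
    if (!nzchar(text)) next
    results <- lapply(1:3, function(k)
      engine_result(paste0("e", k), random_mock_annotations(text), text))
    u <- ensemble_union(results)
    ukey <- paste(u$start, u$end, u$hpo_id)
    for (r in results) {
      rkey <- paste(r$annotations$start, r$annotations$end,
                    r$annotations$hpo_id)
      expect_true(all(rkey %in% ukey))
    }
    # idempotent: union of the union is itself
    again <- ensemble_union(list(engine_result("ensemble", u, text)))
    expect_equal(again, u)
    # order-invariant
    rev_u <- ensemble_union(rev(results))
    expect_equal(rev_u, u)
  }
})

test_that("a single dict engine without negation is find_matches verbatim", {
  text <- "Exam shows short stature and fever."
  got <- run_pipeline(text, list(dict_engine(mini_matcher)), negate = FALSE)
  expect_identical(got, find_matches(mini_matcher, text))
})

test_that("union with a superset mock equals the mock's set", {
  text <- "Exam shows short stature today."
  dict_ann <- find_matches(mini_matcher, text)
  extra <- make_annotations(text, "Exam", "HP:5000008", engine = "mock")
  mock <- structure(list(id = "mock",
                         run = function(t) rbind(dict_ann, extra)),
                    class = "phenotext_engine")
  u <- run_pipeline(text, list(dict_engine(mini_matcher), mock),
                    negate = FALSE)
  expect_equal(nrow(u), nrow(dict_ann) + 1L)
  expect_setequal(paste(u$start, u$hpo_id),
                  paste(c(dict_ann$start, extra$start),
                        c(dict_ann$hpo_id, extra$hpo_id)))
})

test_that("a failing engine degrades to an empty result with a warning", {
  text <- "Exam shows fever."
  boom <- structure(list(id = "boom",
                         run = function(t) stop("service down")),
                    class = "phenotext_engine")
  expect_warning(out <- run_pipeline(text,
                                     list(dict_engine(mini_matcher), boom),
                                     negate = FALSE),
                 "boom.*failed|failed.*boom")
  expect_equal(sort(out$hpo_id),
               sort(find_matches(mini_matcher, text)$hpo_id))

  expect_warning(none <- run_pipeline(text, list(boom), negate = FALSE))
  expect_equal(nrow(none), 0L)
})

test_that("negation inside the pipeline flags dict matches", {
  text <- "Patient denies fever."
  out <- run_pipeline(text, list(dict_engine(mini_matcher)), negate = TRUE)
  expect_true(out$negated[out$hpo_id == "HP:5000007"])
})

test_that("a replay engine reproduces recorded annotations", {
  text <- "Exam shows fever today."
  ann <- find_matches(mini_matcher, text)
  f <- withr::local_tempfile(fileext = ".json")
  write_standoff(annotated_document("d1", text, ann), f)
  out <- run_pipeline(text, list(replay_engine(f)), negate = FALSE)
  expect_equal(out$hpo_id, ann$hpo_id)
  expect_equal(out$start, ann$start)
  # replay against the wrong text fails that engine, pipeline continues
  expect_warning(
    other <- run_pipeline("some other document text",
                          list(replay_engine(f)), negate = FALSE),
    "failed")
  expect_equal(nrow(other), 0L)
})
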