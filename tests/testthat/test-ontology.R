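# OBO parsing, graph queries, lexicon construction.

test_that("the bundled miniature ontology parses with the expected shape", {
  # independent count: scan the raw file text for stanzas and obsolete flags
  raw <- readLines(mini_obo_path)
  n_stanzas <- sum(raw == "[Term]")
  n_obsolete <- sum(grepl("^is_obsolete: true", raw))

  expect_equal(mini_onto$n_terms, n_stanzas)
  expect_equal(sum(vapply(mini_onto$terms, `[[`, logical(1), "obsolete")),
               n_obsolete)
  expect_equal(mini_onto$terms[["HP:5000002"]]$name, "Short stature")
  expect_equal(mini_onto$terms[["HP:5000006"]]$parents,
               c("HP:5000004", "HP:5000005"))
  syn <- mini_onto$terms[["HP:5000009"]]$synonyms
  expect_setequal(syn$scope, c("EXACT", "NARROW"))
  expect_true("UMLS:C0015967" %in% mini_onto$terms[["HP:5000007"]]$xrefs)
})

test_that("parsing an hp.obo-style stanza yields the stated id and name", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:0000118", "name: Phenotypic abnormality"), f)
  onto <- parse_obo(f)
  expect_equal(onto$terms[["HP:0000118"]]$name, "Phenotypic abnormality")
})

test_that("empty input yields an empty ontology", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(character(0), f)
  expect_equal(parse_obo(f)$n_terms, 0L)
})

test_that("malformed stanzas are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "name: Orphan stanza"), f)
  expect_error(parse_obo(f), "line 3.*missing id|missing id.*line 3")

  g <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:0000001", "name: A", "",
               "[Term]", "id: HP:0000001", "name: B"), g)
  expect_error(parse_obo(g), "duplicate")
})

test_that("re-parsing the serialized fixture is deterministic", {
  f <- withr::local_tempfile(fileext = ".obo")
  write_mini_ontology(f)
  expect_identical(parse_obo(f), parse_obo(f))
  expect_identical(parse_obo(f), mini_onto)
})

test_that("descendants handles leaves, diamonds, and unknown roots", {
  # leaf
  expect_equal(descendants(mini_onto, "HP:5000002"), "HP:5000002")
  # diamond A->B, A->C, B->D, C->D: D reachable once
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:0000001", "name: A",
               "", "[Term]", "id: HP:0000002", "name: B",
               "is_a: HP:0000001",
               "", "[Term]", "id: HP:0000003", "name: C",
               "is_a: HP:0000001",
               "", "[Term]", "id: HP:0000004", "name: D",
               "is_a: HP:0000002", "is_a: HP:0000003"), f)
  onto <- parse_obo(f)
  expect_setequal(descendants(onto, "HP:0000001"),
                  c("HP:0000001", "HP:0000002", "HP:0000003", "HP:0000004"))
  expect_error(descendants(onto, "HP:9999999"), "unknown")
})

test_that("a cyclic is_a graph is detected on demand", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:0000001", "name: A", "is_a: HP:0000002",
               "", "[Term]", "id: HP:0000002", "name: B",
               "is_a: HP:0000001"), f)
  onto <- parse_obo(f)
  expect_error(descendants(onto, "HP:0000001"), "cycle")
})

test_that("descendants agrees with brute-force reachability on random DAGs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:20, 1)
    ids <- sprintf("HP:%07d", seq_len(n))
    # edges only from lower to higher index: guaranteed acyclic
    edges <- data.frame(parent = character(), child = character())
    stanzas <- character(0)
    for (i in seq_len(n)) {
      parents <- if (i == 1) integer(0) else
        sample(seq_len(i - 1), sample(0:min(2, i - 1), 1))
      stanzas <- c(stanzas, "[Term]", paste0("id: ", ids[i]),
                   paste0("name: node", i),
                   paste0("is_a: ", ids[parents]), "")
      if (length(parents)) {
        edges <- rbind(edges, data.frame(parent = ids[parents],
                                         child = ids[i]))
      }
    }
    f <- tempfile(fileext = ".obo")
    writeLines(stanzas, f)
    onto <- parse_obo(f)
    root <- sample(ids, 1)
    expect_equal(sort(descendants(onto, root)),
                 brute_reachable(edges, root))
    unlink(f)
  }
})

test_that("lexicon entries follow the name-plus-in-scope-synonyms rule", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:0000001", "name: Root only", "",
               "[Term]", "id: HP:0000002", "name: Twin synonyms",
               "synonym: \"first twin\" EXACT []",
               "synonym: \"second twin\" EXACT []",
               "is_a: HP:0000001"), f)
  onto <- parse_obo(f)
  lex1 <- build_lexicon(onto, "HP:0000002", include_scopes = "EXACT")
  expect_equal(nrow(lex1), 3L)   # 1 NAME + 2 SYNONYM
  expect_equal(sum(lex1$source == "NAME"), 1L)
  lexroot <- build_lexicon(onto, "HP:0000001", include_scopes = "BROAD")
  # no BROAD synonyms anywhere: names only
  expect_true(all(lexroot$source == "NAME"))
  expect_equal(nrow(lexroot), 2L)
})

test_that("fixture lexicon size matches an independent text scan", {
  # oracle: walk the raw OBO text, find non-obsolete stanzas reachable from
  # the fixture root, and sum 1 + synonym count
  raw <- readLines(mini_obo_path)
  breaks <- c(which(raw == "[Term]"), length(raw) + 1L)
  stanzas <- lapply(seq_len(length(breaks) - 1L), function(i)
    raw[breaks[i]:(breaks[i + 1L] - 1L)])
  ids <- vapply(stanzas, function(s)
    sub("^id: ", "", grep("^id: ", s, value = TRUE)[1]), character(1))
  obsolete <- vapply(stanzas, function(s)
    any(grepl("^is_obsolete: true", s)), logical(1))
  edges <- do.call(rbind, lapply(seq_along(stanzas), function(i) {
    p <- sub(" !.*$", "", sub("^is_a: ", "",
                              grep("^is_a: ", stanzas[[i]], value = TRUE)))
    if (length(p)) data.frame(parent = p, child = ids[i]) else NULL
  }))
  in_scope <- brute_reachable(edges, mini_root_id())
  keep <- ids %in% in_scope & !obsolete
  expected <- sum(vapply(stanzas[keep], function(s)
    1L + sum(grepl("^synonym: ", s)), integer(1)))

  expect_equal(nrow(mini_lex), expected)
})

test_that("lexicon scope invariants hold on the fixture", {
  in_scope <- descendants(mini_onto, mini_root_id())
  expect_true(all(mini_lex$hpo_id %in% in_scope))
  # obsolete terms contribute nothing
  expect_false(any(mini_lex$hpo_id %in% c("HP:5000010", "HP:5000011")))
  # the out-of-subtree term contributes nothing
  expect_false("HP:5000012" %in% mini_lex$hpo_id)
})

test_that("labels normalizing to empty are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:0000001", "name: ???", ""), f)
  onto <- parse_obo(f)
  expect_warning(lex <- build_lexicon(onto, "HP:0000001"), "empty")
  expect_equal(nrow(lex), 0L)
})

test_that("unknown build root is an error", {
  expect_error(build_lexicon(mini_onto, "HP:0000000"), "unknown")
})
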