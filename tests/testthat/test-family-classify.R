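test_that("CRP rule: even cysteine count between 2 and 16", {
  # exhaustive sweep over cysteine counts 0..20
  seqs <- vapply(0:20, function(k) {
    paste0(strrep("A", 5), strrep("CA", k), "G")
  }, character(1))
  res <- is_crp(seqs)
  expect_equal(res$cys_count, 0:20)
  expect_equal(res$is_crp, (0:20) %% 2 == 0 & (0:20) >= 2 & (0:20) <= 16)
})

test_that("cysteine-spacing pattern grammar parses and rejects as specified", {
  p1 <- parse_cys_pattern("C x3 C x5 C x5 C x2 C xn C")
  expect_equal(p1$n_cys, 6L)
  expect_equal(
    purrr::map_chr(p1$gaps, "type"),
    c("exact", "exact", "exact", "exact", "variable")
  )
  expect_equal(purrr::map_int(p1$gaps[1:4], "k"), c(3L, 5L, 5L, 2L))

  p2 <- parse_cys_pattern("C x5 C xn C x6 C x4-6 C x1 C")
  expect_equal(p2$gaps[[4]], list(type = "range", a = 4L, b = 6L))

  expect_error(parse_cys_pattern("C C"), "alternate")
  expect_error(parse_cys_pattern("C x3 C xq C"), "malformed gap token")
  expect_error(parse_cys_pattern("x3 C x3"), "expected 'C'")
})

test_that("pattern matching agrees with hand-checked examples", {
  crp1 <- parse_cys_pattern("C x3 C x5 C x5 C x2 C xn C")
  s <- paste0("A", "C", "AAA", "C", "AAAAA", "C", "AAAAA", "C", "AA", "C",
              "AAAA", "C", "G")
  m <- match_cys_pattern(crp1, s)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1L)                  # first cysteine, 0-based
  expect_equal(length(m$cys_positions[[1]]), 6)
  # same sequence without the final cysteine: no match
  expect_equal(nrow(match_cys_pattern(crp1, sub("CG$", "G", s))), 0)
  # zero gap
  expect_equal(nrow(match_cys_pattern("C x0 C", "AACCAA")), 1)
  expect_equal(nrow(match_cys_pattern("C x1 C", "AACCAA")), 0)
})

test_that("pattern matcher agrees with the regex oracle on random sequences", {
  patterns <- list(
    parse_cys_pattern("C x3 C x5 C x5 C x2 C xn C"),
    parse_cys_pattern("C x5 C xn C x6 C x4-6 C x1 C"),
    parse_cys_pattern("C x0 C x2 C")
  )
  withr::with_seed(101, {
    for (pat in patterns) {
      for (i in seq_len(300)) {
        s <- random_aa(sample(20:80, 1), alphabet = c("A", "C", "G"))
        got <- match_cys_pattern(pat, s)
        want <- oracle_cys_matches(pat, s)
        expect_equal(got$start, want$start, info = s)
        expect_equal(got$end, want$end, info = s)
      }
    }
  })
})

test_that("shipped rules lint against the 38-family vocabulary", {
  vocab <- ssp_family_vocabulary()
  expect_equal(nrow(vocab), 38)
  expect_equal(anyDuplicated(vocab$family), 0)
  rules <- default_family_rules()
  # class/mode-of-action always come from the vocabulary
  joined <- dplyr::left_join(rules, vocab, by = "family",
                             suffix = c("", ".vocab"))
  expect_equal(joined$ssp_class, joined$ssp_class.vocab)
  expect_equal(joined$mode_of_action, joined$mode_of_action.vocab)
  expect_error(
    lint_family_rules(tibble::tibble(
      family = "NOTAFAMILY", motif = "AA", priority = 1
    )),
    "not in the vocabulary"
  )
  expect_error(lint_family_rules(rules[0, ]), "Empty")
})

test_that("planted families are classified with the correct class and domain count", {
  sim <- simulate_proteome(seed = 7)
  casc <- run_cascade(sim$proteome)
  cl <- classify_families(casc$ssp)
  truth <- dplyr::inner_join(
    cl, sim$manifest[, c("protein_id", "family", "n_domains", "category")],
    by = "protein_id", suffix = c("", ".true")
  )
  known <- dplyr::filter(truth, !is.na(family.true))
  expect_equal(known$family, known$family.true)
  expect_equal(known$n_domains, known$n_domains.true)
  expect_equal(unique(known$ssp_class[known$family == "CEP"]), "PTM")
  expect_equal(unique(known$ssp_class[known$family == "RALF"]), "CRP")
  expect_equal(unique(known$ssp_class[known$family == "PNP"]), "NonCysNonPTM")
  # novel-archetype candidates remain unknown and are CRPs
  novel <- dplyr::filter(truth, category %in% c("crp6c_i", "crp6c_ii"))
  expect_true(all(novel$family == "unknown"))
  expect_true(all(novel$is_crp))
  expect_true(all(novel$cys_count == 6))
})

test_that("novel CRP family discovery recovers planted archetypes", {
  sim <- simulate_proteome(
    proteome_config(cep = 0, cle = 0, ralf = 0, pnp = 0, crp6c_i = 7,
                    crp6c_ii = 10, cep_multi = 0, oversize = 0, no_sp = 0,
                    tm = 0, kdel = 0),
    seed = 21
  )
  casc <- run_cascade(sim$proteome)
  fam <- discover_crp_families(casc$ssp)
  expect_equal(nrow(fam), 2)
  expect_setequal(fam$pattern_label,
                  c("C x3 C x5 C x5 C x2 C xn C",
                    "C x5 C xn C x6 C x4-6 C x1 C"))
  # membership matches the manifest category exactly (no cross-contamination)
  for (i in seq_len(2)) {
    cats <- sim$manifest$category[match(fam$members[[i]],
                                        sim$manifest$protein_id)]
    expect_equal(dplyr::n_distinct(cats), 1)
  }
  expect_setequal(fam$n_members, c(7L, 10L))

  # permutation stability: shuffled input yields the same groups as sets
  withr::with_seed(55, {
    for (k in seq_len(5)) {
      shuffled <- casc$ssp[sample(nrow(casc$ssp)), ]
      fam2 <- discover_crp_families(shuffled)
      expect_equal(nrow(fam2), 2)
      expect_setequal(
        purrr::map_chr(fam$members, ~ paste(sort(.x), collapse = ",")),
        purrr::map_chr(fam2$members, ~ paste(sort(.x), collapse = ","))
      )
      expect_setequal(fam2$pattern_label, fam$pattern_label)
    }
  })

  # clusters below min_members are not reported
  few <- dplyr::slice(casc$ssp, 1:2)  # two archetype-I members only
  expect_equal(nrow(discover_crp_families(few, min_members = 3)), 0)
})
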