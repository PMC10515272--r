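toy_proteome <- function(lengths) {
  tibble::tibble(
    protein_id = sprintf("P%03d", seq_along(lengths)),
    gene_id = sprintf("P%03d", seq_along(lengths)),
    sequence = vapply(lengths, function(n) strrep("A", n), character(1))
  )
}

test_that("length gate is inclusive on both bounds", {
  prot <- toy_proteome(c(24, 25, 250, 251))
  kept <- filter_length(prot)
  expect_equal(nchar(kept$sequence), c(25, 250))
  expect_equal(nrow(filter_length(toy_proteome(integer(0)))), 0)
  # lengths 10, 20, ..., 300: those in 30..250 survive
  expect_equal(nrow(filter_length(toy_proteome(seq(10, 300, by = 10)))), 23)
  expect_error(filter_length(prot, min_len = 100, max_len = 50), "min_len")
})

test_that("signal-peptide gate sets mature sequences and errors on missing verdicts", {
  prot <- toy_proteome(rep(100, 3))
  verdicts <- tibble::tibble(
    protein_id = c("P001", "P002", "P003"),
    has_signal_peptide = c(TRUE, FALSE, TRUE),
    sp_cleavage_site = c(24L, 0L, 30L)
  )
  out <- filter_signal_peptide(prot, verdicts)
  expect_equal(out$protein_id, c("P001", "P003"))
  expect_equal(nchar(out$mature_sequence), c(76L, 70L))
  expect_error(
    filter_signal_peptide(prot, verdicts[-2, ]),
    "P002"
  )
})

test_that("transmembrane gate removes helix-bearing candidates", {
  cand <- toy_proteome(rep(60, 2))
  verdicts <- tibble::tibble(
    protein_id = c("P001", "P002"), tm_helix_count = c(1L, 0L)
  )
  expect_equal(filter_transmembrane(cand, verdicts)$protein_id, "P002")
})

test_that("ER-retention gate tests only the terminal tetrapeptide", {
  cand <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    sequence = c(
      paste0(strrep("A", 30), "AHDEL"),   # terminal HDEL: removed
      paste0(strrep("A", 30), "KDELS"),   # internal only: kept
      paste0(strrep("A", 30), "GKDEL"),   # terminal KDEL: removed
      strrep("A", 30)
    )
  )
  expect_equal(filter_er_retention(cand)$protein_id, c("b", "d"))
})

test_that("cascade stages are monotone and tallies account for every removal", {
  sim <- simulate_proteome(seed = 11)
  casc <- run_cascade(sim$proteome)
  n <- casc$tally$n
  expect_true(all(diff(n) <= 0))  # survivor sets shrink
  flags <- casc$candidates
  removed <- c(
    sum(!flags$passed_length),
    sum(flags$passed_length & !flags$passed_sp, na.rm = TRUE),
    sum(!is.na(flags$passed_tm) & !flags$passed_tm),
    sum(!is.na(flags$passed_er) & !flags$passed_er)
  )
  expect_equal(n[1] - sum(removed), n[5])
  expect_equal(sum(flags$is_ssp), n[5])
  # is_ssp implies all four gates
  ssp <- dplyr::filter(flags, is_ssp)
  expect_true(all(ssp$passed_length & ssp$passed_sp & ssp$passed_tm &
                    ssp$passed_er))
})

test_that("TM and ER stages commute on the final candidate set", {
  for (seed in c(2, 13, 29)) {
    sim <- simulate_proteome(seed = seed)
    verdicts <- predictor_verdicts(sim$proteome)
    s2 <- filter_signal_peptide(filter_length(sim$proteome), verdicts)
    tm_then_er <- filter_er_retention(filter_transmembrane(s2, verdicts))
    er_then_tm <- filter_transmembrane(filter_er_retention(s2), verdicts)
    expect_setequal(tm_then_er$protein_id, er_then_tm$protein_id)
  }
})

test_that("empty and all-passing proteomes give degenerate tallies", {
  empty <- run_cascade(toy_proteome(integer(0)))
  expect_equal(empty$tally$n, rep(0L, 5))
  sim <- simulate_proteome(
    proteome_config(cep = 5, cle = 0, ralf = 0, pnp = 0, crp6c_i = 0,
                    crp6c_ii = 0, cep_multi = 0, oversize = 0, no_sp = 0,
                    tm = 0, kdel = 0),
    seed = 4
  )
  clean <- run_cascade(sim$proteome)
  expect_equal(clean$tally$n, rep(5L, 5))
})

test_that("glance and tidy expose the cascade results", {
  sim <- simulate_proteome(seed = 5)
  casc <- run_cascade(sim$proteome)
  g <- glance(casc)
  expect_equal(g$n_input, nrow(sim$proteome))
  expect_equal(g$n_ssp, nrow(casc$ssp))
  expect_equal(nrow(tidy(casc)), nrow(sim$proteome))
})
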