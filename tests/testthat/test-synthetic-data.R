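test_that("generators are pure functions of (config, seed)", {
  a <- simulate_proteome(seed = 7)
  b <- simulate_proteome(seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$proteome$sequence,
                         simulate_proteome(seed = 8)$proteome$sequence))

  ga <- simulate_genome(seed = 7)
  gb <- simulate_genome(seed = 7)
  expect_identical(ga, gb)

  ea <- simulate_expression(seed = 7)
  expect_identical(ea, simulate_expression(seed = 7))
  expect_identical(simulate_physiology(seed = 7), simulate_physiology(seed = 7))
})

test_that("zero configuration yields empty outputs", {
  empty <- simulate_proteome(
    proteome_config(cep = 0, cle = 0, ralf = 0, pnp = 0, crp6c_i = 0,
                    crp6c_ii = 0, cep_multi = 0, oversize = 0, undersize = 0,
                    no_sp = 0, tm = 0, kdel = 0),
    seed = 1
  )
  expect_equal(nrow(empty$proteome), 0)
  expect_equal(nrow(empty$manifest), 0)
})

test_that("every planted record appears in exactly one category with unique ids", {
  sim <- simulate_proteome(seed = 3)
  expect_equal(anyDuplicated(sim$manifest$protein_id), 0)
  expect_equal(nrow(sim$proteome), nrow(sim$manifest))
  counts <- dplyr::count(sim$manifest, category)
  cfg <- proteome_config()
  expect_equal(counts$n[counts$category == "cep"], cfg$cep)
  expect_equal(counts$n[counts$category == "decoy_no_sp"], cfg$no_sp)
})

test_that("planted positives pass and decoys fail exactly their target gate", {
  sim <- simulate_proteome(seed = 9)
  prot <- sim$proteome
  man <- sim$manifest
  verdicts <- predictor_verdicts(prot)
  sp <- verdicts$has_signal_peptide
  # all planted SSPs carry the template signal peptide at cleavage 17
  pos <- man$is_ssp
  expect_true(all(sp[pos]))
  expect_true(all(verdicts$sp_cleavage_site[pos] == 17L))
  expect_true(all(verdicts$tm_helix_count[pos] == 0L))
  expect_true(all(nchar(prot$sequence[pos]) >= 25 &
                    nchar(prot$sequence[pos]) <= 250))
  # decoys violate their designated gate
  expect_true(all(nchar(prot$sequence[man$category == "decoy_oversize"]) > 250))
  expect_true(all(!sp[man$category == "decoy_no_sp"]))
  expect_true(all(verdicts$tm_helix_count[man$category == "decoy_tm"] >= 1))
  kdel_tails <- substring(
    prot$sequence[man$category == "decoy_kdel"],
    nchar(prot$sequence[man$category == "decoy_kdel"]) - 3
  )
  expect_true(all(kdel_tails %in% c("KDEL", "HDEL")))
})

test_that("planted cysteine architectures match their manifest gap vectors", {
  sim <- simulate_proteome(seed = 13)
  crp <- dplyr::filter(sim$manifest, category %in% c("crp6c_i", "crp6c_ii"))
  mature <- substring(
    sim$proteome$sequence[match(crp$protein_id, sim$proteome$protein_id)],
    crp$sp_cleavage_site + 1
  )
  for (i in seq_len(nrow(crp))) {
    cpos <- which(strsplit(mature[i], "")[[1]] == "C")
    expect_equal(as.integer(diff(cpos) - 1), crp$gap_vector[[i]])
  }
})

test_that("synthetic genomes contain no start codons outside planted cassettes", {
  g <- simulate_genome(seed = 29)
  for (chrom in names(g$genome)) {
    s <- g$genome[[chrom]]
    man <- dplyr::filter(g$manifest, chrom == !!chrom)
    inside <- function(p) {
      any(p > man$start & p + 2 <= man$end)  # 1-based trigram within a cassette
    }
    atg <- as.integer(gregexpr("ATG", s)[[1]])
    cat_ <- as.integer(gregexpr("CAT", s)[[1]])
    for (p in atg[atg > 0]) expect_true(inside(p))
    for (p in cat_[cat_ > 0]) expect_true(inside(p))
  }
})

test_that("planted expression effects sit inside the declared bands", {
  sim <- simulate_expression(seed = 37)
  mat <- sim$matrix
  lfc <- log2(mat$fpkm_ds_d1 / mat$fpkm_ck)
  up <- sim$manifest$direction == "up"
  dn <- sim$manifest$direction == "down"
  expect_true(all(abs(lfc[up] - 2) <= 0.25))
  expect_true(all(abs(lfc[dn] + 2) <= 0.25))
  expect_true(all(mat$q_ds_d1[up | dn] <= 0.005))
  expect_true(all(mat$q_ds_d1[!(up | dn)] >= 0.2))
})
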