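test_that("non-coding segment extraction complements the CDS mask", {
  genome <- c(chrA = random_dna(1000))
  feats <- tibble::tibble(
    chrom = "chrA", start = 101L, end = 200L, strand = "+", type = "CDS"
  )
  seg <- extract_ncds(genome, feats)
  expect_equal(seg$start, c(0L, 200L))
  expect_equal(seg$end, c(100L, 1000L))
  expect_equal(seg$sequence[1], unname(substring(genome, 1, 100)))

  # no features: one full-length segment
  seg0 <- extract_ncds(genome, feats[0, ])
  expect_equal(nrow(seg0), 1)
  expect_equal(c(seg0$start, seg0$end), c(0L, 1000L))

  # adjacent CDS features merge into one mask
  feats2 <- tibble::tibble(
    chrom = "chrA", start = c(101L, 201L), end = c(200L, 300L),
    strand = "+", type = "CDS"
  )
  seg2 <- extract_ncds(genome, feats2)
  expect_equal(seg2$start, c(0L, 300L))

  # non-CDS features are not masked by default
  feats3 <- dplyr::mutate(feats, type = "exon")
  expect_equal(nrow(extract_ncds(genome, feats3)), 1)

  expect_error(
    extract_ncds(genome, dplyr::mutate(feats, end = 2000L)),
    "bounds"
  )
})

test_that("sORF boundaries respect the peptide length gates", {
  # ATG + 24 non-stop codons + TAA encodes a 25-aa peptide
  s <- paste0("ATG", strrep("GCC", 24), "TAA")
  orfs <- find_sorfs(s, min_aa = 25)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$length_aa, 25)
  expect_equal(orfs$peptide, paste0("M", strrep("A", 24)))
  expect_equal(c(orfs$start, orfs$end), c(0, 78))  # includes the stop codon
  expect_equal(nrow(find_sorfs(s, min_aa = 26)), 0)
  # without an in-frame stop the ORF is dropped by default
  expect_equal(nrow(find_sorfs(paste0("ATG", strrep("GCC", 30)))), 0)
  expect_equal(
    find_sorfs(paste0("ATG", strrep("GCC", 30)), require_stop = FALSE)$length_aa,
    31  # M plus 30 alanines, truncated by the segment end
  )
  # a codon containing N aborts the ORF
  withN <- paste0("ATG", strrep("GCC", 10), "GNC", strrep("GCC", 20), "TAA")
  expect_equal(nrow(find_sorfs(withN, min_aa = 5)), 0)
})

test_that("six-frame scanner equals the brute-force oracle on random DNA", {
  withr::with_seed(202, {
    for (i in seq_len(12)) {
      s <- random_dna(sample(200:1500, 1), p_n = 0.01)
      got <- find_sorfs(s, min_aa = 5, max_aa = 250)
      want <- oracle_orfs(s, min_aa = 5, max_aa = 250)
      expect_equal(orf_key(got), orf_key(want), info = paste("iter", i))
    }
  })
})

test_that("mining a sequence and its reverse complement mirrors coordinates", {
  withr::with_seed(303, {
    s <- random_dna(1200)
    L <- nchar(s)
    fwd <- find_sorfs(s, min_aa = 5, max_aa = 250)
    rev <- find_sorfs(oracle_revcomp(s), min_aa = 5, max_aa = 250)
    mirrored <- data.frame(
      start = L - rev$end, end = L - rev$start,
      strand = ifelse(rev$strand == "+", "-", "+"),
      peptide = rev$peptide
    )
    key <- function(d) sort(paste(d$start, d$end, d$strand, d$peptide))
    expect_equal(key(fwd), key(mirrored))
  })
})

test_that("nested in-frame ORFs collapse to the longest per stop", {
  # two ATGs sharing one stop, same frame
  s <- paste0("ATG", strrep("GCC", 5), "ATG", strrep("GCC", 30), "TAA")
  orfs <- find_sorfs(s, min_aa = 5, max_aa = 250)
  expect_equal(nrow(orfs), 2)
  kept <- eliminate_nested_orfs(orfs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$length_aa, max(orfs$length_aa))  # most upstream ATG
  # unique (chrom, strand, stop) keys after elimination
  stop_key <- ifelse(kept$strand == "+", kept$end, kept$start)
  expect_equal(anyDuplicated(paste(kept$chrom, kept$strand, stop_key)), 0)
  # ORFs with distinct stops are all kept
  s2 <- paste0("ATG", strrep("GCC", 10), "TAA", "ATG", strrep("GCC", 12), "TAA")
  orfs2 <- find_sorfs(s2, min_aa = 5, max_aa = 250)
  fwd2 <- dplyr::filter(orfs2, strand == "+")
  expect_equal(nrow(eliminate_nested_orfs(fwd2)), nrow(fwd2))
})

test_that("reported intervals re-translate to the stored peptide", {
  g <- simulate_genome(seed = 17)
  mined <- mine_secreted_sorfs(g$genome, g$features)
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(mined$orfs))) {
    o <- mined$orfs[i, ]
    nt <- substring(g$genome[[o$chrom]], o$start + 1, o$end)
    if (o$strand == "-") nt <- oracle_revcomp(nt)
    starts <- seq(1, nchar(nt) - 3, by = 3)
    aa <- paste(code[substring(nt, starts, starts + 2)], collapse = "")
    expect_equal(aa, o$peptide)
    expect_equal(code[[substring(nt, nchar(nt) - 2)]], "*")
  }
})

test_that("genome mining recovers the planted manifest exactly", {
  g <- simulate_genome(seed = 23)
  mined <- mine_secreted_sorfs(g$genome, g$features)
  truth <- dplyr::filter(g$manifest, survives_nesting)
  key <- function(d) sort(paste(d$chrom, d$start, d$end, d$strand))
  expect_equal(key(mined$orfs), key(truth))
  secreted <- dplyr::filter(g$manifest, category == "secreted")
  expect_equal(key(mined$ssp), key(secreted))
  expect_setequal(mined$ssp$sequence, secreted$peptide)
  # per-chromosome tally is internally consistent
  expect_equal(sum(mined$per_chromosome$n_ssp), nrow(secreted))
  expect_equal(sum(mined$per_chromosome$n_sorf), nrow(mined$orfs))
})

test_that("fully coding or overlapping regions yield no sORFs", {
  g <- c(chrA = paste0("TTTT", "ATG", strrep("GCC", 30), "TAA", "TTTT"))
  len <- nchar(g[[1]])
  all_cds <- tibble::tibble(
    chrom = "chrA", start = 1L, end = len, strand = "+", type = "CDS"
  )
  mined <- mine_secreted_sorfs(g, all_cds)
  expect_equal(nrow(mined$orfs), 0)
  # planted ORF overlapping a CDS by 1 nt is excluded from the search space
  one_overlap <- tibble::tibble(
    chrom = "chrA", start = 1L, end = 5L, strand = "+", type = "CDS"
  )  # overlaps the ATG's first base
  mined2 <- mine_secreted_sorfs(g, one_overlap, min_aa = 5)
  expect_false(any(mined2$orfs$start == 4))
})
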