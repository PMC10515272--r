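# Ground-truth synthetic data generators. Every generator is a pure
# function of (config, seed): reruns are identical. Planted positives are
# constructed so the built-in heuristic predictors provably accept them,
# and every decoy provably violates exactly the gate it targets, so
# pipeline recovery of the manifest is exact, not probabilistic.

# Hydrophilic residues (all Kyte-Doolittle < 0) used for random filler:
# no C (cysteine counts stay planted), no P/V/I/L/F/M/R/H/W/Y (no
# accidental family motifs, TM windows or signal peptides).
SAFE_AA <- c("D", "E", "G", "K", "N", "Q", "S", "T")

# Signal-peptide template co-designed with predict_signal_peptide():
# charged n-region (K2), hydrophobic core, A-X-A cleavage context; the
# heuristic reports cleavage after residue 17.
SP_TEMPLATE <- "MKTNLFLVLLLAGSALA"
SP_CLEAVAGE <- 17L

random_safe <- function(n) {
  paste(sample(SAFE_AA, n, replace = TRUE), collapse = "")
}

# Bounded template mutation that preserves heuristic detection: position 6
# varies over strongly hydrophobic residues (unit-tested against the
# heuristic).
sp_variant <- function() {
  s <- chars(SP_TEMPLATE)
  s[6] <- sample(c("F", "L", "I", "V"), 1)
  paste(s, collapse = "")
}

# Cysteine block with the given gap vector, flanked by safe filler.
cys_block_mature <- function(gaps, prefix_len, suffix_len) {
  paste0(
    random_safe(prefix_len),
    paste0("C", vapply(gaps, random_safe, character(1)), collapse = ""),
    "C", random_safe(suffix_len)
  )
}

CEP_DOMAIN_A <- "YLGIKNSGPSPGEGH"
CEP_DOMAIN_B <- "TLGGIKAGPSPGEGH"
CLE_BOX <- "RTVPSGPDPLHH"

#' Synthetic proteome configuration
#'
#' Planted counts per category for [simulate_proteome()]. Positives cover
#' the representative families with shipped motif rules (CEP, CLE, RALF,
#' PNP) and the two novel cysteine-spacing archetypes; decoys each provably
#' violate exactly one cascade gate. The defaults plant 40 true SSPs and
#' 50 decoys (15 oversize, 20 without signal peptide, 10 with a
#' transmembrane helix, 5 ER-retained).
#'
#' @param cep,cle,ralf,pnp,crp6c_i,crp6c_ii True-SSP counts per family.
#' @param cep_multi How many of the CEP precursors carry two CEP domains.
#' @param oversize,undersize,no_sp,tm,kdel Decoy counts.
#' @return A named list.
#' @export
proteome_config <- function(cep = 8, cle = 8, ralf = 8, pnp = 8,
                            crp6c_i = 4, crp6c_ii = 4, cep_multi = 2,
                            oversize = 15, undersize = 0, no_sp = 20,
                            tm = 10, kdel = 5) {
  as.list(environment())
}

# Gap vectors of the two planted spacing archetypes. The variable position
# cycles through a fixed value set so small member counts still exhibit the
# full spread; the range position of archetype II cycles over 4-6.
crp6c_i_gaps <- function(j) {
  v <- c(6L, 14L, 10L)[(j - 1L) %% 3L + 1L]
  c(3L, 5L, 5L, 2L, v)
}
crp6c_ii_gaps <- function(j) {
  v <- c(8L, 16L, 12L)[(j - 1L) %% 3L + 1L]
  p <- 4L + (j - 1L) %% 3L
  c(5L, v, 6L, p, 1L)
}

#' Generate a synthetic proteome with planted SSPs and decoys
#'
#' Emits a proteome tibble plus a manifest of per-record ground truth. All
#' randomness is governed by `seed`; reruns are identical.
#'
#' @param config A [proteome_config()] list.
#' @param seed Integer seed.
#' @return A list with `proteome` (columns `protein_id`, `gene_id`,
#'   `sequence`, `description`) and `manifest` (per-record `category`,
#'   `family`, `is_ssp`, planted `sp_cleavage_site`, `n_domains`, and the
#'   planted cysteine `gap_vector` list-column for the novel-family
#'   archetypes).
#' @export
#' @examples
#' sim <- simulate_proteome(proteome_config(cep = 2, tm = 1), seed = 1)
#' sim$manifest
simulate_proteome <- function(config = proteome_config(), seed) {
  with_seed(seed, {
    rows <- list()
    add <- function(prefix, j, category, mature, family = NA_character_,
                    has_sp = TRUE, is_ssp = TRUE, n_domains = NA_integer_,
                    gap_vector = NULL, full_override = NULL) {
      sequence <- full_override %||% paste0(sp_variant(), mature)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        protein_id = sprintf("%s%03d.1", prefix, j),
        gene_id = sprintf("%s%03d", prefix, j),
        sequence = sequence,
        description = paste("synthetic", category),
        category = category,
        family = family,
        is_ssp = is_ssp,
        sp_cleavage_site = if (has_sp) SP_CLEAVAGE else 0L,
        n_domains = n_domains,
        gap_vector = list(gap_vector)
      )
    }
    for (j in seq_len(config$cep)) {
      two <- j <= config$cep_multi
      mature <- paste0(
        random_safe(sample(20:40, 1)), CEP_DOMAIN_A,
        if (two) paste0(random_safe(8), CEP_DOMAIN_B) else ""
      )
      add("CEP", j, "cep", mature, "CEP", n_domains = if (two) 2L else 1L)
    }
    for (j in seq_len(config$cle)) {
      add("CLE", j, "cle", paste0(random_safe(sample(30:60, 1)), CLE_BOX),
          "CLE", n_domains = 1L)
    }
    for (j in seq_len(config$ralf)) {
      mature <- paste0(
        random_safe(5), "RR", random_safe(6),
        "C", random_safe(4), "C", random_safe(7), "C", random_safe(3), "C",
        random_safe(5)
      )
      add("RALF", j, "ralf", mature, "RALF", n_domains = 1L)
    }
    for (j in seq_len(config$pnp)) {
      mature <- paste0(
        random_safe(8), "KVVD", random_safe(6), "LSTNAFQQIA", random_safe(8)
      )
      add("PNP", j, "pnp", mature, "PNP", n_domains = 1L)
    }
    for (j in seq_len(config$crp6c_i)) {
      g <- crp6c_i_gaps(j)
      add("CRPI", j, "crp6c_i",
          cys_block_mature(g, sample(6:12, 1), sample(3:6, 1)),
          gap_vector = g)
    }
    for (j in seq_len(config$crp6c_ii)) {
      g <- crp6c_ii_gaps(j)
      add("CRPII", j, "crp6c_ii",
          cys_block_mature(g, sample(6:12, 1), sample(3:6, 1)),
          gap_vector = g)
    }
    for (j in seq_len(config$oversize)) {
      add("OVR", j, "decoy_oversize", random_safe(250), is_ssp = FALSE)
    }
    for (j in seq_len(config$undersize)) {
      add("UND", j, "decoy_undersize", NULL, is_ssp = FALSE, has_sp = FALSE,
          full_override = paste0("M", random_safe(15)))
    }
    for (j in seq_len(config$no_sp)) {
      add("NOSP", j, "decoy_no_sp", NULL, is_ssp = FALSE, has_sp = FALSE,
          full_override = paste0("M", random_safe(sample(30:60, 1))))
    }
    for (j in seq_len(config$tm)) {
      mature <- paste0(random_safe(10), strrep("L", 19), random_safe(10))
      add("TMD", j, "decoy_tm", mature, is_ssp = FALSE)
    }
    for (j in seq_len(config$kdel)) {
      mature <- paste0(random_safe(sample(20:30, 1)),
                       sample(c("KDEL", "HDEL"), 1))
      add("KDEL", j, "decoy_kdel", mature, is_ssp = FALSE)
    }
    manifest <- dplyr::bind_rows(rows)
    if (nrow(manifest) == 0) {
      manifest <- tibble::tibble(
        protein_id = character(), gene_id = character(),
        sequence = character(), description = character(),
        category = character(), family = character(), is_ssp = logical(),
        sp_cleavage_site = integer(), n_domains = integer(),
        gap_vector = list()
      )
    }
    list(
      proteome = manifest[, c("protein_id", "gene_id", "sequence",
                              "description")],
      manifest = manifest[, c("protein_id", "gene_id", "category", "family",
                              "is_ssp", "sp_cleavage_site", "n_domains",
                              "gap_vector")]
    )
  })
}

# ---- genome generator ------------------------------------------------------

# Fixed back-translation codon table. No codon ends in A (no cross-junction
# ATG via ...A|TG) and no codon ends in AT; start codons are the only
# in-frame ATGs. H is CAC; sequences fed to the generator never place H
# before I/M, the one junction the table cannot encode without creating CAT
# (a reverse-strand start codon).
CODON_TABLE <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCG", Q = "CAG", R = "CGG", S = "TCC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC"
)

# Back-translate a peptide and append a TAA stop. Junctions that would
# create CAT (codon ending C before a codon starting AT) are repaired by
# the synonymous third-base C->T swap.
back_translate_cassette <- function(peptide) {
  codons <- unname(CODON_TABLE[chars(peptide)])
  if (anyNA(codons)) {
    rlang::abort("Peptide contains residues outside the codon table.")
  }
  for (j in seq_along(codons)[-1]) {
    if (substring(codons[j - 1], 3, 3) == "C" &&
        substring(codons[j], 1, 2) == "AT") {
      if (codons[j - 1] == "CAC") {
        rlang::abort("Cannot encode H immediately before I/M without CAT.")
      }
      codons[j - 1] <- paste0(substring(codons[j - 1], 1, 2), "T")
    }
  }
  cassette <- paste0(paste(codons, collapse = ""), "TAA")
  if (grepl("CAT", cassette, fixed = TRUE)) {
    rlang::abort("Internal error: cassette contains CAT.")
  }
  cassette
}

# Random GC-0.38 background purged of ATG and CAT (forward and reverse
# start codons), wrapped in TT so cassette junctions cannot recreate them.
neutral_dna <- function(n) {
  s <- paste0("TT", paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c(0.31, 0.19, 0.19, 0.31)),
    collapse = ""
  ), "TT")
  # Purge after wrapping so the T borders cannot recreate a start codon at
  # either junction; the replacements never touch the border Ts.
  repeat {
    m <- regexpr("ATG|CAT", s)
    if (m == -1) break
    hit <- substring(s, m, m + 2)
    fix <- if (hit == "ATG") "ACG" else "CGT"
    s <- paste0(substring(s, 1, m - 1), fix, substring(s, m + 3))
  }
  s
}

#' Synthetic genome configuration
#'
#' @param n_secreted Planted intergenic sORF cassettes encoding a signal
#'   peptide (true secreted sORFs).
#' @param n_nonsp Planted sORF cassettes without a signal peptide.
#' @param n_nested_pairs Planted nested pairs (two in-frame ATGs sharing a
#'   stop) exercising nested-ORF elimination.
#' @param n_decoy_cds Annotated decoy CDS features masked from the search
#'   space.
#' @param n_chromosomes Number of chromosomes the cassettes are spread over.
#' @param chrom_length Optional fixed chromosome length; assembled content
#'   exceeding it is an error, shorter content is padded.
#' @return A named list.
#' @export
genome_config <- function(n_secreted = 12, n_nonsp = 8, n_nested_pairs = 2,
                          n_decoy_cds = 3, n_chromosomes = 2,
                          chrom_length = NULL) {
  as.list(environment())
}

#' Generate a synthetic genome with planted intergenic sORFs
#'
#' Builds chromosome sequences by concatenating neutral background (random
#' GC-0.38 DNA containing no start codon on either strand), annotated decoy
#' CDS blocks, and planted ORF cassettes (ATG + codons + TAA) separated by
#' >= 50 nt of background. Because the background and cassette encoding are
#' start-codon-free outside the planted starts, the planted cassettes are
#' provably the only ORFs in the genome and manifest recovery by
#' [mine_secreted_sorfs()] is exact.
#'
#' @param config A [genome_config()] list.
#' @param seed Integer seed.
#' @return A list with `genome` (named character vector), `features`
#'   (CDS feature tibble, 1-based inclusive) and `manifest` (planted ORFs:
#'   `category`, `chrom`, 0-based half-open `start`/`end` including the
#'   stop codon, `strand`, `peptide`, and `survives_nesting`).
#' @export
simulate_genome <- function(config = genome_config(), seed) {
  with_seed(seed, {
    plan <- c(
      rep("secreted", config$n_secreted),
      rep("nonsp", config$n_nonsp),
      rep("nested", config$n_nested_pairs),
      rep("cds", config$n_decoy_cds)
    )
    plan <- sample(plan)
    chrom_of <- rep_len(seq_len(config$n_chromosomes), length(plan))
    chroms <- stats::setNames(
      vector("list", config$n_chromosomes),
      sprintf("chr%02d", seq_len(config$n_chromosomes))
    )
    seqs <- character(config$n_chromosomes)
    features <- list()
    manifest <- list()
    strand_toggle <- TRUE
    for (ci in seq_len(config$n_chromosomes)) {
      parts <- neutral_dna(sample(60:150, 1))
      offset <- nchar(parts)
      items <- plan[chrom_of == ci]
      for (item in items) {
        if (item == "cds") {
          block <- neutral_dna(300)
          features[[length(features) + 1L]] <- tibble::tibble(
            chrom = names(chroms)[ci], start = offset + 1L,
            end = offset + nchar(block), strand = "+", type = "CDS"
          )
          parts <- paste0(parts, block)
          offset <- offset + nchar(block)
        } else {
          strand_toggle <- !strand_toggle
          strand <- if (strand_toggle) "+" else "-"
          if (item == "secreted") {
            peptide <- paste0(sp_variant(), random_safe(sample(10:40, 1)))
            nested_peptides <- NULL
          } else if (item == "nonsp") {
            peptide <- paste0("M", random_safe(sample(25:40, 1)))
            nested_peptides <- NULL
          } else {
            inner <- paste0("M", random_safe(30))
            peptide <- paste0("M", random_safe(10), inner)
            nested_peptides <- inner
          }
          cassette <- back_translate_cassette(peptide)
          nt <- if (strand == "+") cassette else revcomp(cassette)
          len <- nchar(cassette)
          manifest[[length(manifest) + 1L]] <- tibble::tibble(
            category = item, chrom = names(chroms)[ci],
            start = offset, end = offset + len, strand = strand,
            peptide = peptide, length_aa = nchar(peptide),
            survives_nesting = TRUE
          )
          if (!is.null(nested_peptides)) {
            inner_off <- 3L * (nchar(peptide) - nchar(nested_peptides))
            istart <- if (strand == "+") offset + inner_off else offset
            iend <- if (strand == "+") offset + len else offset + len - inner_off
            manifest[[length(manifest) + 1L]] <- tibble::tibble(
              category = "nested_inner", chrom = names(chroms)[ci],
              start = istart, end = iend, strand = strand,
              peptide = nested_peptides,
              length_aa = nchar(nested_peptides),
              survives_nesting = FALSE
            )
          }
          parts <- paste0(parts, nt)
          offset <- offset + len
        }
        spacer <- neutral_dna(sample(60:150, 1))
        parts <- paste0(parts, spacer)
        offset <- offset + nchar(spacer)
      }
      if (!is.null(config$chrom_length)) {
        if (offset > config$chrom_length) {
          rlang::abort(sprintf(
            "Planted cassettes exceed chrom_length on %s (%d > %d nt).",
            names(chroms)[ci], offset, config$chrom_length
          ))
        }
        if (offset < config$chrom_length) {
          pad_n <- config$chrom_length - offset
          pad <- if (pad_n >= 10) neutral_dna(pad_n - 4L) else strrep("T", pad_n)
          parts <- substring(paste0(parts, pad), 1, config$chrom_length)
        }
      }
      seqs[ci] <- parts
    }
    names(seqs) <- names(chroms)
    features <- if (length(features) > 0) {
      dplyr::bind_rows(features)
    } else {
      tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        strand = character(), type = character()
      )
    }
    manifest <- if (length(manifest) > 0) {
      dplyr::bind_rows(manifest)
    } else {
      tibble::tibble(
        category = character(), chrom = character(), start = integer(),
        end = integer(), strand = character(), peptide = character(),
        length_aa = integer(), survives_nesting = logical()
      )
    }
    list(genome = seqs, features = features, manifest = manifest)
  })
}

# ---- expression / physiology generators ------------------------------------

#' Generate a drought time-course expression matrix with planted effects
#'
#' Null genes carry log-normal expression noise with q-values drawn at or
#' above 0.2; planted genes have `|log2FC| = effect_lfc +- 0.25` and
#' q-values at or below 0.005 at every time point, so threshold DE calling
#' recovers the planted counts exactly.
#'
#' @param n_up,n_down,n_null Gene counts per category.
#' @param timepoints Treated time-point labels (columns `fpkm_<tp>` /
#'   `q_<tp>` are emitted per label).
#' @param effect_lfc Planted absolute log2 fold change.
#' @param seed Integer seed.
#' @return A list with `matrix` (wide tibble: `gene_id`, `fpkm_ck`, then
#'   per-time-point FPKM and q columns) and `manifest` (`gene_id`,
#'   `direction`).
#' @export
simulate_expression <- function(n_up = 30, n_down = 20, n_null = 50,
                                timepoints = paste0("ds_d", 1:5),
                                effect_lfc = 2, seed) {
  with_seed(seed, {
    n <- n_up + n_down + n_null
    direction <- c(rep("up", n_up), rep("down", n_down), rep("ns", n_null))
    gene_id <- sprintf("GENE%04d", seq_len(n))
    ck <- stats::rlnorm(n, meanlog = log(20), sdlog = 0.6)
    mat <- tibble::tibble(gene_id = gene_id, fpkm_ck = ck)
    for (tp in timepoints) {
      lfc <- dplyr::case_when(
        direction == "up" ~ effect_lfc + stats::runif(n, -0.25, 0.25),
        direction == "down" ~ -effect_lfc + stats::runif(n, -0.25, 0.25),
        TRUE ~ stats::runif(n, -0.2, 0.2)
      )
      q <- ifelse(direction == "ns",
        stats::runif(n, 0.2, 1), stats::runif(n, 1e-6, 0.005)
      )
      mat[[paste0("fpkm_", tp)]] <- ck * 2^lfc
      mat[[paste0("q_", tp)]] <- q
    }
    list(
      matrix = mat,
      manifest = tibble::tibble(gene_id = gene_id, direction = direction)
    )
  })
}

#' Generate a drought physiology sample table with planted group effects
#'
#' Emulates the leaf measurements of a drought/peptide-rescue experiment:
#' four treatment groups (well-watered, drought, drought plus each of two
#' peptide treatments) with group-level RWC, REC and MDA targets and small
#' within-group noise. The raw columns feed [compute_physiology()] and
#' [group_compare()].
#'
#' @param n_per_group Samples per treatment group.
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, `treatment` and the raw measurement
#'   columns (`fw`, `sw`, `dw`, `k1`, `k2`, `a532`, `a600`, `vr`, `wt`,
#'   `vt`, `v`).
#' @export
simulate_physiology <- function(n_per_group = 15, seed) {
  with_seed(seed, {
    targets <- tibble::tribble(
      ~treatment, ~rwc, ~rec, ~a_diff,
      "well_watered", 92, 15, 0.03,
      "drought", 55, 65, 0.16,
      "drought_cep10", 75, 40, 0.09,
      "drought_cep11b", 73, 42, 0.09
    )
    purrr::pmap(targets, function(treatment, rwc, rec, a_diff) {
      dw <- stats::runif(n_per_group, 0.45, 0.55)
      sw <- dw + stats::runif(n_per_group, 1.8, 2.2)
      fw <- dw + (sw - dw) * pmin(pmax(
        rwc / 100 + stats::rnorm(n_per_group, 0, 0.02), 0.01
      ), 1)
      k2 <- stats::runif(n_per_group, 1.0, 1.4)
      k1 <- k2 * pmin(pmax(
        rec / 100 + stats::rnorm(n_per_group, 0, 0.02), 0.001
      ), 1)
      a600 <- stats::runif(n_per_group, 0.01, 0.03)
      a532 <- a600 + pmax(a_diff + stats::rnorm(n_per_group, 0, 0.008), 0.001)
      tibble::tibble(
        sample_id = sprintf("%s_%02d", treatment, seq_len(n_per_group)),
        treatment = treatment, fw = fw, sw = sw, dw = dw, k1 = k1, k2 = k2,
        a532 = a532, a600 = a600, vr = 4, wt = 0.3, vt = 1, v = 3
      )
    }) %>% dplyr::bind_rows()
  })
}
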