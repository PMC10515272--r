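# Independent oracles used to cross-check the package's scanners. They are
# deliberately written with different algorithms from the implementation:
# the ORF oracle walks every (position, strand) pair codon by codon, and the
# cysteine-pattern oracle compiles the pattern to a PCRE regular expression.

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Brute-force six-frame ORF enumerator: for every position on each strand,
# if an ATG starts there, walk codons until a stop (record) or an
# N-containing codon / sequence end (discard).
oracle_orfs <- function(sequence, chrom = "seg", seg_start = 0,
                        min_aa = 25, max_aa = 250) {
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else oracle_revcomp(sequence)
    L <- nchar(s)
    p <- 1L
    while (p + 2L <= L) {
      if (substring(s, p, p + 2L) == "ATG") {
        k <- p
        n_aa <- 0L
        found_stop <- FALSE
        while (k + 2L <= L) {
          aa <- code[substring(s, k, k + 2L)]
          if (is.na(aa)) break
          if (aa == "*") {
            found_stop <- TRUE
            break
          }
          n_aa <- n_aa + 1L
          k <- k + 3L
        }
        if (found_stop && n_aa >= min_aa && n_aa <= max_aa) {
          a0 <- p - 1L
          b0 <- k + 2L
          pep <- paste(
            code[substring(s, seq(p, k - 3L, by = 3L),
                           seq(p, k - 3L, by = 3L) + 2L)],
            collapse = ""
          )
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom,
            start = if (strand == "+") seg_start + a0 else seg_start + L - b0,
            end = if (strand == "+") seg_start + b0 else seg_start + L - a0,
            strand = strand,
            length_aa = n_aa,
            peptide = pep
          )
        }
      }
      p <- p + 1L
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), length_aa = integer(), peptide = character()
    ))
  }
  do.call(rbind, out)
}

orf_key <- function(d) {
  sort(paste(d$chrom, d$start, d$end, d$strand, d$peptide))
}

# Regex oracle for cysteine-spacing patterns: gaps become [^C]{k},
# [^C]{a,b} or [^C]* blocks.
oracle_cys_regex <- function(pattern) {
  parts <- vapply(pattern$gaps, function(g) {
    switch(g$type,
      exact = sprintf("[^C]{%d}", g$k),
      range = sprintf("[^C]{%d,%d}", g$a, g$b),
      variable = "[^C]*"
    )
  }, character(1))
  paste0("C", paste0(parts, "C", collapse = ""))
}

oracle_cys_matches <- function(pattern, sequence) {
  rx <- oracle_cys_regex(pattern)
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + attr(m, "match.length")
  )
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "G", "K")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
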