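# Unannotated sORF mining: extract non-coding sequence (genome minus
# annotated CDS), six-frame translate, enumerate ATG-to-stop ORFs of
# 25-250 codons, drop nested in-frame ORFs sharing a stop, then run the SSP
# cascade on the encoded peptides.
#
# Coordinate conventions: GFF3 input/output is 1-based inclusive; all
# internal interval arithmetic is 0-based half-open; conversion happens only
# in the readers/writers. An ORF's genomic interval covers the start codon
# through the stop codon inclusive (the peptide excludes the stop).

#' Read a genome FASTA into a named character vector
#'
#' @param path Path to a (multi-)FASTA of chromosome sequences.
#' @return A named character vector, chromosome id -> uppercase DNA string.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Read genome annotation features from GFF3
#'
#' @param path Path to a GFF3 file.
#' @return A tibble of features with `chrom`, `start`, `end` (1-based
#'   inclusive, as in GFF3), `strand` and `type`.
#' @export
read_genome_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type)
  )
}

#' Extract non-coding segments of a genome
#'
#' Complements the (strand-ignored) union of masked feature intervals per
#' chromosome and returns the maximal non-coding segments with their
#' sequence. By default only CDS features are masked, so UTRs and introns
#' remain searchable.
#'
#' @param genome Named character vector of chromosome sequences (see
#'   [read_genome_fasta()]).
#' @param features Feature tibble (see [read_genome_annotation()]) with
#'   1-based inclusive `start`/`end`.
#' @param mask_feature_types Feature types removed from the search space.
#' @param min_segment Minimum segment length (nt) retained; pass 78 (the
#'   smallest 25-codon ORF plus stop) to skip segments that cannot hold an
#'   ORF.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   `sequence`.
#' @export
extract_ncds <- function(genome, features, mask_feature_types = "CDS",
                         min_segment = 1) {
  check_columns(features, c("chrom", "start", "end", "type"), "features")
  purrr::imap(genome, function(seq, chrom) {
    len <- nchar(seq)
    f <- features[features$chrom == chrom &
                    features$type %in% mask_feature_types, , drop = FALSE]
    if (nrow(f) > 0 && (any(f$start < 1) || any(f$end > len) ||
                          any(f$start > f$end))) {
      rlang::abort(sprintf(
        "Feature outside chromosome bounds on '%s' (length %d).", chrom, len
      ))
    }
    mask <- IRanges::reduce(IRanges::IRanges(f$start, f$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1, len), mask)
    if (length(gaps) == 0) {
      return(tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        sequence = character()
      ))
    }
    tibble::tibble(
      chrom = chrom,
      start = BiocGenerics::start(gaps) - 1L,
      end = BiocGenerics::end(gaps),
      sequence = substring(seq, BiocGenerics::start(gaps),
                           BiocGenerics::end(gaps))
    )
  }) %>%
    dplyr::bind_rows() %>%
    dplyr::filter(.data$end - .data$start >= min_segment)
}

# Scan one strand of one segment in all three frames.
scan_strand <- function(s, chrom, seg_start, seg_len, strand, min_aa, max_aa,
                        require_stop) {
  n <- nchar(s)
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < 1) next
    starts_nt <- f + 3 * (seq_len(ncod) - 1) + 1
    codons <- substring(s, starts_nt, starts_nt + 2)
    aa <- unname(code[codons])  # NA for codons containing N
    is_stop <- !is.na(aa) & aa == "*"
    is_na <- is.na(aa)
    is_start <- codons == "ATG"
    breaks <- sort(c(which(is_stop | is_na), ncod + 1L))
    start_idx <- which(is_start)
    if (length(start_idx) == 0) next
    nb <- findInterval(start_idx, breaks) + 1L
    for (j in seq_along(start_idx)) {
      si <- start_idx[j]
      b <- breaks[nb[j]]
      len_aa <- b - si
      if (len_aa < min_aa || len_aa > max_aa) next
      has_stop <- b <= ncod && is_stop[b]
      if (b <= ncod && is_na[b]) next  # N codon aborts the ORF
      if (!has_stop && require_stop) next
      span_cod <- if (has_stop) len_aa + 1L else len_aa
      a0 <- f + 3L * (si - 1L)          # 0-based within scanned strand
      b0 <- a0 + 3L * span_cod
      if (strand == "+") {
        gstart <- seg_start + a0
        gend <- seg_start + b0
      } else {
        gstart <- seg_start + seg_len - b0
        gend <- seg_start + seg_len - a0
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, start = gstart, end = gend, strand = strand,
        frame = f, length_aa = len_aa,
        peptide = paste(aa[si:(b - 1L)], collapse = ""),
        has_stop = has_stop
      )
    }
  }
  out
}

#' Find small ORFs by six-frame translation
#'
#' Enumerates every ATG-to-stop open reading frame in the three forward and
#' three reverse-complement frames of each non-coding segment, keeping those
#' whose peptide length (excluding the stop) lies in `[min_aa, max_aa]`.
#' Codons containing `N` are non-translatable and abort the ORF spanning
#' them. Coordinates are forward-strand 0-based half-open and include the
#' stop codon.
#'
#' @param segments Segment tibble from [extract_ncds()] (columns `chrom`,
#'   `start`, `end`, `sequence`), or a single DNA string.
#' @param min_aa,max_aa Peptide length bounds in residues.
#' @param require_stop Drop ORFs truncated by the segment end (default).
#' @return A tibble with `chrom`, `start`, `end`, `strand`, `frame` (0--2
#'   within the segment on the scanned strand), `length_aa`, `peptide`,
#'   `has_stop`.
#' @export
find_sorfs <- function(segments, min_aa = 25, max_aa = 250,
                       require_stop = TRUE) {
  if (is.character(segments)) {
    segments <- tibble::tibble(
      chrom = "seg", start = 0L, end = nchar(segments), sequence = segments
    )
  }
  check_columns(segments, c("chrom", "start", "sequence"), "segments")
  rows <- purrr::pmap(
    segments[, c("chrom", "start", "sequence")],
    function(chrom, start, sequence) {
      s <- toupper(sequence)
      L <- nchar(s)
      c(
        scan_strand(s, chrom, start, L, "+", min_aa, max_aa, require_stop),
        scan_strand(revcomp(s), chrom, start, L, "-", min_aa, max_aa,
                    require_stop)
      )
    }
  )
  rows <- purrr::flatten(rows)
  if (length(rows) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), frame = integer(), length_aa = integer(),
      peptide = character(), has_stop = logical()
    ))
  }
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$strand)
}

#' Drop nested in-frame ORFs
#'
#' Among ORFs on the same chromosome and strand that share a stop codon
#' position (hence the same frame), keeps only the longest (most upstream
#' ATG). ORFs with distinct stops are all kept.
#'
#' @param orfs ORF tibble from [find_sorfs()].
#' @return The de-nested ORF tibble.
#' @export
eliminate_nested_orfs <- function(orfs) {
  check_columns(orfs, c("chrom", "start", "end", "strand", "length_aa"),
    "orfs")
  orfs %>%
    dplyr::mutate(
      .stop_key = ifelse(.data$strand == "+", .data$end, .data$start)
    ) %>%
    dplyr::group_by(.data$chrom, .data$strand, .data$.stop_key) %>%
    dplyr::arrange(dplyr::desc(.data$length_aa), .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".stop_key") %>%
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$strand)
}

#' Mine unannotated secreted sORFs from a genome
#'
#' Runs the full mining procedure: non-coding segment extraction, six-frame
#' sORF enumeration, nested-ORF elimination, then the SSP cascade on the
#' encoded peptides (the size gate is pre-satisfied by the enumeration
#' bounds). Candidate ids have the form `ORF<i>_<chrom>_<start>_<strand>`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param features Feature tibble (1-based inclusive) used to mask coding
#'   sequence.
#' @param verdicts Optional precomputed predictor verdicts; when `NULL` the
#'   built-in heuristics are used.
#' @param min_aa,max_aa ORF peptide length bounds.
#' @param mask_feature_types Feature types masked from the search space.
#' @return An object of class `sorf_mining`: list with `orfs` (de-nested ORF
#'   table), `cascade` (the [run_cascade()] result on the ORF peptides),
#'   `ssp` (final secreted sORF candidates with genomic coordinates) and
#'   `per_chromosome` (survivor tally per chromosome and stage).
#' @export
mine_secreted_sorfs <- function(genome, features, verdicts = NULL,
                                min_aa = 25, max_aa = 250,
                                mask_feature_types = "CDS") {
  segments <- extract_ncds(genome, features, mask_feature_types,
    min_segment = 3 * (min_aa + 1)
  )
  orfs <- find_sorfs(segments, min_aa, max_aa) %>%
    eliminate_nested_orfs()
  if (nrow(orfs) > 0) {
    orfs$protein_id <- sprintf(
      "ORF%d_%s_%d_%s", seq_len(nrow(orfs)), orfs$chrom, orfs$start,
      ifelse(orfs$strand == "+", "fwd", "rev")
    )
  } else {
    orfs$protein_id <- character(0)
  }
  proteome <- tibble::tibble(
    protein_id = orfs$protein_id,
    gene_id = orfs$protein_id,
    sequence = orfs$peptide
  )
  cascade <- run_cascade(proteome, verdicts, min_aa, max_aa,
    skip_length_gate = TRUE
  )
  flags <- cascade$candidates
  coords <- orfs[, c("protein_id", "chrom", "start", "end", "strand",
                     "frame", "length_aa")]
  ssp <- dplyr::inner_join(coords, cascade$ssp, by = "protein_id")
  per_chrom <- dplyr::left_join(coords, flags, by = "protein_id") %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(
      n_sorf = dplyr::n(),
      n_sp = sum(!is.na(.data$passed_sp) & .data$passed_sp),
      n_non_tm = sum(!is.na(.data$passed_tm) & .data$passed_tm),
      n_ssp = sum(.data$is_ssp),
      .groups = "drop"
    )
  structure(
    list(orfs = orfs, cascade = cascade, ssp = ssp,
         per_chromosome = per_chrom),
    class = "sorf_mining"
  )
}

#' @export
print.sorf_mining <- function(x, ...) {
  cat(sprintf(
    "<sorf_mining> %d sORFs -> %d secreted candidates on %d chromosome(s)\n",
    nrow(x$orfs), nrow(x$ssp), nrow(x$per_chromosome)
  ))
  invisible(x)
}

#' Write mined sORFs to GFF3
#'
#' Emits one `ORF` feature per row (1-based inclusive coordinates, interval
#' covering start through stop codon) with peptide length and frame
#' attributes.
#'
#' @param orfs ORF tibble from [find_sorfs()] / [eliminate_nested_orfs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sorf_gff <- function(orfs, path) {
  check_columns(orfs, c("chrom", "start", "end", "strand"), "orfs")
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$chrom,
    ranges = IRanges::IRanges(orfs$start + 1L, orfs$end),
    strand = orfs$strand
  )
  gr$type <- "ORF"
  gr$length_aa <- orfs$length_aa
  gr$frame <- orfs$frame
  if ("protein_id" %in% names(orfs)) gr$ID <- orfs$protein_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
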