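#' Read a protein FASTA file into a tidy proteome table
#'
#' Reads predicted proteome sequences into a one-row-per-protein tibble.
#' Sequences are uppercased, a trailing stop symbol (`*`) is stripped with a
#' warning, and the gene id is derived from the protein id (by default by
#' stripping a trailing `.<number>` isoform suffix, which matches
#' `Solyc02g092890.1 -> Solyc02g092890`-style identifiers).
#'
#' @param path Path to a protein FASTA file.
#' @param gene_id_pattern Regular expression removed from `protein_id` to
#'   obtain `gene_id`. Override for id conventions that do not use a
#'   `.<number>` isoform suffix.
#' @return A tibble with columns `protein_id`, `gene_id`, `sequence`
#'   (uppercase amino acids, no stop symbol) and `description`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1.1 demo", "MKTAYIAKQR", ">g1.2", "MKTAYIAKQRQISFVK"), fa)
#' read_protein_fasta(fa)
read_protein_fasta <- function(path, gene_id_pattern = "\\.\\d+$") {
  if (!file.exists(path)) {
    rlang::abort(sprintf("FASTA file not found: %s", path))
  }
  aa <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      rlang::abort(sprintf("Malformed FASTA '%s': %s", path, conditionMessage(e)))
    }
  )
  if (length(aa) == 0) {
    rlang::warn(sprintf("FASTA file '%s' contains no records.", path))
    return(tibble::tibble(
      protein_id = character(), gene_id = character(),
      sequence = character(), description = character()
    ))
  }
  headers <- names(aa)
  protein_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers), ""
  )
  sequence <- toupper(as.character(aa))
  has_stop <- grepl("\\*$", sequence)
  if (any(has_stop)) {
    rlang::warn(sprintf(
      "Stripped trailing stop symbol (*) from %d record(s).", sum(has_stop)
    ))
    sequence <- sub("\\*+$", "", sequence)
  }
  bad <- protein_id[nchar(sequence) == 0 | grepl("\\*", sequence)]
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Record(s) with empty sequence or internal stop symbol: %s",
      paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(protein_id)) {
    rlang::abort(sprintf(
      "Duplicate protein id(s): %s",
      paste(unique(protein_id[duplicated(protein_id)]), collapse = ", ")
    ))
  }
  tibble::tibble(
    protein_id = unname(protein_id),
    gene_id = derive_gene_id(protein_id, gene_id_pattern),
    sequence = unname(sequence),
    description = unname(description)
  )
}

#' Derive gene ids from protein/transcript ids
#'
#' @param protein_id Character vector of protein ids.
#' @param pattern Regular expression stripped from the id (default: a
#'   trailing `.<number>` isoform suffix).
#' @return Character vector of gene ids.
#' @export
derive_gene_id <- function(protein_id, pattern = "\\.\\d+$") {
  unname(sub(pattern, "", protein_id))
}

#' Write a proteome table to FASTA
#'
#' Emits one entry per row, wrapped at 60 columns.
#'
#' @param proteome A proteome tibble (see [read_protein_fasta()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteome, path) {
  check_columns(proteome, c("protein_id", "sequence"), "proteome")
  set <- Biostrings::BStringSet(proteome$sequence)
  desc <- if ("description" %in% names(proteome)) proteome$description else ""
  names(set) <- trimws(paste(proteome$protein_id, desc))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Keep the longest transcript per gene
#'
#' For genes represented by several transcripts/isoforms, retains the record
#' with the maximal sequence length; ties are broken by the lexicographically
#' smallest protein id so the result is deterministic.
#'
#' @param proteome A proteome tibble with `protein_id`, `gene_id`, `sequence`.
#' @return A tibble with exactly one row per `gene_id`, in the original
#'   column layout.
#' @export
select_longest_transcript <- function(proteome) {
  check_columns(proteome, c("protein_id", "gene_id", "sequence"), "proteome")
  proteome %>%
    dplyr::mutate(.len = nchar(.data$sequence)) %>%
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$.len), .data$protein_id) %>%
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) %>%
    dplyr::select(-".len") %>%
    dplyr::arrange(.data$protein_id)
}

#' Compute protein length, molecular weight and isoelectric point
#'
#' Adds per-protein physico-chemical properties: length in residues,
#' molecular weight in kDa (sum of average residue masses plus one water
#' mass), and isoelectric point solved by bisection on the net charge using
#' an EMBOSS-style pKa table. Ambiguity codes (X/B/Z/U) count for length,
#' contribute an average residue mass, and are excluded from the charge
#' balance.
#'
#' @param proteome A proteome tibble with a `sequence` column.
#' @return The input with `length`, `mw_kda` and `pi` columns appended.
#' @export
#' @examples
#' protein_properties(tibble::tibble(protein_id = "p", sequence = "GAVLIK"))
protein_properties <- function(proteome) {
  check_columns(proteome, "sequence", "proteome")
  proteome %>%
    dplyr::mutate(
      length = nchar(.data$sequence),
      mw_kda = protein_mw(.data$sequence),
      pi = protein_pi(.data$sequence)
    )
}

#' @rdname protein_properties
#' @param sequence Character vector of amino-acid sequences.
#' @return `protein_mw()`: molecular weight(s) in kDa; `protein_pi()`:
#'   isoelectric point(s) in pH units.
#' @export
protein_mw <- function(sequence) {
  masses <- c(RESIDUE_MASS, RESIDUE_MASS_EXTRA)
  vapply(toupper(sequence), function(s) {
    if (nchar(s) == 0) return(NA_real_)
    m <- masses[chars(s)]
    if (anyNA(m)) {
      rlang::abort(sprintf(
        "Sequence contains unsupported residue(s): %s",
        paste(unique(chars(s)[is.na(m)]), collapse = ", ")
      ))
    }
    (sum(m) + WATER_MASS) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname protein_properties
#' @param tol Convergence tolerance on the net charge (elementary charges).
#' @export
protein_pi <- function(sequence, tol = 1e-6) {
  vapply(toupper(sequence), function(s) {
    if (nchar(s) == 0) return(NA_real_)
    counts <- table(factor(chars(s), levels = names(KD_HYDROPATHY)))
    net_charge <- function(ph) {
      pos <- 1 / (1 + 10^(ph - PKA_TABLE$n_term))
      for (r in names(PKA_TABLE$positive)) {
        pos <- pos + counts[[r]] / (1 + 10^(ph - PKA_TABLE$positive[[r]]))
      }
      neg <- 1 / (1 + 10^(PKA_TABLE$c_term - ph))
      for (r in names(PKA_TABLE$negative)) {
        neg <- neg + counts[[r]] / (1 + 10^(PKA_TABLE$negative[[r]] - ph))
      }
      pos - neg
    }
    lo <- 0; hi <- 14
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      q <- net_charge(mid)
      if (abs(q) < tol) break
      if (q > 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1), USE.NAMES = FALSE)
}
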