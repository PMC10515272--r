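# CEP (C-terminally encoded peptide) domain analysis. The CEP domain is
# located by its conserved SPGxG[H/N] box; the candidate mature peptide is
# the 15-residue window ending at the motif's last residue (both published
# synthesized CEPs are 15-mers ending in SPGEGH). The window length is an
# operational convention, not a biochemical cleavage rule, and is exposed
# as a parameter.

CEP_MOTIF_REGEX <- "SPG.G[HN]"

#' Detect CEP domains in precursor proteins
#'
#' Scans each sequence for non-overlapping occurrences of the conserved
#' `SPGxG[H/N]` box (leftmost-greedy) and reports, per hit, the matched
#' 6-mer, its 0-based half-open coordinates on the precursor and the
#' `mature_len`-residue candidate mature peptide ending at the motif end.
#' Hits closer than `mature_len` residues to the N terminus are flagged as
#' left-truncated.
#'
#' @param proteome A proteome tibble (`protein_id`, `sequence`) or a
#'   character vector of sequences.
#' @param mature_len Length of the reported mature-peptide window.
#' @return A tibble with one row per domain hit: `protein_id`, `start`,
#'   `end`, `motif_text`, `mature_peptide`, `left_truncated`.
#' @export
#' @examples
#' detect_cep_domains("YLGIKNSGPSPGEGH")
detect_cep_domains <- function(proteome, mature_len = 15) {
  if (is.character(proteome)) {
    proteome <- tibble::tibble(
      protein_id = paste0("seq", seq_along(proteome)), sequence = proteome
    )
  }
  check_columns(proteome, c("protein_id", "sequence"), "proteome")
  purrr::map2(proteome$protein_id, toupper(proteome$sequence),
    function(id, s) {
      hits <- motif_matches(CEP_MOTIF_REGEX, s)
      if (nrow(hits) == 0) return(NULL)
      hits %>%
        dplyr::mutate(
          protein_id = id,
          motif_text = .data$text,
          mature_peptide = substring(
            s, pmax(.data$end - mature_len + 1L, 1L), .data$end
          ),
          left_truncated = .data$end < mature_len
        ) %>%
        dplyr::select("protein_id", "start", "end", "motif_text",
                      "mature_peptide", "left_truncated")
    }
  ) %>% dplyr::bind_rows()
}

#' Summarise single- versus multi-domain CEP architecture
#'
#' Counts CEP domain hits per protein and labels each precursor single
#' (1 domain) or multi (>= 2 domains). Proteins present in `proteome` but
#' without any hit are excluded with a warning.
#'
#' @param hits Domain-hit tibble from [detect_cep_domains()].
#' @param proteome Optional proteome tibble used to warn about proteins
#'   without hits.
#' @return A tibble with `protein_id`, `n_domains`, `architecture`
#'   (`"single"`/`"multi"`).
#' @export
summarize_domain_architecture <- function(hits, proteome = NULL) {
  check_columns(hits, "protein_id", "hits")
  if (!is.null(proteome)) {
    none <- setdiff(proteome$protein_id, hits$protein_id)
    if (length(none) > 0) {
      rlang::warn(sprintf(
        "%d protein(s) without a CEP domain excluded: %s",
        length(none), paste(utils::head(none, 5), collapse = ", ")
      ))
    }
  }
  hits %>%
    dplyr::count(.data$protein_id, name = "n_domains") %>%
    dplyr::mutate(
      architecture = ifelse(.data$n_domains >= 2, "multi", "single")
    )
}
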