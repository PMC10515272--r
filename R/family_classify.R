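# Rule/motif-based family classification. A rule = family + motif (compact
# syntax: amino-acid letters, `x` = any residue, `[...]` = alternatives)
# searched in a region of the candidate (mature sequence, its C-terminal
# window, or the full precursor), optionally with a co-occurring second
# motif and an exact mature cysteine-count constraint. Rules are applied in
# priority order and each candidate receives at most one family.

#' Cysteine-rich peptide (CRP) call
#'
#' A mature sequence is called a putative CRP when it contains an even
#' number of cysteines between 2 and 16 inclusive. The whole mature sequence
#' (after signal-peptide removal) is counted.
#'
#' @param mature_sequence Character vector of mature sequences.
#' @return A tibble with `cys_count` and logical `is_crp`, one row per
#'   input.
#' @export
#' @examples
#' is_crp(c("ACACAC", "ACACA", "A"))
is_crp <- function(mature_sequence) {
  counts <- stringr::str_count(toupper(mature_sequence), "C")
  tibble::tibble(
    cys_count = as.integer(counts),
    is_crp = counts %% 2 == 0 & counts >= 2 & counts <= 16
  )
}

# Compact motif syntax -> regular expression ("x" = any residue).
motif_to_regex <- function(motif) {
  gsub("x", ".", motif, fixed = TRUE)
}

#' Default family motif rules
#'
#' The shipped rule set, read from the editable YAML resource in
#' `inst/extdata/family_rules.yaml`. Default motifs exist for the families
#' with published motif evidence: CEP (the conserved `SPGxG[HN]` box near
#' the C terminus), CLE (a conservative CLE dodecapeptide box), RALF (four
#' mature cysteines plus the `RR` dibasic processing site) and PNP (the
#' `K[VI][VI]D` and `LSxxA[FI]xxIA` boxes co-occurring).
#'
#' @param path Optional path to an alternative rule file.
#' @return A tibble of rules with columns `family`, `ssp_class`,
#'   `mode_of_action`, `motif`, `motif2`, `n_cys`, `search_region`,
#'   `priority`.
#' @export
default_family_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "family_rules.yaml",
    package = "sspminer", mustWork = TRUE
  )
  raw <- yaml::read_yaml(path)
  rules <- purrr::map(raw$rules, function(r) {
    tibble::tibble(
      family = r$family,
      motif = r$motif,
      motif2 = r$motif2 %||% NA_character_,
      n_cys = r$n_cys %||% NA_integer_,
      search_region = r$search_region %||% "mature",
      c_terminal_k = r$c_terminal_k %||% 30L,
      priority = r$priority
    )
  }) %>% dplyr::bind_rows()
  lint_family_rules(rules)
}

#' Validate a rule table against the family vocabulary
#'
#' Checks that every rule family exists in [ssp_family_vocabulary()], that
#' motifs compile, and attaches the vocabulary's class and mode of action
#' (so a rule can never contradict the controlled taxonomy).
#'
#' @param rules A rule tibble (see [default_family_rules()]).
#' @return The rule tibble with `ssp_class` and `mode_of_action` attached,
#'   sorted by priority.
#' @export
lint_family_rules <- function(rules) {
  check_columns(rules, c("family", "motif", "priority"), "rules")
  if (nrow(rules) == 0) rlang::abort("Empty family rule set.")
  vocab <- ssp_family_vocabulary()
  unknown <- setdiff(rules$family, vocab$family)
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "Rule families not in the vocabulary: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  if (anyDuplicated(rules$family)) {
    rlang::abort("Each family may have at most one rule.")
  }
  for (m in c(rules$motif, rules$motif2[!is.na(rules$motif2)])) {
    tryCatch(regexpr(motif_to_regex(m), "A"), error = function(e) {
      rlang::abort(sprintf("Motif '%s' does not compile: %s", m, conditionMessage(e)))
    })
  }
  rules %>%
    dplyr::select(-dplyr::any_of(c("ssp_class", "mode_of_action"))) %>%
    dplyr::left_join(
      vocab[, c("family", "ssp_class", "mode_of_action")], by = "family"
    ) %>%
    dplyr::arrange(.data$priority)
}

rule_region <- function(rule, mature, full) {
  switch(rule$search_region,
    mature = mature,
    full = full,
    c_terminal_k = stringr::str_sub(mature, -rule$c_terminal_k),
    rlang::abort(sprintf("Unknown search_region '%s'.", rule$search_region))
  )
}

# Non-overlapping motif matches in a region; returns a tibble of 0-based
# half-open coordinates and matched text.
motif_matches <- function(motif, region) {
  rx <- motif_to_regex(motif)
  m <- gregexpr(rx, region, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(
      start = integer(), end = integer(), text = character()
    ))
  }
  len <- attr(m, "match.length")
  tibble::tibble(
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + len,
    text = substring(region, m, m + len - 1L)
  )
}

#' Classify SSP candidates into known families
#'
#' Applies motif rules in priority order; each candidate receives the first
#' matching family or `"unknown"`. The SSP class and mode of action come
#' from the controlled vocabulary; `n_domains` counts non-overlapping
#' matches of the family's primary motif in the searched region.
#'
#' @param candidates Tibble of SSP candidates with `protein_id`, `sequence`
#'   and `mature_sequence` (e.g. the `ssp` table of [run_cascade()]).
#' @param rules Rule tibble; defaults to [default_family_rules()].
#' @return A tibble with `protein_id`, `family`, `ssp_class`,
#'   `mode_of_action`, `n_domains`, `cys_count`, `is_crp` and an `evidence`
#'   column (matched motif text with 0-based half-open coordinates on the
#'   searched region).
#' @export
classify_families <- function(candidates, rules = default_family_rules()) {
  check_columns(candidates, c("protein_id", "sequence", "mature_sequence"),
    "candidates")
  rules <- lint_family_rules(rules)
  crp <- is_crp(candidates$mature_sequence)
  assignments <- purrr::pmap(
    list(candidates$protein_id, candidates$sequence,
         candidates$mature_sequence, crp$cys_count),
    function(id, full, mature, n_cys) {
      for (i in seq_len(nrow(rules))) {
        rule <- rules[i, ]
        if (!is.na(rule$n_cys) && n_cys != rule$n_cys) next
        region <- rule_region(rule, mature, full)
        hits <- motif_matches(rule$motif, region)
        if (nrow(hits) == 0) next
        if (!is.na(rule$motif2) &&
            nrow(motif_matches(rule$motif2, region)) == 0) next
        return(tibble::tibble(
          protein_id = id,
          family = rule$family,
          ssp_class = rule$ssp_class,
          mode_of_action = rule$mode_of_action,
          n_domains = nrow(hits),
          evidence = paste(
            sprintf("%s@[%d,%d)", hits$text, hits$start, hits$end),
            collapse = ";"
          )
        ))
      }
      tibble::tibble(
        protein_id = id, family = "unknown", ssp_class = NA_character_,
        mode_of_action = NA_character_, n_domains = 0L,
        evidence = NA_character_
      )
    }
  ) %>% dplyr::bind_rows()
  dplyr::bind_cols(assignments, crp)
}

#' Discover novel CRP families by cysteine spacing
#'
#' Groups unclassified CRP candidates by the spacing of the cysteines in
#' their mature sequences. Each candidate contributes its gap vector (number
#' of residues between consecutive cysteines); candidates with the same
#' cysteine count are agglomerated greedily in input order into clusters in
#' which every gap position, except the one of maximal spread (the
#' designated variable position), varies by at most `gap_tolerance` around a
#' common centre (spread `<= 2 * gap_tolerance`). Clusters reaching
#' `min_members` are reported with a consensus [cys_pattern()]: zero-spread
#' positions become exact gaps, the maximal-spread position becomes a
#' variable gap when its spread exceeds the tolerance band, and remaining
#' positions become ranges.
#'
#' @param candidates Tibble with `protein_id` and `mature_sequence`,
#'   typically the cascade's SSPs left `"unknown"` by [classify_families()]
#'   and passing [is_crp()].
#' @param min_members Minimum cluster size reported as a family.
#' @param gap_tolerance Allowed deviation (residues) of a gap from the
#'   cluster centre at non-variable positions.
#' @return A tibble with one row per discovered family: `pattern_label`,
#'   `n_cys`, `n_members`, list-columns `members` (protein ids) and
#'   `pattern` (`cys_pattern` objects).
#' @export
discover_crp_families <- function(candidates, min_members = 3,
                                  gap_tolerance = 1) {
  check_columns(candidates, c("protein_id", "mature_sequence"), "candidates")
  gaps <- purrr::map(candidates$mature_sequence, cys_gap_vector)
  keep <- purrr::map_int(gaps, length) >= 1
  ids <- candidates$protein_id[keep]
  gaps <- gaps[keep]
  clusters <- list()  # each: list(len, members = idx vector, mat = matrix)
  for (i in seq_along(gaps)) {
    g <- gaps[[i]]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      if (cl$len != length(g)) next
      mat <- rbind(cl$mat, g)
      spreads <- apply(mat, 2, function(v) max(v) - min(v))
      jstar <- which.max(spreads)
      if (all(spreads[-jstar] <= 2 * gap_tolerance)) {
        clusters[[k]]$mat <- mat
        clusters[[k]]$members <- c(cl$members, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        len = length(g), members = i, mat = matrix(g, nrow = 1)
      )
    }
  }
  clusters <- purrr::keep(clusters, ~ length(.x$members) >= min_members)
  if (length(clusters) == 0) {
    return(tibble::tibble(
      pattern_label = character(), n_cys = integer(), n_members = integer(),
      members = list(), pattern = list()
    ))
  }
  purrr::map(clusters, function(cl) {
    pat <- consensus_cys_pattern(cl$mat, gap_tolerance)
    tibble::tibble(
      pattern_label = pat$label,
      n_cys = pat$n_cys,
      n_members = length(cl$members),
      members = list(ids[cl$members]),
      pattern = list(pat)
    )
  }) %>% dplyr::bind_rows()
}
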