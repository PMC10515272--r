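# Signal-peptide / transmembrane predictor contract.
#
# The cascade consumes a per-protein verdict table with columns
#   protein_id, has_signal_peptide, sp_cleavage_site, tm_helix_count
# which can come from precomputed SignalP-5.0 / TMHMM-2.0 short-format
# outputs, or from the built-in deterministic heuristics. The heuristics are
# a documented stand-in so the pipeline is testable without the external
# tools; they do not reproduce the neural/HMM predictions.

#' Parse SignalP-5.0 short-format output
#'
#' Reads the tab-separated "short" output of SignalP-5.0 (comment lines start
#' with `#`; columns ID, Prediction, SP(Sec/SPI) probability, OTHER
#' probability, CS position). A protein is called signal-peptide-positive
#' when its Prediction equals `"SP(Sec/SPI)"`; the cleavage site is the last
#' signal-peptide residue, parsed from the `CS pos: X-Y` annotation.
#'
#' @param path Path to a SignalP-5.0 short-format file.
#' @return A tibble with columns `protein_id`, `has_signal_peptide`,
#'   `sp_cleavage_site` (0 when no signal peptide).
#' @export
read_signalp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(
      protein_id = character(), has_signal_peptide = logical(),
      sp_cleavage_site = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  purrr::map(fields, function(f) {
    pred <- f[[2]]
    if (!pred %in% c("SP(Sec/SPI)", "OTHER")) {
      rlang::warn(sprintf(
        "Unknown SignalP prediction label '%s' for %s; treated as no signal peptide.",
        pred, f[[1]]
      ))
    }
    has_sp <- identical(pred, "SP(Sec/SPI)")
    cs <- 0L
    if (has_sp) {
      m <- regmatches(
        paste(f, collapse = "\t"),
        regexpr("CS pos: *([0-9]+)-[0-9]+", paste(f, collapse = "\t"))
      )
      if (length(m) == 1) {
        cs <- as.integer(sub("CS pos: *([0-9]+)-[0-9]+", "\\1", m))
      } else {
        rlang::warn(sprintf("No cleavage site annotation for %s; treated as no signal peptide.", f[[1]]))
        has_sp <- FALSE
      }
    }
    tibble::tibble(
      protein_id = f[[1]], has_signal_peptide = has_sp, sp_cleavage_site = cs
    )
  }) %>% dplyr::bind_rows()
}

#' Parse TMHMM-2.0 short-format output
#'
#' Reads the one-line-per-protein "short" output of TMHMM-2.0 and extracts
#' the predicted transmembrane helix count from the `PredHel=N` field.
#'
#' @param path Path to a TMHMM-2.0 short-format file.
#' @return A tibble with columns `protein_id`, `tm_helix_count`.
#' @export
read_tmhmm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(protein_id = character(), tm_helix_count = integer()))
  }
  id <- sub("\\s.*$", "", lines)
  hel <- regmatches(lines, regexpr("PredHel=([0-9]+)", lines))
  if (length(hel) != length(lines)) {
    rlang::abort("TMHMM short-format line without a PredHel field.")
  }
  tibble::tibble(
    protein_id = id,
    tm_helix_count = as.integer(sub("PredHel=", "", hel, fixed = TRUE))
  )
}

#' Built-in heuristic signal-peptide detector
#'
#' Deterministic rule-based stand-in for an external signal-peptide
#' predictor. A signal peptide is declared when, within the first
#' `search_window` residues, there is an 8-residue hydrophobic core with mean
#' Kyte-Doolittle hydropathy >= `core_hydropathy`, at least one K/R among the
#' residues preceding that core (the n-region charge), and a candidate
#' cleavage site 3--7 residues downstream of the core whose -1 and -3
#' residues are small (A/G/S/C/T), mirroring the classical (-3,-1) rule. The
#' leftmost admissible core is used and, among its admissible cleavage
#' positions, the rightmost is reported (the cleavage site is the last
#' residue of the signal peptide).
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param search_window Number of N-terminal residues searched for the core.
#' @param core_hydropathy Minimum mean hydropathy of the 8-residue core.
#' @return A tibble with `has_signal_peptide` and `sp_cleavage_site`
#'   (0 when none), one row per input sequence.
#' @export
#' @examples
#' predict_signal_peptide("MKTNLFLVLLLAGSALAQQDDEEKKNNSSTT")
predict_signal_peptide <- function(sequence, search_window = 45,
                                   core_hydropathy = 1.6) {
  core_len <- 8L
  small <- c("A", "G", "S", "C", "T")
  res <- purrr::map(sequence, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    cc <- if (n > 0) chars(s) else character(0)
    kd <- kd_values(cc)
    limit <- min(search_window, n)
    if (limit >= core_len) {
      means <- roll_mean(kd[seq_len(limit)], core_len)
      for (i in seq_along(means)) {
        if (means[i] < core_hydropathy) next
        core_end <- i + core_len - 1L
        if (i > 1 && !any(cc[seq_len(i - 1)] %in% c("K", "R"))) next
        cand <- (core_end + 3L):(core_end + 7L)
        cand <- cand[cand >= 3 & cand <= n - 1L]
        ok <- cand[cc[cand] %in% small & cc[cand - 2L] %in% small]
        if (length(ok) > 0) {
          return(list(TRUE, as.integer(max(ok))))
        }
      }
    }
    list(FALSE, 0L)
  })
  tibble::tibble(
    has_signal_peptide = purrr::map_lgl(res, 1),
    sp_cleavage_site = purrr::map_int(res, 2)
  )
}

#' Built-in heuristic transmembrane helix counter
#'
#' Counts non-overlapping 19-residue windows with mean Kyte-Doolittle
#' hydropathy >= `threshold`, scanning greedily left to right. Intended to be
#' applied to the mature sequence (after signal-peptide removal) so the
#' signal peptide's own hydrophobic core is not counted as a helix.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param window Window width in residues.
#' @param threshold Minimum mean hydropathy calling a window a helix.
#' @return Integer vector of helix counts.
#' @export
count_tm_helices <- function(sequence, window = 19, threshold = 1.8) {
  vapply(sequence, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < window) return(0L)
    kd <- kd_values(chars(s))
    cs <- cumsum(c(0, kd))
    count <- 0L
    i <- 1L
    while (i + window - 1L <= n) {
      if ((cs[i + window] - cs[i]) / window >= threshold) {
        count <- count + 1L
        i <- i + window
      } else {
        i <- i + 1L
      }
    }
    count
  }, integer(1), USE.NAMES = FALSE)
}

#' Assemble per-protein predictor verdicts
#'
#' Builds the verdict table consumed by [run_cascade()], either by parsing
#' precomputed SignalP-5.0/TMHMM-2.0 short-format files or by running the
#' built-in heuristics on the sequences. When TMHMM output is supplied its
#' helix count is used as-is; with the heuristic, helices are counted on the
#' mature sequence only.
#'
#' @param proteome A proteome tibble (`protein_id`, `sequence`).
#' @param signalp,tmhmm Optional paths to precomputed predictor outputs.
#'   When `NULL`, the corresponding built-in heuristic is used.
#' @return A tibble with columns `protein_id`, `has_signal_peptide`,
#'   `sp_cleavage_site`, `tm_helix_count`.
#' @export
predictor_verdicts <- function(proteome, signalp = NULL, tmhmm = NULL) {
  check_columns(proteome, c("protein_id", "sequence"), "proteome")
  if (is.null(signalp)) {
    sp <- predict_signal_peptide(proteome$sequence)
    sp$protein_id <- proteome$protein_id
  } else {
    sp <- read_signalp(signalp)
  }
  verdicts <- dplyr::left_join(
    proteome[, "protein_id", drop = FALSE], sp, by = "protein_id"
  )
  if (is.null(tmhmm)) {
    mature <- ifelse(
      !is.na(verdicts$has_signal_peptide) & verdicts$has_signal_peptide,
      substring(proteome$sequence, verdicts$sp_cleavage_site + 1L),
      proteome$sequence
    )
    verdicts$tm_helix_count <- count_tm_helices(mature)
  } else {
    tm <- read_tmhmm(tmhmm)
    verdicts <- dplyr::left_join(verdicts, tm, by = "protein_id")
  }
  verdicts
}
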