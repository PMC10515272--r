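# Cysteine-spacing patterns. A pattern such as "C x3 C x5 C x5 C x2 C xn C"
# describes a block of n cysteines separated by gaps of non-cysteine
# residues: exact gaps (x3), bounded ranges (x4-6) and variable gaps (xn,
# any number >= 0). Patterns double as motif matchers and as cluster
# signatures for novel CRP family discovery.

#' Build or parse a cysteine-spacing pattern
#'
#' `cys_pattern()` constructs a pattern from a list of gap specs;
#' `parse_cys_pattern()` parses the compact text form whose tokens are `C`,
#' `x<k>` (exact gap), `x<a>-<b>` (range gap) and `xn` (variable gap, any
#' number of residues), alternating `C` and gap tokens.
#'
#' @param gaps A list of gap specs: a single number (exact), a length-2
#'   numeric vector (range), or the string `"n"` (variable).
#' @param label Optional pattern label.
#' @return An object of class `cys_pattern` with fields `n_cys`, `gaps` and
#'   `label`.
#' @export
#' @examples
#' parse_cys_pattern("C x3 C x5 C x5 C x2 C xn C")
cys_pattern <- function(gaps, label = NULL) {
  gaps <- purrr::map(gaps, function(g) {
    if (identical(g, "n") || identical(g, "variable")) {
      list(type = "variable")
    } else if (is.numeric(g) && length(g) == 1) {
      if (g < 0) rlang::abort("Exact gap must be >= 0.")
      list(type = "exact", k = as.integer(g))
    } else if (is.numeric(g) && length(g) == 2) {
      if (any(g < 0) || g[1] > g[2]) rlang::abort("Invalid range gap.")
      list(type = "range", a = as.integer(g[1]), b = as.integer(g[2]))
    } else {
      rlang::abort("Each gap must be a number, a length-2 range, or \"n\".")
    }
  })
  structure(
    list(
      n_cys = length(gaps) + 1L, gaps = gaps,
      label = label %||% format_gaps(gaps)
    ),
    class = "cys_pattern"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

format_gaps <- function(gaps) {
  toks <- purrr::map_chr(gaps, function(g) {
    switch(g$type,
      exact = paste0("x", g$k),
      range = paste0("x", g$a, "-", g$b),
      variable = "xn"
    )
  })
  paste(c(rbind(rep("C", length(toks)), toks)), collapse = " ") %>%
    paste("C")
}

#' @rdname cys_pattern
#' @param text Pattern text, e.g. `"C x5 C xn C x6 C x4-6 C x1 C"`.
#' @export
parse_cys_pattern <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(toks) < 3 || length(toks) %% 2 == 0) {
    rlang::abort(sprintf(
      "Pattern '%s' must alternate C and gap tokens (C gap C ...).", text
    ))
  }
  gaps <- vector("list", (length(toks) - 1) / 2)
  for (i in seq_along(toks)) {
    tok <- toks[i]
    if (i %% 2 == 1) {
      if (tok != "C") {
        rlang::abort(sprintf(
          "Pattern '%s': expected 'C' at token %d, found '%s'.", text, i, tok
        ))
      }
    } else {
      g <- if (tok == "xn") {
        "n"
      } else if (grepl("^x[0-9]+-[0-9]+$", tok)) {
        as.numeric(strsplit(sub("^x", "", tok), "-", fixed = TRUE)[[1]])
      } else if (grepl("^x[0-9]+$", tok)) {
        as.numeric(sub("^x", "", tok))
      } else {
        rlang::abort(sprintf(
          "Pattern '%s': malformed gap token '%s' at position %d.", text, tok, i
        ))
      }
      gaps[[i / 2]] <- g
    }
  }
  cys_pattern(gaps, label = paste(toks, collapse = " "))
}

#' @export
print.cys_pattern <- function(x, ...) {
  cat(sprintf("<cys_pattern> %s (%d cysteines)\n", x$label, x$n_cys))
  invisible(x)
}

#' @export
format.cys_pattern <- function(x, ...) x$label

gap_ok <- function(gap, width) {
  switch(gap$type,
    exact = width == gap$k,
    range = width >= gap$a && width <= gap$b,
    variable = TRUE
  )
}

#' Match a cysteine-spacing pattern against a sequence
#'
#' Finds all non-overlapping occurrences of the pattern, scanning left to
#' right. Gap residues must be non-cysteine, so a matched block contains
#' exactly the pattern's cysteines; consequently every match aligns the
#' pattern's cysteines with consecutive cysteines of the sequence.
#'
#' @param pattern A `cys_pattern` (or pattern text, parsed on the fly).
#' @param sequence A single amino-acid sequence (typically a mature
#'   sequence, after signal-peptide removal).
#' @return A tibble with 0-based half-open `start`/`end` coordinates of each
#'   match and a `cys_positions` list-column (0-based positions of the
#'   matched cysteines).
#' @export
#' @examples
#' match_cys_pattern("C x0 C", "AACCAA")
match_cys_pattern <- function(pattern, sequence) {
  if (is.character(pattern)) pattern <- parse_cys_pattern(pattern)
  stopifnot(inherits(pattern, "cys_pattern"))
  s <- toupper(sequence)
  cpos <- which(chars(s) == "C")  # 1-based
  n <- pattern$n_cys
  out <- list()
  i <- 1L
  while (i + n - 1L <= length(cpos)) {
    block <- cpos[i:(i + n - 1L)]
    widths <- diff(block) - 1L
    ok <- all(purrr::map2_lgl(pattern$gaps, widths, gap_ok))
    if (ok) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start = block[1] - 1L, end = block[n],
        cys_positions = list(block - 1L)
      )
      i <- i + n  # non-overlapping: jump past the matched cysteines
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      start = integer(), end = integer(), cys_positions = list()
    ))
  }
  dplyr::bind_rows(out)
}

# Gap vector between consecutive cysteines of a sequence (all cysteines).
# Returns integer(0) for < 2 cysteines.
cys_gap_vector <- function(sequence) {
  cpos <- which(chars(toupper(sequence)) == "C")
  if (length(cpos) < 2) return(integer(0))
  as.integer(diff(cpos) - 1L)
}

# Consensus pattern from a matrix of member gap vectors (rows = members).
# Positions with zero spread become exact gaps; the position of maximal
# spread becomes variable when its spread exceeds 2*tolerance; remaining
# positions with small spread become [min, max] ranges.
consensus_cys_pattern <- function(gap_matrix, gap_tolerance = 1) {
  spreads <- apply(gap_matrix, 2, function(v) max(v) - min(v))
  jstar <- which.max(spreads)
  gaps <- purrr::map(seq_len(ncol(gap_matrix)), function(j) {
    v <- gap_matrix[, j]
    if (j == jstar && spreads[j] > 2 * gap_tolerance) {
      "n"
    } else if (max(v) == min(v)) {
      min(v)
    } else {
      c(min(v), max(v))
    }
  })
  cys_pattern(gaps)
}
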