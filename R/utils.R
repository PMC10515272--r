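# Internal helpers shared across modules.

# Split an amino-acid or nucleotide string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Mean Kyte-Doolittle hydropathy of a character vector of residues;
# residues outside the 20-letter alphabet score 0.
kd_values <- function(residues) {
  v <- KD_HYDROPATHY[residues]
  v[is.na(v)] <- 0
  unname(v)
}

# Rolling mean over a fixed window (used by the SP/TM heuristics).
roll_mean <- function(x, width) {
  n <- length(x)
  if (n < width) return(numeric(0))
  cs <- cumsum(c(0, x))
  (cs[(width + 1):(n + 1)] - cs[1:(n - width + 1)]) / width
}

# Reverse complement of an ACGTN string (kept local: callers pass plain
# character vectors, not XStringSet objects).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""), character(1)
  ))
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    rlang::abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Assert that a data frame carries the named columns.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
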