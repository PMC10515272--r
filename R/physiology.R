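# Leaf-level drought-damage physiology: relative water content (RWC),
# relative electrolyte conductivity (REC) and malondialdehyde (MDA)
# concentration, plus one-way ANOVA group comparison with a compact letter
# display.

#' Relative water content (RWC)
#'
#' `RWC = (FW - DW) / (SW - DW) * 100` (percent), from fresh (FW),
#' water-saturated (SW) and dry (DW) leaf weight in grams. A fresh weight
#' outside `[DW, SW]` yields a validation warning but the value is still
#' returned.
#'
#' @param fw,sw,dw Fresh, saturated and dry weight (g).
#' @return RWC in percent.
#' @export
#' @examples
#' rwc(2.0, 2.5, 0.5)  # 75
rwc <- function(fw, sw, dw) {
  if (any(sw == dw)) {
    rlang::abort("RWC undefined: saturated weight equals dry weight.")
  }
  if (any(fw < dw | fw > sw)) {
    rlang::warn("Fresh weight outside [dry weight, saturated weight].")
  }
  (fw - dw) / (sw - dw) * 100
}

#' Relative electrolyte conductivity (REC)
#'
#' `REC = K1 / K2 * 100` (percent), from conductivity before (`K1`) and
#' after (`K2`) boiling. Values above 100 percent are flagged.
#'
#' @param k1,k2 Initial and final conductivity (same units).
#' @return REC in percent.
#' @export
rec <- function(k1, k2) {
  if (any(k2 <= 0)) rlang::abort("REC undefined: K2 must be positive.")
  out <- k1 / k2 * 100
  if (any(out > 100)) rlang::warn("REC above 100% (K1 > K2).")
  out
}

#' Malondialdehyde (MDA) concentration
#'
#' `MDA (nM/g) = [(A532 - A600) * Vr / eps * 1e9] / (Wt * Vt / V)` with the
#' MDA-TBA extinction coefficient `eps = 1.55e5 L/mol/cm`, reaction volume
#' `Vr` (mL), total extract volume `V` (mL), extract volume used `Vt` (mL)
#' and fresh tissue weight `Wt` (g). A blank exceeding the signal (negative
#' absorbance difference) is returned as a negative value with a warning.
#'
#' @param a532,a600 Absorbance at 532 and 600 nm.
#' @param vr Reaction volume (mL).
#' @param wt Fresh tissue weight (g).
#' @param vt Extract volume used in the reaction (mL).
#' @param v Total extract volume (mL).
#' @param epsilon Extinction coefficient (L/mol/cm).
#' @return MDA concentration in nM per g fresh weight.
#' @export
#' @examples
#' mda(0.155 + 0.02, 0.02, vr = 4, wt = 0.3, vt = 1, v = 3)  # 40000
mda <- function(a532, a600, vr, wt, vt, v, epsilon = MDA_EXTINCTION) {
  if (any(c(vr, wt, vt, v) <= 0)) {
    rlang::abort("Volumes and tissue weight must be positive.")
  }
  if (any(a532 < 0 | a600 < 0)) rlang::abort("Absorbances must be >= 0.")
  diff <- a532 - a600
  if (any(diff < 0)) {
    rlang::warn("A600 exceeds A532; returning negative MDA (blank > signal).")
  }
  (diff * vr / epsilon * 1e9) / (wt * vt / v)
}

#' Compute physiology metrics for a sample table
#'
#' Applies whichever of [rwc()], [rec()] and [mda()] the table's columns
#' support. Expected columns (all optional as a group): `fw`, `sw`, `dw`
#' for RWC; `k1`, `k2` for REC; `a532`, `a600`, `vr`, `wt`, `vt`, `v` for
#' MDA.
#'
#' @param samples Sample tibble.
#' @return The input with `rwc`, `rec` and/or `mda` columns appended.
#' @export
compute_physiology <- function(samples) {
  out <- samples
  if (all(c("fw", "sw", "dw") %in% names(samples))) {
    out$rwc <- rwc(samples$fw, samples$sw, samples$dw)
  }
  if (all(c("k1", "k2") %in% names(samples))) {
    out$rec <- rec(samples$k1, samples$k2)
  }
  if (all(c("a532", "a600", "vr", "wt", "vt", "v") %in% names(samples))) {
    out$mda <- mda(samples$a532, samples$a600, samples$vr, samples$wt,
                   samples$vt, samples$v)
  }
  out
}

# Compact letter display by insert-and-absorb: start from one letter
# containing all groups; for each significantly different pair, split every
# letter containing both; finally absorb letters that are subsets of others.
letter_display <- function(groups, sig_pairs) {
  letters_sets <- list(groups)
  for (p in sig_pairs) {
    for (k in seq_along(letters_sets)) {
      set <- letters_sets[[k]]
      if (all(p %in% set)) {
        letters_sets[[k]] <- setdiff(set, p[1])
        letters_sets[[length(letters_sets) + 1L]] <- setdiff(set, p[2])
      }
    }
    keep <- rep(TRUE, length(letters_sets))
    for (a in seq_along(letters_sets)) {
      for (b in seq_along(letters_sets)) {
        if (a != b && keep[b] &&
            all(letters_sets[[a]] %in% letters_sets[[b]]) &&
            (length(letters_sets[[a]]) < length(letters_sets[[b]]) ||
               a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    letters_sets <- letters_sets[keep]
  }
  labels <- letters[seq_along(letters_sets)]
  vapply(groups, function(g) {
    paste(labels[vapply(letters_sets, function(s) g %in% s, logical(1))],
          collapse = "")
  }, character(1))
}

#' One-way ANOVA group comparison with letter display
#'
#' Classical one-way ANOVA across treatment groups followed by Tukey HSD
#' pairwise comparisons; groups not sharing a letter differ at level
#' `alpha`. Pairwise p-values that are undefined (e.g. zero variance
#' everywhere) are treated as non-significant.
#'
#' @param data A tibble of measurements.
#' @param value,group Column names (strings) of the measurement and the
#'   grouping factor.
#' @param alpha Significance level for the letter display.
#' @return An object of class `group_comparison`; [tidy()] returns
#'   per-group `mean`, `sd`, `n` and `letter`, [glance()] the ANOVA
#'   `statistic` (F), `p_value`, `df_between`, `df_within`.
#' @export
#' @examples
#' d <- data.frame(g = rep(c("ck", "ds"), each = 5),
#'                 y = c(rnorm(5, 90, 2), rnorm(5, 55, 2)))
#' tidy(group_compare(d, "y", "g"))
group_compare <- function(data, value, group, alpha = 0.05) {
  check_columns(data, c(value, group), "data")
  df <- data.frame(
    y = data[[value]], g = factor(data[[group]])
  )
  counts <- table(df$g)
  if (length(counts) < 2 || any(counts < 2)) {
    rlang::abort("Need >= 2 groups with >= 2 values each.")
  }
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  tukey <- as.data.frame(stats::TukeyHSD(fit, conf.level = 1 - alpha)$g)
  pair_names <- strsplit(rownames(tukey), "-", fixed = TRUE)
  sig <- !is.na(tukey$`p adj`) & tukey$`p adj` < alpha
  sig_pairs <- pair_names[sig]
  groups <- levels(df$g)
  lett <- letter_display(groups, sig_pairs)
  summary_tbl <- df %>%
    dplyr::group_by(.data$g) %>%
    dplyr::summarise(
      mean = mean(.data$y), sd = stats::sd(.data$y), n = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::rename(group = "g") %>%
    dplyr::mutate(
      group = as.character(.data$group),
      letter = unname(lett[match(.data$group, groups)])
    )
  structure(
    list(
      summary = summary_tbl,
      anova = tibble::tibble(
        statistic = fstat, p_value = pval,
        df_between = an$Df[1], df_within = an$Df[2]
      ),
      tukey = tibble::as_tibble(tukey, rownames = "pair"),
      alpha = alpha
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> one-way ANOVA F = %.3g, p = %.3g (alpha = %g)\n",
    x$anova$statistic, x$anova$p_value, x$alpha
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname group_compare
#' @param x,object A `group_comparison` object.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' @rdname group_compare
#' @export
glance.group_comparison <- function(x, ...) x$anova

#' @rdname group_compare
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$group, y = .data$mean)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal()
}
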