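# Drought differential-expression filtering and qPCR relative expression.
# The DE rule is threshold-based on precomputed FPKM and q-values:
# up when log2(FPKM_treated / FPKM_control) >= 1 and q <= 0.05, down with
# the mirrored fold-change bound.

#' Call differential expression for one contrast
#'
#' Vectorised threshold rule: `"up"` when
#' `log2((treated + pseudocount) / (control + pseudocount)) >= lfc_threshold`
#' and `qvalue <= q_threshold`; `"down"` with the mirrored bound; otherwise
#' `"ns"`. With `pseudocount = 0`, a zero FPKM on either side is an explicit
#' error rather than a silent infinite fold change.
#'
#' @param fpkm_control,fpkm_treated Non-negative expression values.
#' @param qvalue Multiple-testing-adjusted significance in `[0, 1]`.
#' @param lfc_threshold Absolute log2 fold-change threshold.
#' @param q_threshold q-value threshold.
#' @param pseudocount Added to both FPKMs before the ratio.
#' @return Character vector of calls in `{"up", "down", "ns"}`.
#' @export
#' @examples
#' de_call(10, 40, 0.01)
de_call <- function(fpkm_control, fpkm_treated, qvalue, lfc_threshold = 1,
                    q_threshold = 0.05, pseudocount = 0) {
  if (any(fpkm_control < 0, na.rm = TRUE) ||
      any(fpkm_treated < 0, na.rm = TRUE)) {
    rlang::abort("FPKM values must be non-negative.")
  }
  if (pseudocount == 0 &&
      any(fpkm_control == 0 | fpkm_treated == 0, na.rm = TRUE)) {
    rlang::abort(paste0(
      "Zero FPKM with pseudocount = 0 gives an undefined fold change; ",
      "supply a pseudocount or filter the genes."
    ))
  }
  lfc <- log2((fpkm_treated + pseudocount) / (fpkm_control + pseudocount))
  dplyr::case_when(
    lfc >= lfc_threshold & qvalue <= q_threshold ~ "up",
    lfc <= -lfc_threshold & qvalue <= q_threshold ~ "down",
    TRUE ~ "ns"
  )
}

#' Call differential expression across all time points of a matrix
#'
#' Expects a wide matrix with a control column `fpkm_ck` and, per time
#' point `<tp>`, paired `fpkm_<tp>` and `q_<tp>` columns (the layout of the
#' drought time-course: `ds_d1` ... `ds_d5`).
#'
#' @param matrix_df Expression tibble (one row per gene, `gene_id` column).
#' @param timepoints Time-point labels; auto-detected from column names
#'   when `NULL`.
#' @inheritParams de_call
#' @return A long tibble with `gene_id`, `timepoint`, `log2_fc`, `qvalue`,
#'   `call`.
#' @export
call_de <- function(matrix_df, timepoints = NULL, lfc_threshold = 1,
                    q_threshold = 0.05, pseudocount = 0) {
  check_columns(matrix_df, c("gene_id", "fpkm_ck"), "expression matrix")
  if (is.null(timepoints)) {
    timepoints <- sub(
      "^fpkm_", "",
      setdiff(grep("^fpkm_", names(matrix_df), value = TRUE), "fpkm_ck")
    )
  }
  purrr::map(timepoints, function(tp) {
    check_columns(matrix_df, paste0(c("fpkm_", "q_"), tp), "expression matrix")
    treated <- matrix_df[[paste0("fpkm_", tp)]]
    q <- matrix_df[[paste0("q_", tp)]]
    tibble::tibble(
      gene_id = matrix_df$gene_id,
      timepoint = tp,
      log2_fc = log2((treated + pseudocount) /
                       (matrix_df$fpkm_ck + pseudocount)),
      qvalue = q,
      call = de_call(matrix_df$fpkm_ck, treated, q, lfc_threshold,
                     q_threshold, pseudocount)
    )
  }) %>% dplyr::bind_rows()
}

#' Tally up-/down-regulated genes per time point
#'
#' Counts `"up"` and `"down"` calls per time point and appends a `"union"`
#' row counting genes called in the given direction at any time point (a
#' gene up at one time point and down at another contributes to both union
#' counts, once each).
#'
#' @param calls Long call tibble from [call_de()].
#' @return A tibble with `timepoint`, `n_up`, `n_down`.
#' @export
tally_de <- function(calls) {
  check_columns(calls, c("gene_id", "timepoint", "call"), "calls")
  per_tp <- calls %>%
    dplyr::group_by(.data$timepoint) %>%
    dplyr::summarise(
      n_up = sum(.data$call == "up"),
      n_down = sum(.data$call == "down"),
      .groups = "drop"
    )
  union_row <- tibble::tibble(
    timepoint = "union",
    n_up = dplyr::n_distinct(calls$gene_id[calls$call == "up"]),
    n_down = dplyr::n_distinct(calls$gene_id[calls$call == "down"])
  )
  dplyr::bind_rows(per_tp, union_row)
}

#' Benjamini-Hochberg adjustment convenience
#'
#' Utility for synthetic or raw-p workflows whose input lacks q-values;
#' wraps [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Raw p-values.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' qPCR relative expression by the 2^-ddCt method
#'
#' `ddct_fold_change()` is the numeric core: per sample,
#' `dCt = target_ct - reference_ct`; `ddCt = dCt_treated - dCt_control`;
#' the relative expression is `2^-ddCt`.
#'
#' @param target_ct_treated,reference_ct_treated Ct values of the target
#'   and reference gene in the treated sample.
#' @param target_ct_control,reference_ct_control Ct values in the control
#'   (calibrator) sample.
#' @return Fold change(s), dimensionless.
#' @export
#' @examples
#' ddct_fold_change(24, 20, 26, 20)  # ddCt = -2 -> 4
ddct_fold_change <- function(target_ct_treated, reference_ct_treated,
                             target_ct_control, reference_ct_control) {
  dct_treated <- target_ct_treated - reference_ct_treated
  dct_control <- target_ct_control - reference_ct_control
  2^-(dct_treated - dct_control)
}

#' @describeIn ddct_fold_change Data-frame verb: computes per-sample fold
#'   changes relative to the mean delta-Ct of the control condition.
#' @param ct A Ct tibble with columns `sample_id`, `condition`, `target_ct`,
#'   `reference_ct`.
#' @param control_condition Label of the calibrator condition.
#' @export
qpcr_relative_expression <- function(ct, control_condition) {
  check_columns(ct, c("sample_id", "condition", "target_ct", "reference_ct"),
    "ct table")
  if (any(!is.finite(ct$target_ct)) || any(!is.finite(ct$reference_ct)) ||
      any(ct$target_ct <= 0) || any(ct$reference_ct <= 0)) {
    rlang::abort("Ct values must be positive and finite.")
  }
  if (!control_condition %in% ct$condition) {
    rlang::abort(sprintf("No samples with condition '%s'.", control_condition))
  }
  dct <- ct$target_ct - ct$reference_ct
  dct_cal <- mean(dct[ct$condition == control_condition])
  ct %>%
    dplyr::mutate(
      delta_ct = dct,
      fold_change = 2^-(dct - dct_cal)
    )
}
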