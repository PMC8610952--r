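#' Published operating points of the two risk models
#'
#' Reported sensitivity/specificity pairs and likelihood ratios for the
#' multi-feature logistic model, the deep model, and the deep model's
#' per-stage breakdown, as printed in the original multi-center ICU study.
#' These are reference constants, not outputs of this package: the fitted
#' score thresholds behind them (56, 70, 72) are artifacts of that study's
#' restricted-access training data and are re-derived per run here.
#'
#' `lr_consistent` marks whether the printed likelihood ratios agree with
#' the printed sensitivity/specificity through the identities
#' `LR+ = sens/(1-spec)`, `LR- = (1-sens)/spec`; three printed entries do
#' not (the multi-feature fixed-sensitivity LR-, and the deep model's
#' fixed-sensitivity LR- and knee LR+), and consistency checks skip the
#' offending value.
#'
#' @return data.frame with `model`, `working_point` (or stage),
#'   `sensitivity`, `specificity`, printed `lr_pos`/`lr_neg`, number of
#'   printed decimals `digits`, and flags `lr_pos_consistent`,
#'   `lr_neg_consistent`.
#' @export
published_operating_points <- function() {
  data.frame(
    model = c("logistic_multi", "logistic_multi", "deep", "deep",
              "deep_stage2", "deep_stage3"),
    working_point = c("sensitivity_80", "knee", "sensitivity_80", "knee",
                      "stage_2", "stage_3"),
    sensitivity = c(0.800, 0.774, 0.800, 0.820, 0.800, 0.830),
    specificity = c(0.750, 0.780, 0.840, 0.820, 0.836, 0.836),
    lr_pos = c(3.20, 3.52, 5.00, 4.50, 4.87, 5.06),
    lr_neg = c(0.31, 0.29, 0.20, 0.22, 0.24, 0.20),
    digits = 2L,
    lr_pos_consistent = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    lr_neg_consistent = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
}

#' Published single-feature rules
#'
#' Window length, alarm threshold (ml/kg/h) and reported test
#' characteristics of the single-feature rules for every window size 2-12;
#' the 7-hour window at 0.372 ml/kg/h is the study's headline rule. All
#' printed likelihood ratios in this table are consistent with their
#' sensitivity/specificity to three decimals.
#'
#' @return data.frame with `window_h`, `threshold_mlkg_h`, `sensitivity`,
#'   `specificity`, `precision`, `lr_pos`, `lr_neg`, `auroc`.
#' @export
published_single_feature_rules <- function() {
  data.frame(
    window_h = 2:12,
    threshold_mlkg_h = c(0.251, 0.288, 0.311, 0.341, 0.362, 0.372, 0.407,
                         0.427, 0.457, 0.471, 0.487),
    sensitivity = c(0.733, 0.733, 0.739, 0.738, 0.739, 0.755, 0.743, 0.749,
                    0.744, 0.750, 0.753),
    specificity = c(0.733, 0.733, 0.741, 0.741, 0.741, 0.759, 0.741, 0.750,
                    0.741, 0.750, 0.750),
    precision = c(0.008, 0.008, 0.009, 0.010, 0.011, 0.012, 0.012, 0.012,
                  0.013, 0.012, 0.013),
    lr_pos = c(2.745, 2.745, 2.853, 2.849, 2.853, 3.133, 2.869, 2.996,
               2.873, 3.000, 3.012),
    lr_neg = c(0.364, 0.364, 0.352, 0.354, 0.352, 0.323, 0.347, 0.335,
               0.345, 0.333, 0.329),
    auroc = c(0.786, 0.786, 0.798, 0.804, 0.810, 0.813, 0.817, 0.815,
              0.817, 0.818, 0.817)
  )
}
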