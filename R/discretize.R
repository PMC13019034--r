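# Percentile discretization of continuous study variables into the three
# ordered states low / moderate / high.

#' Percentile discretization rule
#'
#' Describes how continuous scores are mapped to ordered categories: values
#' below the lower percentile cut-off are "low", values above the upper
#' cut-off are "high", and everything in the closed middle band (cut-offs
#' included) is "moderate".
#'
#' @param p_low,p_high Percentiles (0-100) for the lower and upper cut-offs;
#'   defaults 25 and 75.
#' @param state_labels Three ordered labels, lowest band first.
#' @param percentile_method Quantile estimator type passed to
#'   [stats::quantile()]; the default 7 is linear interpolation of order
#'   statistics.
#' @return An object of class `discretization_rule`.
#' @export
#' @examples
#' discretization_rule()
discretization_rule <- function(p_low = 25, p_high = 75,
                                state_labels = c("low", "moderate", "high"),
                                percentile_method = 7) {
  if (!is_finite_num(c(p_low, p_high)) || p_low <= 0 || p_high >= 100 || p_low >= p_high) {
    stop_input("percentiles must satisfy 0 < p_low < p_high < 100")
  }
  if (length(state_labels) != 3 || anyDuplicated(state_labels)) {
    stop_input("exactly three distinct, ordered state labels are required")
  }
  structure(list(p_low = p_low, p_high = p_high, state_labels = state_labels,
                 percentile_method = percentile_method),
            class = "discretization_rule")
}

#' @export
print.discretization_rule <- function(x, ...) {
  cat(sprintf("Discretization rule: %s < P%g <= %s <= P%g < %s (quantile type %d)\n",
              x$state_labels[1], x$p_low, x$state_labels[2], x$p_high,
              x$state_labels[3], as.integer(x$percentile_method)))
  invisible(x)
}

#' Percentile cut-offs for a sample
#'
#' @param values Numeric vector; at least 4 finite values.
#' @param rule A [discretization_rule()].
#' @return Named numeric vector `c(c_low, c_high)`.
#' @export
#' @examples
#' percentile_cutoffs(1:8)  # c(2.75, 6.25)
percentile_cutoffs <- function(values, rule = discretization_rule()) {
  if (length(values) < 4) stop_input("need at least 4 values to place percentile cut-offs")
  if (!is_finite_num(values)) stop_input("values must be finite")
  q <- stats::quantile(values, probs = c(rule$p_low, rule$p_high) / 100,
                       type = rule$percentile_method, names = FALSE)
  c(c_low = q[1], c_high = q[2])
}

#' Categorize values against percentile cut-offs
#'
#' Values strictly below `c_low` are "low", strictly above `c_high` are
#' "high"; values at or between the cut-offs (the closed middle band) are
#' "moderate". Tied values always receive the same label.
#'
#' @param value Numeric vector.
#' @param cutoffs Numeric `c(c_low, c_high)` as from [percentile_cutoffs()].
#' @param rule A [discretization_rule()] supplying the labels.
#' @return Character vector of state labels.
#' @export
#' @examples
#' categorize(c(2, 2.75, 5, 6.25, 7), percentile_cutoffs(1:8))
categorize <- function(value, cutoffs, rule = discretization_rule()) {
  if (!is_finite_num(value)) stop_input("values must be finite")
  if (length(cutoffs) != 2 || !is_finite_num(cutoffs) || cutoffs[1] > cutoffs[2]) {
    stop_input("cutoffs must be finite with c_low <= c_high")
  }
  lab <- rule$state_labels
  out <- rep(lab[2], length(value))
  out[value < cutoffs[1]] <- lab[1]
  out[value > cutoffs[2]] <- lab[3]
  out
}

# canonical node names and the patient-table columns they come from
.study_vars <- c("lden", "sensitivity", "annoyance", "comfort", "itl")
.study_cols <- c(lden = "lden_db", sensitivity = "wnss", annoyance = "annoyance_vas",
                 comfort = "comfort", itl = "itl_vas")

#' Categorize a patient cohort
#'
#' Computes per-variable percentile cut-offs over the whole cohort, then
#' applies them row-wise, mapping the five continuous study measures to
#' low/moderate/high states. Acoustic comfort is kept on its native scale
#' (higher = more comfortable): "low" comfort is the bottom quartile of
#' comfort scores, with no reverse-coding.
#'
#' @param records Data frame with columns `patient_id`, `lden_db`, `wnss`,
#'   `comfort`, `annoyance_vas`, `itl_vas` (see [read_patient_table()]).
#' @param rule A [discretization_rule()].
#' @return A list with `categories` (data frame `patient_id` plus one factor
#'   column per study variable, levels low < moderate < high) and `cutoffs`
#'   (per-variable cut-off matrix).
#' @export
categorize_cohort <- function(records, rule = discretization_rule()) {
  if (!is.data.frame(records) || nrow(records) == 0) stop_input("empty cohort")
  miss <- setdiff(unname(.study_cols), names(records))
  if (length(miss)) stop_input("patient table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"patient_id" %in% names(records)) {
    records$patient_id <- sprintf("P%04d", seq_len(nrow(records)))
  }
  for (v in .study_vars) {
    col <- records[[.study_cols[[v]]]]
    bad <- which(!is.finite(col))
    if (length(bad)) {
      stop_input("missing or non-finite value for patient ",
                 records$patient_id[bad[1]], ", field ", .study_cols[[v]])
    }
  }
  cuts <- vapply(.study_vars,
                 function(v) percentile_cutoffs(records[[.study_cols[[v]]]], rule),
                 numeric(2))
  cats <- data.frame(patient_id = records$patient_id, stringsAsFactors = FALSE)
  for (v in .study_vars) {
    cats[[v]] <- factor(categorize(records[[.study_cols[[v]]]], cuts[, v], rule),
                        levels = rule$state_labels)
  }
  list(categories = cats, cutoffs = cuts)
}
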