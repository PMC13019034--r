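# Evidence scenarios and delta-p sensitivity analysis.
#
# Delta-p for a target state is the updated posterior probability of that
# state minus its baseline (prior) probability, reported in percentage
# points; a positive sign means the state became more probable after the
# evidence was set.

#' Define an evidence scenario
#'
#' @param name Scenario label.
#' @param evidence Named character vector or list mapping variables to
#'   hard-evidence states (must be non-empty). "X high 100%" means
#'   `c(X = "high")`; soft evidence is not supported.
#' @return An object of class `evidence_scenario`.
#' @export
#' @examples
#' evidence_scenario("lden_high", c(lden = "high"))
evidence_scenario <- function(name, evidence) {
  evidence <- unlist(evidence)
  if (length(evidence) == 0) stop_input("scenario evidence must be non-empty")
  if (is.null(names(evidence)) || any(names(evidence) == "")) {
    stop_input("scenario evidence must be a named variable = state mapping")
  }
  structure(list(name = as.character(name), evidence = evidence),
            class = "evidence_scenario")
}

#' The five default study scenarios
#'
#' Hard-evidence scenarios on the two exogenous drivers: exposure high,
#' sensitivity high, exposure high with sensitivity low, exposure low with
#' sensitivity high, and both high.
#'
#' @return List of [evidence_scenario()] objects.
#' @export
default_scenarios <- function() {
  list(
    evidence_scenario("lden_high", c(lden = "high")),
    evidence_scenario("sensitivity_high", c(sensitivity = "high")),
    evidence_scenario("lden_high_sensitivity_low", c(lden = "high", sensitivity = "low")),
    evidence_scenario("lden_low_sensitivity_high", c(lden = "low", sensitivity = "high")),
    evidence_scenario("lden_high_sensitivity_high", c(lden = "high", sensitivity = "high"))
  )
}

#' Read / write scenario files
#'
#' Scenario files are JSON lists of `{"name": ..., "evidence": {var: state}}`.
#'
#' @param path File path.
#' @return `read_scenarios()`: a list of [evidence_scenario()] objects.
#' @export
read_scenarios <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) evidence_scenario(s$name, unlist(s$evidence)))
}

#' @rdname read_scenarios
#' @param scenarios List of [evidence_scenario()] objects.
#' @export
write_scenarios <- function(scenarios, path) {
  jsonlite::write_json(
    lapply(scenarios, function(s) list(name = s$name, evidence = as.list(s$evidence))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Delta-p between a baseline and an updated distribution
#'
#' @param baseline,updated Named probability vectors over the same states
#'   (same variable).
#' @return Named numeric vector: `100 * (updated - baseline)` per state, in
#'   percentage points.
#' @export
#' @examples
#' delta_p(c(low = 0.346, moderate = 0.313, high = 0.341),
#'         c(low = 0.252, moderate = 0.284, high = 0.464))
delta_p <- function(baseline, updated) {
  if (is.null(names(baseline)) || is.null(names(updated)) ||
      !identical(sort(names(baseline)), sort(names(updated)))) {
    stop_input("baseline and updated distributions must share the same state set")
  }
  100 * (updated[names(baseline)] - baseline)
}

#' Run evidence scenarios and build delta-p reports
#'
#' Computes the baseline (prior) marginals once, then for each scenario the
#' updated posterior marginals and the per-state delta-p. Each report also
#' carries an influence ranking of non-evidence (variable, state) pairs by
#' decreasing absolute delta-p.
#'
#' @param net A [discrete_bn()].
#' @param scenarios List of [evidence_scenario()] objects.
#' @return List of objects of class `delta_p_report`, one per scenario, each
#'   with elements `scenario`, `evidence`, `baseline`, `updated`, `delta`
#'   (percentage points) and `ranking`.
#' @export
#' @examples
#' run_scenarios(default_generating_net(), default_scenarios())[[1]]
run_scenarios <- function(net, scenarios) {
  if (length(scenarios) == 0) return(list())
  baseline <- infer_marginals(net)
  lapply(scenarios, function(sc) {
    if (!inherits(sc, "evidence_scenario")) {
      stop_input("scenarios must be evidence_scenario objects")
    }
    updated <- infer_marginals(net, sc$evidence)
    delta <- lapply(names(baseline), function(v) delta_p(baseline[[v]], updated[[v]]))
    names(delta) <- names(baseline)
    free <- setdiff(names(baseline), names(sc$evidence))
    rk <- do.call(rbind, lapply(free, function(v) {
      data.frame(variable = v, state = names(delta[[v]]),
                 delta_pp = as.numeric(delta[[v]]), stringsAsFactors = FALSE)
    }))
    rk <- rk[order(-abs(rk$delta_pp)), ]
    rownames(rk) <- NULL
    structure(list(scenario = sc$name, evidence = sc$evidence,
                   baseline = baseline, updated = updated,
                   delta = delta, ranking = rk),
              class = "delta_p_report")
  })
}

#' Format a delta-p report as table rows
#'
#' Renders one row per (variable, state) with the delta-p formatted to one
#' decimal percentage point and an explicit sign; evidence variables are
#' rendered as `"-"` (their change is trivially 100 minus the baseline for
#' the instantiated state).
#'
#' @param report A `delta_p_report` from [run_scenarios()].
#' @return Data frame with columns `variable`, `state`, `delta_p`.
#' @export
format_report <- function(report) {
  if (!inherits(report, "delta_p_report")) stop_input("not a delta_p_report")
  rows <- do.call(rbind, lapply(names(report$delta), function(v) {
    d <- report$delta[[v]]
    txt <- if (v %in% names(report$evidence)) rep("-", length(d)) else format_pp(d)
    data.frame(variable = v, state = names(d), delta_p = txt, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' @export
print.delta_p_report <- function(x, ...) {
  cat(sprintf("Delta-p report: %s  (evidence: %s)\n", x$scenario,
              paste(names(x$evidence), x$evidence, sep = " = ", collapse = ", ")))
  print(format_report(x), row.names = FALSE)
  invisible(x)
}
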