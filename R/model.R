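# The user-facing model: fit the study's discrete Bayesian network to a
# patient cohort and query it.

#' Fit the hospital-noise Bayesian network to a patient cohort
#'
#' Takes a patient-level table, discretizes the five continuous study
#' measures (Lden, noise sensitivity, annoyance, acoustic comfort, intention
#' to leave) into low/moderate/high states at the sample P25/P75 cut-offs,
#' and fits the conditional probability tables of a discrete Bayesian
#' network over the given structure by (optionally smoothed) relative
#' frequency. If `data` already holds categorical state columns named
#' `lden`, `sensitivity`, `annoyance`, `comfort`, `itl`, the discretization
#' step is skipped.
#'
#' @param data Data frame: either continuous columns `lden_db`, `wnss`,
#'   `annoyance_vas`, `comfort`, `itl_vas` (plus optional `patient_id`), or
#'   categorical state columns named after the network variables.
#' @param structure Network topology, a [bn_structure()]; defaults to the
#'   mediating study structure [study_structure()].
#' @param rule Discretization rule, a [discretization_rule()].
#' @param pseudocount Laplace smoothing count for CPT estimation (default 0).
#' @return An object of class `noisebn` with components `call`, `n`,
#'   `structure`, `rule`, `cutoffs` (`NULL` when data came in categorical),
#'   `continuous`, `categories`, `net` (the fitted [discrete_bn()]) and
#'   `marginals` (baseline marginals).
#' @seealso [predict.noisebn()], [simulate.noisebn()], [run_scenarios()]
#' @export
#' @examples
#' cohort <- sample_cohort(generator_config(n_patients = 300, seed = 1))
#' fit <- noisebn(cohort$patients)
#' fit
#' predict(fit, evidence = c(lden = "high"))
noisebn <- function(data, structure = study_structure(),
                    rule = discretization_rule(), pseudocount = 0) {
  if (!is.data.frame(data) || nrow(data) == 0) stop_input("data must be a non-empty data frame")
  vars <- names(structure$variables)
  cutoffs <- NULL
  continuous <- NULL
  if (all(vars %in% names(data))) {
    categories <- data[vars]
  } else {
    disc <- categorize_cohort(data, rule)
    cutoffs <- disc$cutoffs
    continuous <- data
    categories <- disc$categories[setdiff(names(disc$categories), "patient_id")]
  }
  net <- fit_cpts(categories, structure, pseudocount)
  structure(list(call = match.call(), n = nrow(data), structure = structure,
                 rule = rule, pseudocount = pseudocount, cutoffs = cutoffs,
                 continuous = continuous, categories = categories,
                 net = net, marginals = infer_marginals(net)),
            class = "noisebn")
}

#' @export
print.noisebn <- function(x, ...) {
  cat("Hospital-noise Bayesian network fit\n")
  cat(sprintf("  n = %d patients, %d variables, %d edges, pseudocount = %g\n",
              x$n, length(x$structure$variables), nrow(x$structure$edges),
              x$pseudocount))
  if (!is.null(x$cutoffs)) {
    cat(sprintf("  cut-offs (P%g/P%g):\n", x$rule$p_low, x$rule$p_high))
    for (v in colnames(x$cutoffs)) {
      cat(sprintf("    %-12s %.2f / %.2f\n", v, x$cutoffs[1, v], x$cutoffs[2, v]))
    }
  }
  print(x$marginals)
  invisible(x)
}

#' Summarize a fitted hospital-noise network
#'
#' @param object A [noisebn()] fit.
#' @param scenarios Evidence scenarios for the delta-p section; defaults to
#'   [default_scenarios()].
#' @param ... Unused.
#' @return An object of class `summary.noisebn` with the descriptive table,
#'   baseline marginals and delta-p reports.
#' @export
summary.noisebn <- function(object, scenarios = default_scenarios(), ...) {
  structure(list(fit = object,
                 descriptives = descriptives_table(object),
                 reports = run_scenarios(object$net, scenarios)),
            class = "summary.noisebn")
}

#' @export
print.summary.noisebn <- function(x, ...) {
  print(x$fit)
  cat("\nDescriptives:\n")
  print(x$descriptives, row.names = FALSE)
  cat("\nDelta-p (percentage points; evidence variables shown as '-'):\n")
  print(delta_p_table(x$reports), row.names = FALSE)
  invisible(x)
}

#' Extract the fitted conditional probability tables
#'
#' @param object A [noisebn()] fit.
#' @param ... Unused.
#' @return Named list of CPT arrays (child states on the first dimension).
#' @export
coef.noisebn <- function(object, ...) {
  lapply(object$net$cpts, `[[`, "prob")
}

#' Posterior marginals or delta-p for a fitted network
#'
#' @param object A [noisebn()] fit.
#' @param evidence Named mapping of variables to observed states; `NULL` for
#'   the baseline marginals.
#' @param type `"marginals"` for the posterior distributions, `"delta_p"`
#'   for the change against the baseline in percentage points.
#' @param ... Unused.
#' @return A `bn_marginals` list, or for `type = "delta_p"` a named list of
#'   per-state changes in percentage points.
#' @export
predict.noisebn <- function(object, evidence = NULL,
                            type = c("marginals", "delta_p"), ...) {
  type <- match.arg(type)
  updated <- infer_marginals(object$net, evidence)
  if (type == "marginals") return(updated)
  if (is.null(evidence)) stop_input("delta_p prediction needs evidence")
  out <- lapply(names(object$marginals),
                function(v) delta_p(object$marginals[[v]], updated[[v]]))
  stats::setNames(out, names(object$marginals))
}

#' Simulate categorical records from a fitted network
#'
#' Forward-samples complete state assignments from the fitted conditional
#' probability tables.
#'
#' @param object A [noisebn()] fit.
#' @param nsim Number of records.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame of factor columns, one per variable.
#' @export
simulate.noisebn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sample_states(object$net, nsim)
}

#' Plot delta-p under an evidence scenario
#'
#' Horizontal bar chart of the per-state probability changes (percentage
#' points) for all non-evidence variables.
#'
#' @param x A [noisebn()] fit.
#' @param evidence Named evidence mapping; default: exposure high.
#' @param ... Passed to [graphics::barplot()].
#' @return The delta-p values, invisibly.
#' @export
plot.noisebn <- function(x, evidence = c(lden = "high"), ...) {
  d <- predict(x, evidence = evidence, type = "delta_p")
  free <- setdiff(names(d), names(evidence))
  vals <- unlist(lapply(free, function(v) {
    stats::setNames(as.numeric(d[[v]]), paste(v, names(d[[v]])))
  }))
  old <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(rev(vals), horiz = TRUE, las = 1,
                    xlab = "delta-p (percentage points)",
                    main = paste(names(evidence), evidence, sep = " = ", collapse = ", "),
                    ...)
  graphics::abline(v = 0)
  invisible(d)
}
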