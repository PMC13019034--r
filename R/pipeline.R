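# Reporting pipeline: descriptive, marginal, updated-distribution and
# delta-p tables, plus the file-producing commands wrapped by the CLI script.

#' Descriptive statistics table
#'
#' One row per variable and state with the category frequency, the percent
#' (one decimal, integers printed without decimal), and -- when continuous
#' scores are available -- the variable's overall mean and SD.
#'
#' @param fit A [noisebn()] fit, or a list with elements `categories` (state
#'   data frame) and optionally `continuous` (patient table).
#' @return Data frame `variable`, `level`, `n`, `percent`, `mean`, `sd`.
#' @export
descriptives_table <- function(fit) {
  cats <- fit$categories
  cont <- fit$continuous
  rows <- lapply(intersect(.study_vars, names(cats)), function(v) {
    tab <- table(factor(cats[[v]], levels = .states3))
    out <- data.frame(variable = v, level = names(tab), n = as.integer(tab),
                      percent = format_percent(100 * as.integer(tab) / sum(tab)),
                      stringsAsFactors = FALSE)
    if (!is.null(cont) && .study_cols[[v]] %in% names(cont)) {
      out$mean <- round(mean(cont[[.study_cols[[v]]]]), 2)
      out$sd <- round(stats::sd(cont[[.study_cols[[v]]]]), 2)
    } else {
      out$mean <- NA_real_
      out$sd <- NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline marginal table
#'
#' @param net A [discrete_bn()] or [noisebn()] fit.
#' @param digits Decimals (default 3); rows are rounding-repaired so each
#'   variable's printed probabilities sum to 1.
#' @return Data frame `variable`, `state`, `probability`.
#' @export
marginals_table <- function(net, digits = 3) {
  if (inherits(net, "noisebn")) net <- net$net
  m <- infer_marginals(net)
  out <- do.call(rbind, lapply(names(m), function(v) {
    data.frame(variable = v, state = names(m[[v]]),
               probability = round_probs_repair(m[[v]], digits),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Updated distributions under scenarios
#'
#' @param net A [discrete_bn()] or [noisebn()] fit.
#' @param scenarios List of [evidence_scenario()] objects.
#' @param digits Decimals (default 3).
#' @return Data frame `variable`, `state`, then one probability column per
#'   scenario.
#' @export
updated_table <- function(net, scenarios = default_scenarios(), digits = 3) {
  if (inherits(net, "noisebn")) net <- net$net
  reports <- run_scenarios(net, scenarios)
  out <- NULL
  for (rp in reports) {
    col <- unlist(lapply(names(rp$updated),
                         function(v) round_probs_repair(rp$updated[[v]], digits)))
    if (is.null(out)) {
      out <- data.frame(
        variable = rep(names(rp$updated), times = vapply(rp$updated, length, 1L)),
        state = unlist(lapply(rp$updated, names), use.names = FALSE),
        stringsAsFactors = FALSE)
    }
    out[[rp$scenario]] <- as.numeric(col)
  }
  rownames(out) <- NULL
  out
}

#' Delta-p table over scenarios
#'
#' @param reports List of reports from [run_scenarios()].
#' @return Data frame `variable`, `state`, then one formatted delta-p column
#'   per scenario (evidence variables rendered `"-"`).
#' @export
delta_p_table <- function(reports) {
  out <- NULL
  for (rp in reports) {
    f <- format_report(rp)
    if (is.null(out)) out <- f[c("variable", "state")]
    out[[rp$scenario]] <- f$delta_p
  }
  out
}

.write_provenance <- function(out_dir, config_list) {
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config_list, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  prov <- list(
    package = "noisebn",
    version = as.character(utils::packageVersion("noisebn")),
    config_file = "config.json",
    config_md5 = unname(tools::md5sum(cfg_path))
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg_path)
}

#' Generate a synthetic cohort and write it to disk
#'
#' Writes `patients.csv`, `noise_log.csv`, `true_categories.csv`, the
#' generating network (`generating_net.json`), the configuration echo and a
#' provenance record to `out_dir`. With the seed and configuration recorded,
#' a rerun reproduces the files bit for bit.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  if (!inherits(config, "generator_config")) stop_input("config must be a generator_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sample_cohort(config)
  pat <- cohort$patients
  num <- unname(.study_cols)
  pat[num] <- lapply(pat[num], round, digits = 4)
  files <- c(
    patients = file.path(out_dir, "patients.csv"),
    noise_log = file.path(out_dir, "noise_log.csv"),
    true_categories = file.path(out_dir, "true_categories.csv"),
    generating_net = file.path(out_dir, "generating_net.json")
  )
  write_patient_table(pat, files["patients"])
  write_noise_log(cohort$noise_logs, files["noise_log"])
  utils::write.table(cohort$true_categories, files["true_categories"],
                     sep = ",", row.names = FALSE, quote = FALSE)
  write_network_spec(config$generating_net, files["generating_net"])
  .write_provenance(out_dir, list(
    command = "simulate", n_patients = config$n_patients, seed = config$seed,
    marginal_params = config$marginal_params
  ))
  invisible(files)
}

#' Run the full analysis pipeline and write report tables
#'
#' Fits the network to a patient table and writes four report tables --
#' descriptives, baseline marginals, updated distributions per scenario, and
#' the delta-p table -- plus a log of the cut-offs and a provenance record.
#'
#' @param patients Patient table (data frame) or path to one.
#' @param out_dir Output directory (created if needed).
#' @param structure,rule,pseudocount Passed to [noisebn()].
#' @param scenarios List of [evidence_scenario()] objects.
#' @param noise_log Optional noise log (data frame or path); when given a
#'   per-location Lden table is written too.
#' @param verbose Log progress to standard error.
#' @return The fitted [noisebn()] model, invisibly; file paths in attribute
#'   `"files"`.
#' @export
cmd_run <- function(patients, out_dir, structure = study_structure(),
                    rule = discretization_rule(), pseudocount = 0,
                    scenarios = default_scenarios(), noise_log = NULL,
                    verbose = FALSE) {
  if (is.character(patients)) patients <- read_patient_table(patients)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[noisebn] ", ...)
  say("fitting network to ", nrow(patients), " patients")
  fit <- noisebn(patients, structure = structure, rule = rule, pseudocount = pseudocount)
  if (!is.null(fit$cutoffs)) {
    say("cut-offs: ", paste(colnames(fit$cutoffs),
                            apply(round(fit$cutoffs, 3), 2, paste, collapse = "/"),
                            sep = " = ", collapse = "; "))
  }
  reports <- run_scenarios(fit$net, scenarios)
  files <- c(
    descriptives = file.path(out_dir, "descriptives.csv"),
    marginals = file.path(out_dir, "marginals.csv"),
    updated = file.path(out_dir, "updated.csv"),
    delta_p = file.path(out_dir, "delta_p.csv"),
    network = file.path(out_dir, "fitted_net.json")
  )
  wt <- function(df, path) utils::write.table(df, path, sep = ",",
                                              row.names = FALSE, quote = FALSE)
  wt(descriptives_table(fit), files["descriptives"])
  wt(marginals_table(fit$net), files["marginals"])
  wt(updated_table(fit$net, scenarios), files["updated"])
  wt(delta_p_table(reports), files["delta_p"])
  write_network_spec(fit$net, files["network"])
  if (!is.null(noise_log)) {
    if (is.character(noise_log)) noise_log <- read_noise_log(noise_log)
    files["lden"] <- file.path(out_dir, "lden_by_location.csv")
    wt(lden_by_location(noise_log), files["lden"])
  }
  .write_provenance(out_dir, list(
    command = "run", n = nrow(patients), pseudocount = pseudocount,
    rule = unclass(rule),
    cutoffs = if (!is.null(fit$cutoffs)) as.data.frame(t(fit$cutoffs)),
    edges = apply(structure$edges, 1, paste, collapse = "->"),
    scenarios = lapply(scenarios, function(s) list(name = s$name,
                                                   evidence = as.list(s$evidence)))
  ))
  say("wrote ", length(files), " report files to ", out_dir)
  attr(fit, "files") <- files
  invisible(fit)
}

#' Per-location Lden report
#'
#' @param noise_log Noise log (data frame or path).
#' @param out Optional output path for the table.
#' @return The per-location Lden data frame (levels rounded to 2 decimals).
#' @export
cmd_lden <- function(noise_log, out = NULL) {
  if (is.character(noise_log)) noise_log <- read_noise_log(noise_log)
  tab <- lden_by_location(noise_log)
  if (!is.null(out)) {
    utils::write.table(tab, out, sep = ",", row.names = FALSE, quote = FALSE)
  }
  tab
}

#' Bundled reference distributions for the hospital-noise cohort
#'
#' Loads the baseline marginal distributions and the updated distributions
#' under the five evidence scenarios that are bundled with the package as
#' worked-example inputs (see the package README). Useful for exercising
#' [delta_p()] without refitting anything.
#'
#' @return List with `marginals` (named list of probability vectors) and
#'   `updated` (named list of such lists, one per scenario).
#' @export
#' @examples
#' ref <- reference_distributions()
#' delta_p(ref$marginals$annoyance, ref$updated$lden_high$annoyance)
reference_distributions <- function() {
  md <- utils::read.csv(system.file("extdata", "reference_marginals.csv",
                                    package = "noisebn"), stringsAsFactors = FALSE)
  ud <- utils::read.csv(system.file("extdata", "reference_updated.csv",
                                    package = "noisebn"), stringsAsFactors = FALSE)
  to_dists <- function(df) {
    out <- lapply(split(df, df$variable)[unique(df$variable)], function(d) {
      stats::setNames(d$probability, d$state)
    })
    out[intersect(.study_vars, names(out))]
  }
  list(
    marginals = to_dists(md),
    updated = lapply(split(ud, ud$scenario)[unique(ud$scenario)], to_dists)
  )
}
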