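test_that("the generator is a deterministic function of its configuration", {
  cfg <- generator_config(n_patients = 120, seed = 9)
  a <- sample_cohort(cfg)
  b <- sample_cohort(generator_config(n_patients = 120, seed = 9))
  expect_identical(a$patients, b$patients)
  expect_identical(a$true_categories, b$true_categories)
  expect_identical(a$noise_logs, b$noise_logs)
  c <- sample_cohort(generator_config(n_patients = 120, seed = 10))
  expect_false(identical(a$patients, c$patients))
  expect_error(generator_config(n_patients = 2), "n_patients")
})

test_that("the default generating net reproduces the reference baseline marginals", {
  net <- default_generating_net()
  prior <- infer_marginals(net)
  ref <- reference_distributions()$marginals
  for (v in study_vars) {
    expect_equal(as.numeric(prior[[v]]), as.numeric(ref[[v]]), tolerance = 1e-9)
  }
})

test_that("every CPT row of the default net is stochastically ordered", {
  net <- default_generating_net()
  cum2 <- function(p) cumsum(p)[1:2]
  for (v in c("annoyance", "comfort")) {
    pr <- net$cpts[[v]]$prob
    sign <- if (v == "annoyance") 1 else -1
    for (j in 1:3) for (i in 1:2) {
      # raising either parent shifts the child in the expected direction
      expect_true(all(sign * (cum2(pr[, i + 1, j]) - cum2(pr[, i, j])) <= 1e-12))
      expect_true(all(sign * (cum2(pr[, j, i + 1]) - cum2(pr[, j, i])) <= 1e-12))
    }
  }
  pr <- net$cpts$itl$prob  # parents: annoyance (up), comfort (down)
  for (j in 1:3) for (i in 1:2) {
    expect_true(all(cum2(pr[, i + 1, j]) - cum2(pr[, i, j]) <= 1e-12))
    expect_true(all(cum2(pr[, j, i + 1]) - cum2(pr[, j, i]) >= -1e-12))
  }
})

test_that("delta-p signs on the default net follow the monotone exposure pattern", {
  reports <- run_scenarios(default_generating_net(), default_scenarios())
  names(reports) <- vapply(reports, `[[`, "", "scenario")
  for (nm in c("lden_high", "sensitivity_high", "lden_high_sensitivity_high")) {
    d <- reports[[nm]]$delta
    expect_gt(d$annoyance[["high"]], 0)
    expect_lt(d$annoyance[["low"]], 0)
    expect_gt(d$comfort[["low"]], 0)
    expect_lt(d$comfort[["high"]], 0)
    expect_gt(d$itl[["high"]], 0)
    expect_lt(d$itl[["low"]], 0)
  }
  # joint evidence is stronger than either single factor
  expect_gt(reports$lden_high_sensitivity_high$delta$annoyance[["high"]],
            max(reports$lden_high$delta$annoyance[["high"]],
                reports$sensitivity_high$delta$annoyance[["high"]]))
})

test_that("continuous scores stay in range with ordered category bands", {
  cfg <- generator_config(n_patients = 2000, seed = 4)
  coh <- sample_cohort(cfg)
  mp <- default_marginal_params()
  cols <- c("lden_db", "wnss", "annoyance_vas", "comfort", "itl_vas")
  for (i in 1:5) {
    x <- coh$patients[[cols[i]]]
    expect_true(all(x >= mp$min[i] & x <= mp$max[i]))
    # scores grouped by true category are strictly separated bands
    grp <- split(x, coh$true_categories[[mp$variable[i]]])
    expect_lt(max(grp$low), min(grp$moderate))
    expect_lt(max(grp$moderate), min(grp$high))
  }
  map <- category_score_map(cfg)
  expect_equal(nrow(map), 15)
  expect_true(all(map$mean[map$state == "low"] < map$mean[map$state == "high"]))
})

test_that("quartile relabelling recovers the true categories away from the cut-offs", {
  coh <- sample_cohort(generator_config(n_patients = 10000, seed = 1))
  d <- categorize_cohort(coh$patients)
  for (v in study_vars) {
    agree <- mean(as.character(d$categories[[v]]) ==
                    as.character(coh$true_categories[[v]]))
    expect_gte(agree, 0.8)
  }
})

test_that("per-patient noise logs reproduce the continuous Lden", {
  coh <- sample_cohort(generator_config(n_patients = 100, seed = 2))
  for (i in sample(100, 20)) {
    id <- coh$patients$patient_id[i]
    log <- coh$noise_logs[coh$noise_logs$location_id == id, ]
    expect_equal(nrow(log), 8)
    lden <- as.numeric(compute_lden(period_levels_from_log(log)))
    expect_equal(lden, coh$patients$lden_db[i], tolerance = 0.1)
  }
})

test_that("injected missingness masks at the requested rate and blocks fitting", {
  coh <- sample_cohort(generator_config(n_patients = 2000, seed = 5))
  expect_identical(inject_missingness(coh, 0), coh)
  masked <- inject_missingness(coh, 0.1, seed = 5)
  cols <- c("lden_db", "wnss", "annoyance_vas", "comfort", "itl_vas")
  rate <- mean(is.na(as.matrix(masked$patients[cols])))
  se <- sqrt(0.1 * 0.9 / (2000 * 5))
  expect_lt(abs(rate - 0.1), 4 * se)
  expect_error(categorize_cohort(masked$patients), "missing")
  cats <- masked$true_categories[study_vars]
  cats$lden[1] <- NA
  expect_error(fit_cpts(cats, study_structure()), "missing state")
  expect_error(inject_missingness(coh, 1), "rate")
})

test_that("delta-p recovery from refit cohorts is bounded by CPT sampling error", {
  # single-evidence scenarios aggregate over CPT rows and recover within 1 pp;
  # double-evidence posteriors are raw CPT rows, bounded by the TV-scale error
  gen <- default_generating_net()
  coh <- sample_cohort(generator_config(n_patients = 50000, seed = 1))
  fit <- fit_cpts(coh$true_categories[study_vars], study_structure())
  rg <- run_scenarios(gen, default_scenarios())
  rf <- run_scenarios(fit, default_scenarios())
  for (i in seq_along(rg)) {
    err <- max(abs(unlist(rg[[i]]$delta) - unlist(rf[[i]]$delta)))
    expect_lt(err, if (length(rg[[i]]$evidence) == 1) 1 else 2.5)
  }
  # the discretized route attenuates but preserves the direction of effects
  refit <- fit_cpts(categorize_cohort(coh$patients)$categories[study_vars],
                    study_structure())
  rr <- run_scenarios(refit, default_scenarios())
  names(rr) <- names(rg) <- vapply(rg, `[[`, "", "scenario")
  for (nm in c("lden_high", "sensitivity_high", "lden_high_sensitivity_high")) {
    big <- abs(unlist(rg[[nm]]$delta)) > 2
    expect_true(all(sign(unlist(rr[[nm]]$delta))[big] ==
                      sign(unlist(rg[[nm]]$delta))[big]))
  }
})
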