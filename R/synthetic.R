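# Synthetic cohort generator.
#
# Design: categorical ground truth first, continuous scores second. Each
# patient's five ternary states are forward-sampled from a known generating
# network; each state is then back-mapped to a continuous score by inverse-CDF
# sampling from the corresponding band of a moment-matched truncated normal.
# Because the bands partition the truncated normal at exactly the
# generating-net marginal masses, the mixture over categories IS that
# truncated normal, so cohort means and SDs hit the configured targets in
# expectation and CPT ground truth is exact for parameter-recovery tests.

# ---- truncated normal machinery ------------------------------------------

# mean and sd of N(mu, sigma^2) truncated to [a, b]
tn_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  d <- (stats::dnorm(al) - stats::dnorm(be)) / z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z - d^2)
  c(mean = m, sd = sqrt(v))
}

# find (mu, sigma) of the parent normal such that its truncation to [a, b]
# has the requested mean and sd
solve_truncnorm <- function(mean, sd, a, b) {
  obj <- function(par) {
    m <- tn_moments(par[1], exp(par[2]), a, b)
    sum((m - c(mean, sd))^2)
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
  if (fit$value > 1e-10) {
    stop_compute("could not match truncated-normal moments (residual ", fit$value, ")")
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]), a = a, b = b)
}

# quantile function of the truncated parent
qtrunc <- function(p, tn) {
  pa <- stats::pnorm(tn$a, tn$mu, tn$sigma)
  pb <- stats::pnorm(tn$b, tn$mu, tn$sigma)
  stats::qnorm(pa + p * (pb - pa), tn$mu, tn$sigma)
}

# ---- generating network ---------------------------------------------------

#' Default ground-truth generating network
#'
#' A monotone discrete Bayesian network over the five ternary study
#' variables with the mediating structure of [study_structure()]. Root
#' priors equal the study's reported baseline marginals; child CPT rows are
#' linear in an ordinal parent score so that (a) every row pair is
#' stochastically ordered in the expected direction -- higher exposure or
#' sensitivity shifts annoyance up and comfort down, higher annoyance or
#' lower comfort shifts intention-to-leave up -- and (b) the implied prior
#' marginals of all five variables reproduce the reported baseline marginals
#' exactly. The dependency strengths themselves are this package's choice:
#' the study does not publish its CPTs.
#'
#' @return A [discrete_bn()].
#' @export
#' @examples
#' infer_marginals(default_generating_net())
default_generating_net <- function() {
  struct <- study_structure()
  row3 <- function(low, high) c(low, 1 - low - high, high)
  grid2 <- function(f) {
    arr <- array(0, dim = c(3, 3, 3))
    for (i in 1:3) for (j in 1:3) arr[, i, j] <- f(i, j)
    as.numeric(arr)
  }
  cpts <- list(
    lden = list(parents = character(0), prob = c(0.310, 0.385, 0.305)),
    sensitivity = list(parents = character(0), prob = c(0.350, 0.327, 0.323)),
    # ordinal parent score s in [-2, 2]; slope 0.09 per step
    annoyance = list(parents = c("lden", "sensitivity"), prob = grid2(function(i, j) {
      s <- (i - 2) + (j - 2)
      row3(0.34312 - 0.09 * s, 0.34388 + 0.09 * s)
    })),
    comfort = list(parents = c("lden", "sensitivity"), prob = grid2(function(i, j) {
      s <- (i - 2) + (j - 2)
      row3(0.35288 + 0.09 * s, 0.27612 - 0.09 * s)
    })),
    # annoyance raises, comfort lowers; slope 0.08 per step of the contrast
    itl = list(parents = c("annoyance", "comfort"), prob = grid2(function(a, c) {
      t <- (a - 2) - (c - 2)
      row3(0.33128 - 0.08 * t, 0.19872 + 0.08 * t)
    }))
  )
  discrete_bn(struct, cpts)
}

#' Default continuous marginal parameters
#'
#' Target mean, SD and scale limits per study variable: Lden in dB on
#' [35, 85], the 21-item Weinstein noise-sensitivity score on [0, 105],
#' annoyance and intention-to-leave visual-analogue scores on [0, 100], and
#' the 7-point acoustic-comfort rating on [1, 7].
#'
#' @return Data frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
default_marginal_params <- function() {
  data.frame(
    variable = .study_vars,
    mean = c(57.95, 42.57, 38.46, 4.73, 26.06),
    sd = c(6.61, 18.16, 17.07, 1.45, 11.78),
    min = c(35, 0, 0, 1, 0),
    max = c(85, 105, 100, 7, 100),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_patients Cohort size (at least 4); default 226.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param marginal_params Data frame as [default_marginal_params()].
#' @param generating_net Ground-truth [discrete_bn()] over the five ternary
#'   study variables.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 226, seed = 1,
                             marginal_params = default_marginal_params(),
                             generating_net = default_generating_net()) {
  if (!is_finite_num(n_patients) || n_patients < 4) stop_input("n_patients must be >= 4")
  if (!is_finite_num(seed)) stop_input("seed must be a finite integer")
  need <- c("variable", "mean", "sd", "min", "max")
  if (!is.data.frame(marginal_params) || !all(need %in% names(marginal_params)) ||
      !setequal(marginal_params$variable, .study_vars)) {
    stop_input("marginal_params must cover exactly the five study variables")
  }
  if (any(marginal_params$sd <= 0)) stop_input("marginal sd must be > 0")
  if (any(marginal_params$min >= marginal_params$max)) stop_input("min must be < max")
  if (!inherits(generating_net, "discrete_bn") ||
      !setequal(names(generating_net$structure$variables), .study_vars)) {
    stop_input("generating_net must be a discrete_bn over the five study variables")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 marginal_params = marginal_params, generating_net = generating_net),
            class = "generator_config")
}

# per-variable score model: moment-matched truncated parent plus band bounds
# at the generating-net marginal masses
.score_models <- function(config) {
  prior <- infer_marginals(config$generating_net)
  mp <- config$marginal_params
  models <- list()
  for (v in .study_vars) {
    p <- mp[mp$variable == v, ]
    tn <- solve_truncnorm(p$mean, p$sd, p$min, p$max)
    mass <- as.numeric(prior[[v]])
    tn$cum <- c(0, cumsum(mass))
    tn$bounds <- qtrunc(tn$cum, tn)
    tn$bounds[1] <- p$min
    tn$bounds[4] <- p$max
    models[[v]] <- tn
  }
  models
}

#' Per-state score components implied by a generator configuration
#'
#' The mean and SD of the continuous score within each category band, i.e.
#' the component distributions the generator draws from once a patient's
#' category is fixed. Bands are ordered low < moderate < high and do not
#' overlap.
#'
#' @param config A [generator_config()].
#' @return Data frame `variable`, `state`, `lower`, `upper`, `mean`, `sd`.
#' @export
category_score_map <- function(config) {
  models <- .score_models(config)
  rows <- lapply(.study_vars, function(v) {
    tn <- models[[v]]
    m <- t(vapply(1:3, function(k) {
      tn_moments(tn$mu, tn$sigma, tn$bounds[k], tn$bounds[k + 1])
    }, numeric(2)))
    data.frame(variable = v, state = .states3,
               lower = tn$bounds[1:3], upper = tn$bounds[2:4],
               mean = m[, 1], sd = m[, 2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# fixed measurement grid: eight 3-hour intervals covering 24 h
.log_grid <- data.frame(
  start = c("07:00", "10:00", "13:00", "16:00", "19:00", "22:00", "01:00", "04:00"),
  end = c("10:00", "13:00", "16:00", "19:00", "22:00", "01:00", "04:00", "07:00"),
  stringsAsFactors = FALSE
)
# diurnal profile (relative dB): busier daytime, quieter small hours
.log_profile <- c(2, 3, 2.5, 1.5, -1, -4, -7, -5)

# Lden implied by one row of eight interval levels on the fixed grid
# (vectorized over a matrix of cohorts x intervals)
.lden_from_grid <- function(L) {
  E <- 10^(L / 10)
  e_day <- (3 * (E[, 1] + E[, 2] + E[, 3] + E[, 4])) / 12
  e_eve <- (3 * E[, 5] + 1 * E[, 6]) / 4
  e_night <- (2 * E[, 6] + 3 * E[, 7] + 3 * E[, 8]) / 8
  10 * log10((12 * e_day + 4 * e_eve * 10^0.5 + 8 * e_night * 10) / 24)
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` records in three steps: (1) forward-sample the five
#' ternary states from the generating network; (2) map each state to a
#' continuous score by inverse-CDF sampling within that category's band of
#' the moment-matched truncated normal; (3) emit a per-patient noise log of
#' eight 3-hour intervals whose aggregated period levels reproduce the
#' patient's continuous Lden exactly (a common level shift is applied to a
#' diurnal profile, and shifting all interval levels by a constant shifts
#' Lden by the same constant). The result is a deterministic function of the
#' configuration.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_cohort`: list with `patients`
#'   (continuous scores), `true_categories` (ground-truth states),
#'   `noise_logs` (interval Leq log, `location_id` = patient id) and
#'   `config`.
#' @export
#' @examples
#' cohort <- sample_cohort(generator_config(n_patients = 50, seed = 1))
#' head(cohort$patients)
sample_cohort <- function(config) {
  if (!inherits(config, "generator_config")) stop_input("config must be a generator_config")
  n <- config$n_patients
  set.seed(config$seed)
  states <- sample_states(config$generating_net, n)
  models <- .score_models(config)
  ids <- sprintf("P%05d", seq_len(n))
  patients <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (v in .study_vars) {
    tn <- models[[v]]
    k <- as.integer(states[[v]])
    u <- stats::runif(n)
    p <- tn$cum[k] + u * (tn$cum[k + 1] - tn$cum[k])
    patients[[.study_cols[[v]]]] <- qtrunc(p, tn)
  }
  patients <- patients[c("patient_id", unname(.study_cols))]
  true_categories <- cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE), states)
  # noise logs: profile + interval noise, then shift to the patient's Lden
  L <- matrix(rep(.log_profile, each = n), nrow = n) +
    matrix(stats::rnorm(n * 8, 0, 1.5), nrow = n)
  L <- L + (patients$lden_db - .lden_from_grid(L))
  noise_logs <- data.frame(
    location_id = rep(ids, each = 8),
    start = rep(.log_grid$start, times = n),
    end = rep(.log_grid$end, times = n),
    leq_db = as.numeric(t(L)),
    stringsAsFactors = FALSE
  )
  structure(list(patients = patients, true_categories = true_categories,
                 noise_logs = noise_logs, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (seed %d), %d noise-log rows\n",
              nrow(x$patients), x$config$seed, nrow(x$noise_logs)))
  invisible(x)
}

#' Mask fields at random for negative-path testing
#'
#' Sets continuous score fields to `NA` with the given rate. The default
#' cohort is complete (the study excluded incomplete responses); masked
#' cohorts exist so that downstream validation -- which must reject records
#' with missing states -- can be exercised.
#'
#' @param cohort A [sample_cohort()] result.
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Integer seed for the mask.
#' @return The cohort with masked `patients` fields.
#' @export
inject_missingness <- function(cohort, rate, seed = 1) {
  if (!inherits(cohort, "synthetic_cohort")) stop_input("cohort must be a synthetic_cohort")
  if (!is_finite_num(rate) || rate < 0 || rate >= 1) stop_input("rate must be in [0, 1)")
  if (rate == 0) return(cohort)
  set.seed(seed)
  cols <- unname(.study_cols)
  mask <- matrix(stats::runif(nrow(cohort$patients) * length(cols)) < rate,
                 ncol = length(cols))
  for (j in seq_along(cols)) {
    cohort$patients[[cols[j]]][mask[, j]] <- NA_real_
  }
  cohort
}
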