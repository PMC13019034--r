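test_that("CPTs are relative frequencies, with Laplace smoothing on request", {
  s <- bn_structure(list(a = c("a1", "a2")))
  recs <- data.frame(a = c("a1", "a1", "a1", "a2"))
  expect_equal(as.numeric(fit_cpts(recs, s)$cpts$a$prob), c(0.75, 0.25))
  expect_equal(as.numeric(fit_cpts(recs, s, pseudocount = 1)$cpts$a$prob),
               c(4 / 6, 2 / 6))
  expect_error(fit_cpts(recs[0, , drop = FALSE], s), "no records")
  recs$a[2] <- NA
  expect_error(fit_cpts(recs, s), "missing state")
})

test_that("unobserved parent combinations fall back to uniform with a warning", {
  s <- bn_structure(list(a = c("a1", "a2"), b = c("b1", "b2")), list(c("a", "b")))
  recs <- data.frame(a = c("a1", "a1"), b = c("b1", "b2"))
  expect_warning(net <- fit_cpts(recs, s), "unobserved parent-state")
  expect_equal(as.numeric(net$cpts$b$prob[, "a2"]), c(0.5, 0.5))
  expect_equal(as.numeric(net$cpts$b$prob[, "a1"]), c(0.5, 0.5))
  # with smoothing there is no warning and no uniform fallback needed
  expect_silent(net2 <- fit_cpts(recs, s, pseudocount = 0.5))
  expect_equal(as.numeric(net2$cpts$b$prob[, "a1"]), c(0.5, 0.5))
})

test_that("joint probabilities factorize over the DAG and normalize", {
  net <- chain_net()
  expect_equal(joint_probability(net, c(a = "a1", b = "b1")), 0.54)
  expect_error(joint_probability(net, c(a = "a1")), "incomplete assignment")
  # uniform net over 3 binary variables: every assignment has mass 1/8
  s <- bn_structure(list(x = c("0", "1"), y = c("0", "1"), z = c("0", "1")))
  unif <- fit_cpts(data.frame(x = c("0", "1"), y = c("0", "1"), z = c("0", "1")),
                   s, pseudocount = 1e9)
  expect_equal(joint_probability(unif, c(x = "0", y = "1", z = "0")), 1 / 8,
               tolerance = 1e-6)
  # the study net's joint sums to 1 over all 3^5 assignments
  set.seed(7)
  gen <- default_generating_net()
  grid <- expand.grid(lden = states3, sensitivity = states3, annoyance = states3,
                      comfort = states3, itl = states3, stringsAsFactors = FALSE)
  total <- sum(vapply(seq_len(nrow(grid)),
                      function(i) joint_probability(gen, unlist(grid[i, ])),
                      numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("fitted CPTs converge to the sampling distribution", {
  set.seed(11)
  gen <- default_generating_net()
  fit <- fit_cpts(simulate_records <- sample_cohort(
    generator_config(n_patients = 5000, seed = 11))$true_categories[study_vars],
    study_structure())
  for (v in c("lden", "sensitivity")) {
    expect_equal(as.numeric(fit$cpts[[v]]$prob), as.numeric(gen$cpts[[v]]$prob),
                 tolerance = 0.05 / 0.3)
  }
})
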