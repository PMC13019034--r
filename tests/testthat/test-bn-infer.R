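test_that("posteriors on the two-node chain follow Bayes' rule", {
  net <- chain_net()
  post <- infer_marginals(net, c(b = "b1"))
  expect_equal(as.numeric(post$a), c(0.54 / 0.62, 0.08 / 0.62), tolerance = 1e-12)
  expect_equal(as.numeric(post$b), c(1, 0))
  prior <- infer_marginals(net)
  expect_equal(as.numeric(prior$b), c(0.62, 0.38), tolerance = 1e-12)
})

test_that("every returned distribution is a distribution", {
  set.seed(5)
  for (i in 1:10) {
    net <- rand_ternary_net(sample(3:7, 1))
    ev_var <- sample(names(net$structure$variables), 1)
    m <- infer_marginals(net, stats::setNames("s2", ev_var))
    for (v in names(m)) {
      expect_equal(sum(m[[v]]), 1, tolerance = 1e-9)
      expect_true(all(m[[v]] >= -1e-15))
    }
  }
})

test_that("variable elimination agrees with the enumeration oracle", {
  set.seed(6)
  for (i in 1:25) {
    net <- rand_ternary_net(sample(3:9, 1))
    ev <- NULL
    if (i %% 2 == 0) {
      v <- sample(names(net$structure$variables), 1)
      ev <- stats::setNames(sample(c("s1", "s2", "s3"), 1), v)
    }
    expect_lt(max_abs_diff(infer_marginals(net, ev), enumerate_oracle(net, ev)), 1e-9)
  }
})

test_that("impossible or malformed evidence is rejected", {
  s <- bn_structure(list(a = c("a1", "a2"), b = c("b1", "b2")), list(c("a", "b")))
  net <- discrete_bn(s, list(
    a = list(parents = character(0), prob = c(1, 0)),
    b = list(parents = "a", prob = c(1, 0, 0.5, 0.5))
  ))
  expect_error(infer_marginals(net, c(a = "a2")), "probability zero")
  expect_error(infer_marginals(net, c(b = "b2")), "probability zero")
  expect_error(enumerate_oracle(net, c(a = "a2")), "probability zero")
  expect_error(infer_marginals(net, c(z = "a1")), "undeclared variable")
  expect_error(infer_marginals(net, c(a = "zap")), "not a state")
  expect_error(infer_marginals(net, c(a = "a1", a = "a1")), "twice")
})

test_that("evidence fixing all nodes returns point masses", {
  net <- chain_net()
  m <- infer_marginals(net, c(a = "a2", b = "b1"))
  expect_equal(as.numeric(m$a), c(0, 1))
  expect_equal(as.numeric(m$b), c(1, 0))
  # single-node net returns its own CPT
  one <- discrete_bn(bn_structure(list(a = c("a1", "a2", "a3"))),
                     list(a = list(parents = character(0), prob = c(0.2, 0.3, 0.5))))
  expect_equal(as.numeric(enumerate_oracle(one)$a), c(0.2, 0.3, 0.5))
  expect_equal(as.numeric(infer_marginals(one)$a), c(0.2, 0.3, 0.5))
})

test_that("the enumeration oracle refuses oversized state spaces", {
  vl <- stats::setNames(rep(list(c("s1", "s2", "s3")), 14), paste0("v", 1:14))
  s <- bn_structure(vl)
  cpts <- stats::setNames(rep(list(list(parents = character(0),
                                        prob = rep(1 / 3, 3))), 14), paste0("v", 1:14))
  expect_error(enumerate_oracle(discrete_bn(s, cpts)), "too large")
})

test_that("evidence on exposure does not move the d-separated sensitivity root", {
  net <- default_generating_net()
  prior <- infer_marginals(net)
  for (st in states3) {
    post <- infer_marginals(net, c(lden = st))
    expect_equal(as.numeric(post$sensitivity), as.numeric(prior$sensitivity),
                 tolerance = 1e-12)
  }
  # but conditioning on a collider's descendant d-connects the roots
  post2 <- infer_marginals(net, c(lden = "high", itl = "high"))
  expect_gt(max(abs(post2$sensitivity - prior$sensitivity)), 1e-4)
})
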