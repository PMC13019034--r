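# Shared fixtures: small hand-built networks, random ternary networks, and a
# categorical cohort whose exposure distribution equals the reported
# 70/87/69 split.

states3 <- c("low", "moderate", "high")
study_vars <- c("lden", "sensitivity", "annoyance", "comfort", "itl")

# two-node chain with known posteriors: P(a1)=0.6, P(b1|a1)=0.9, P(b1|a2)=0.2
chain_net <- function() {
  s <- bn_structure(list(a = c("a1", "a2"), b = c("b1", "b2")), list(c("a", "b")))
  discrete_bn(s, list(
    a = list(parents = character(0), prob = c(0.6, 0.4)),
    b = list(parents = "a", prob = c(0.9, 0.1, 0.2, 0.8))
  ))
}

# random ternary DAG with random Dirichlet(1) CPT rows; uses the session RNG
rand_ternary_net <- function(n_nodes, max_parents = 3) {
  vars <- paste0("v", seq_len(n_nodes))
  vl <- stats::setNames(rep(list(c("s1", "s2", "s3")), n_nodes), vars)
  edges <- list()
  for (i in seq_len(n_nodes)[-1]) {
    np <- sample(0:min(max_parents, i - 1), 1)
    if (np > 0) {
      for (p in sample(i - 1, np)) edges[[length(edges) + 1]] <- c(vars[p], vars[i])
    }
  }
  s <- bn_structure(vl, if (length(edges)) edges else NULL)
  cpts <- lapply(vars, function(v) {
    pa <- s$edges[s$edges[, 2] == v, 1]
    nr <- 3^length(pa)
    m <- matrix(stats::rgamma(3 * nr, 1) + 1e-4, nrow = 3)
    m <- sweep(m, 2, colSums(m), "/")
    list(parents = pa, prob = as.numeric(m))
  })
  names(cpts) <- vars
  discrete_bn(s, cpts)
}

# categorical cohort of 226 records; lden has exactly 70 low / 87 moderate /
# 69 high, the other variables cycle through the states
lden_fixture_226 <- function() {
  df <- data.frame(
    lden = rep(states3, times = c(70, 87, 69)),
    stringsAsFactors = FALSE
  )
  # stagger the cycle lengths so every parent-state combination is observed
  df$sensitivity <- rep_len(states3, 226)
  df$annoyance <- rep_len(rep(states3, each = 3), 226)
  df$comfort <- rep_len(rep(states3, each = 9), 226)
  df$itl <- rep_len(rep(states3, each = 27), 226)
  df
}

max_abs_diff <- function(a, b) {
  max(abs(unlist(lapply(names(a), function(v) a[[v]][names(b[[v]])] - b[[v]]))))
}
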