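# Exact inference: variable elimination and a brute-force enumeration oracle.
#
# Factors are plain lists: vars (character, dimension order) and vals (numeric
# vector in column-major order over the state grid of vars). Cardinalities are
# looked up in the network structure, so factors stay lightweight.

# linear index into a sub-factor (dimension order `sub`) for every cell of the
# full column-major grid over `vars` with cardinalities `card` (named by vars)
.lin_index <- function(vars, card, sub) {
  n <- prod(card)
  idx <- rep(1L, n)
  stride <- 1L
  for (v in sub) {
    pos <- match(v, vars)
    inner <- if (pos > 1) prod(card[seq_len(pos - 1)]) else 1
    a <- rep(rep(seq_len(card[pos]), each = inner), length.out = n)
    idx <- idx + (a - 1L) * stride
    stride <- stride * card[pos]
  }
  idx
}

.f_product <- function(f1, f2, card_all) {
  vars <- union(f1$vars, f2$vars)
  card <- card_all[vars]
  v1 <- if (length(f1$vars)) f1$vals[.lin_index(vars, card, f1$vars)] else f1$vals
  v2 <- if (length(f2$vars)) f2$vals[.lin_index(vars, card, f2$vars)] else f2$vals
  list(vars = vars, vals = v1 * v2)
}

.f_sumout <- function(f, v, card_all) {
  d <- card_all[f$vars]
  p <- match(v, f$vars)
  arr <- array(f$vals, d)
  perm <- c(setdiff(seq_along(d), p), p)
  m <- matrix(aperm(arr, perm), ncol = d[p])
  list(vars = f$vars[-p], vals = as.numeric(rowSums(m)))
}

# condition a factor on evidence: slice the observed state, drop the dimension
.f_reduce <- function(f, evidence_idx, card_all) {
  keep <- setdiff(f$vars, names(evidence_idx))
  if (length(keep) == length(f$vars)) return(f)
  d <- card_all[f$vars]
  arr <- array(f$vals, d)
  idx <- lapply(f$vars, function(v) {
    if (v %in% names(evidence_idx)) evidence_idx[[v]] else seq_len(card_all[[v]])
  })
  sl <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  list(vars = keep, vals = as.numeric(sl))
}

.check_evidence <- function(net, evidence) {
  if (is.null(evidence) || length(evidence) == 0) return(integer(0))
  evidence <- unlist(evidence)
  vars <- net$structure$variables
  if (is.null(names(evidence)) || any(names(evidence) == "")) {
    stop_input("evidence must be a named variable = state mapping")
  }
  if (anyDuplicated(names(evidence))) stop_input("a variable appears twice in the evidence")
  idx <- integer(0)
  for (v in names(evidence)) {
    if (!v %in% names(vars)) stop_input("evidence on undeclared variable '", v, "'")
    i <- match(evidence[[v]], vars[[v]])
    if (is.na(i)) {
      stop_input("'", evidence[[v]], "' is not a state of variable '", v, "'")
    }
    idx[v] <- i
  }
  idx
}

# eliminate all variables except `keep`, multiplying everything down to a
# factor over `keep` (greedy min-width elimination order)
.ve_eliminate <- function(factors, keep, card_all) {
  hidden <- setdiff(unique(unlist(lapply(factors, `[[`, "vars"))), keep)
  while (length(hidden)) {
    width <- vapply(hidden, function(v) {
      touched <- unique(unlist(lapply(factors, function(f) if (v %in% f$vars) f$vars)))
      prod(card_all[touched])
    }, numeric(1))
    v <- hidden[which.min(width)]
    hit <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod <- Reduce(function(a, b) .f_product(a, b, card_all), factors[hit])
    factors <- c(factors[!hit], list(.f_sumout(prod, v, card_all)))
    hidden <- setdiff(hidden, v)
  }
  Reduce(function(a, b) .f_product(a, b, card_all), factors)
}

#' Exact posterior marginals by variable elimination
#'
#' Propagates evidence through the network and returns the exact posterior
#' marginal distribution of every variable. Evidence variables come back as a
#' point mass on the observed state. Evidence whose prior probability is zero
#' is an error, not a silent NaN.
#'
#' @param net A [discrete_bn()].
#' @param evidence Named character vector or list mapping variable names to
#'   observed states; `NULL` (default) for the prior marginals.
#' @return Named list of named probability vectors, one per variable, of
#'   class `bn_marginals`.
#' @export
#' @examples
#' net <- default_generating_net()
#' infer_marginals(net)                       # baseline (prior) marginals
#' infer_marginals(net, c(lden = "high"))     # updated distributions
infer_marginals <- function(net, evidence = NULL) {
  struct <- net$structure
  vars <- names(struct$variables)
  card_all <- vapply(struct$variables, length, 1L)
  ev_idx <- .check_evidence(net, evidence)
  base_factors <- lapply(vars, function(v) {
    f <- list(vars = c(v, net$cpts[[v]]$parents), vals = as.numeric(net$cpts[[v]]$prob))
    .f_reduce(f, as.list(ev_idx), card_all)
  })
  # evidence probability: eliminate everything
  z <- .ve_eliminate(base_factors, character(0), card_all)$vals
  if (!is.finite(z) || z <= 0) stop_compute("evidence has probability zero")
  out <- vector("list", length(vars))
  names(out) <- vars
  for (v in vars) {
    st <- struct$variables[[v]]
    if (v %in% names(ev_idx)) {
      p <- stats::setNames(as.numeric(st == st[ev_idx[[v]]]), st)
    } else {
      f <- .ve_eliminate(base_factors, v, card_all)
      p <- stats::setNames(f$vals / sum(f$vals), st)
    }
    out[[v]] <- p
  }
  structure(out, class = "bn_marginals", evidence = unlist(evidence))
}

#' @export
print.bn_marginals <- function(x, digits = 3, ...) {
  ev <- attr(x, "evidence")
  cat(if (length(ev)) {
    paste0("Posterior marginals | ", paste(names(ev), ev, sep = " = ", collapse = ", "), "\n")
  } else "Prior (baseline) marginals\n")
  for (v in names(x)) {
    cat(sprintf("  %-12s %s\n", v,
                paste(sprintf("%s %.3f", names(x[[v]]), round_probs_repair(x[[v]], digits)),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Brute-force posterior marginals by full enumeration
#'
#' Independent correctness oracle for [infer_marginals()]: sums the
#' factorized joint over every complete assignment consistent with the
#' evidence, then normalizes. Refuses joint state spaces above one million
#' cells.
#'
#' @inheritParams infer_marginals
#' @return Named list of named probability vectors, one per variable.
#' @export
enumerate_oracle <- function(net, evidence = NULL) {
  struct <- net$structure
  vars <- names(struct$variables)
  card <- vapply(struct$variables, length, 1L)
  total <- prod(card)
  if (total > 1e6) stop_input("joint state space too large to enumerate (", total, " cells)")
  ev_idx <- .check_evidence(net, evidence)
  cell <- seq_len(total) - 1L
  states_idx <- matrix(0L, nrow = total, ncol = length(vars), dimnames = list(NULL, vars))
  inner <- 1
  for (v in vars) {
    states_idx[, v] <- (cell %/% inner) %% card[[v]] + 1L
    inner <- inner * card[[v]]
  }
  p <- rep(1, total)
  for (v in vars) {
    cpt <- net$cpts[[v]]
    idx <- states_idx[, v]
    stride <- card[[v]]
    for (pa in cpt$parents) {
      idx <- idx + (states_idx[, pa] - 1L) * stride
      stride <- stride * card[[pa]]
    }
    p <- p * as.numeric(cpt$prob)[idx]
  }
  for (v in names(ev_idx)) p[states_idx[, v] != ev_idx[[v]]] <- 0
  z <- sum(p)
  if (z <= 0) stop_compute("evidence has probability zero")
  out <- lapply(vars, function(v) {
    m <- vapply(seq_len(card[[v]]), function(s) sum(p[states_idx[, v] == s]), numeric(1))
    stats::setNames(m / z, struct$variables[[v]])
  })
  stats::setNames(out, vars)
}
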