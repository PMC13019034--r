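# Discrete Bayesian network objects and CPT estimation.
#
# A CPT for child X with parents (P1, ..., Pk) is stored as a numeric array
# with dim = c(|X|, |P1|, ..., |Pk|) and dimnames naming the states; each
# slice over the child dimension (one parent-state combination) sums to 1.

#' Construct a discrete Bayesian network from a structure and CPTs
#'
#' @param structure A [bn_structure()].
#' @param cpts Named list, one entry per variable: a list with `parents`
#'   (character, matching the structure's in-edges) and `prob` (numeric array,
#'   child states first).
#' @return An object of class `discrete_bn`.
#' @export
discrete_bn <- function(structure, cpts) {
  vars <- names(structure$variables)
  if (!setequal(names(cpts), vars)) {
    stop_input("cpts must contain exactly one entry per variable")
  }
  for (v in vars) {
    cpt <- cpts[[v]]
    pa <- bn_parents(structure, v)
    if (!setequal(cpt$parents, pa)) {
      stop_input("CPT parents for '", v, "' do not match the structure's in-edges")
    }
    card <- c(length(structure$variables[[v]]),
              vapply(cpt$parents, function(p) length(structure$variables[[p]]), 1L))
    pr <- cpt$prob
    if (length(pr) != prod(card)) stop_input("CPT for '", v, "' has the wrong size")
    dim(pr) <- card
    m <- matrix(pr, nrow = card[1])
    if (any(pr < 0) || any(abs(colSums(m) - 1) > 1e-9)) {
      stop_input("CPT rows for '", v, "' must be non-negative and sum to 1")
    }
    dimnames(pr) <- c(list(structure$variables[[v]]),
                      lapply(cpt$parents, function(p) structure$variables[[p]]))
    names(dimnames(pr)) <- c(v, cpt$parents)
    cpts[[v]] <- list(parents = cpt$parents, prob = pr)
  }
  structure(list(structure = structure, cpts = cpts[vars]), class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d variables, %d edges\n",
              length(x$structure$variables), nrow(x$structure$edges)))
  for (v in names(x$cpts)) {
    pa <- x$cpts[[v]]$parents
    cat(sprintf("  P(%s%s): %d row(s)\n", v,
                if (length(pa)) paste0(" | ", paste(pa, collapse = ", ")) else "",
                length(x$cpts[[v]]$prob) / length(x$structure$variables[[v]])))
  }
  invisible(x)
}

#' Fit conditional probability tables from categorical records
#'
#' Estimates each variable's CPT by relative frequency with optional Laplace
#' smoothing: `P(x | pa) = (n(x, pa) + pseudocount) / (n(pa) + pseudocount *
#' |states|)`. With `pseudocount = 0`, a parent-state combination never
#' observed in the data gets a uniform row and a warning is raised naming the
#' affected child.
#'
#' @param records Data frame of categorical records: one column per variable
#'   in `structure`, values being valid state labels (factors or strings).
#'   Records with missing states are rejected.
#' @param structure A [bn_structure()].
#' @param pseudocount Non-negative Laplace smoothing count; default 0 (plain
#'   maximum likelihood).
#' @return A [discrete_bn()].
#' @export
#' @examples
#' recs <- data.frame(a = c("a1", "a1", "a1", "a2"))
#' net <- fit_cpts(recs, bn_structure(list(a = c("a1", "a2"))))
#' net$cpts$a$prob  # 0.75 / 0.25
fit_cpts <- function(records, structure, pseudocount = 0) {
  if (!is.data.frame(records) || nrow(records) == 0) stop_input("no records to fit from")
  if (!is_finite_num(pseudocount) || pseudocount < 0) stop_input("pseudocount must be >= 0")
  vars <- names(structure$variables)
  miss <- setdiff(vars, names(records))
  if (length(miss)) stop_input("records lack variable(s): ", paste(miss, collapse = ", "))
  cols <- list()
  for (v in vars) {
    x <- as.character(records[[v]])
    if (anyNA(x)) {
      stop_input("missing state for variable '", v, "' in record ",
                 which(is.na(x))[1],
                 "; records with missing states cannot be used to fit CPTs")
    }
    bad <- setdiff(unique(x), structure$variables[[v]])
    if (length(bad)) {
      stop_input("invalid state(s) for variable '", v, "': ", paste(bad, collapse = ", "))
    }
    cols[[v]] <- factor(x, levels = structure$variables[[v]])
  }
  cpts <- list()
  for (v in vars) {
    pa <- bn_parents(structure, v)
    counts <- table(cols[c(v, pa)]) + pseudocount
    arr <- array(as.numeric(counts), dim = dim(counts), dimnames = dimnames(counts))
    k <- dim(arr)[1]
    m <- matrix(arr, nrow = k)
    tot <- colSums(m)
    empty <- tot == 0
    if (any(empty)) {
      warning("unobserved parent-state combination(s) for '", v,
              "': CPT row(s) set to uniform", call. = FALSE)
      m[, empty] <- 1 / k
      tot[empty] <- 1
    }
    m <- sweep(m, 2, tot, "/")
    arr[] <- m
    cpts[[v]] <- list(parents = pa, prob = arr)
  }
  discrete_bn(structure, cpts)
}

#' Joint probability of a complete assignment
#'
#' Evaluates the factorized joint `prod_v P(x_v | x_parents(v))` for one full
#' state assignment.
#'
#' @param net A [discrete_bn()].
#' @param assignment Named character vector or list: one state per variable,
#'   covering all variables.
#' @return Probability in `[0, 1]`.
#' @export
joint_probability <- function(net, assignment) {
  assignment <- unlist(assignment)
  vars <- names(net$structure$variables)
  miss <- setdiff(vars, names(assignment))
  if (length(miss)) {
    stop_input("incomplete assignment; missing: ", paste(miss, collapse = ", "))
  }
  p <- 1
  for (v in vars) {
    cpt <- net$cpts[[v]]
    idx <- as.list(assignment[c(v, cpt$parents)])
    st <- net$structure$variables[[v]]
    if (!assignment[[v]] %in% st) stop_input("invalid state for '", v, "'")
    p <- p * do.call(`[`, c(list(cpt$prob), idx))
  }
  as.numeric(p)
}

# Forward-sample n complete records from the net (topological order),
# vectorized over records. Returns a data frame of factors.
sample_states <- function(net, n) {
  struct <- net$structure
  vars <- names(struct$variables)
  out <- vector("list", length(vars))
  names(out) <- vars
  idx <- matrix(0L, nrow = n, ncol = length(vars), dimnames = list(NULL, vars))
  for (v in struct$order) {
    cpt <- net$cpts[[v]]
    k <- length(struct$variables[[v]])
    pm <- matrix(cpt$prob, nrow = k)
    if (length(cpt$parents) == 0) {
      col <- rep(1L, n)
    } else {
      col <- rep(1L, n)
      stride <- 1L
      for (pa in cpt$parents) {
        col <- col + (idx[, pa] - 1L) * stride
        stride <- stride * length(struct$variables[[pa]])
      }
    }
    probs <- pm[, col, drop = FALSE] # k x n
    u <- stats::runif(n)
    s <- rep(1L, n)
    cum <- rep(0, n)
    for (j in seq_len(k - 1)) {
      cum <- cum + probs[j, ]
      s <- s + (u > cum)
    }
    idx[, v] <- s
  }
  for (v in vars) {
    out[[v]] <- factor(struct$variables[[v]][idx[, v]], levels = struct$variables[[v]])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
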