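# DAG structure of a discrete Bayesian network: variable declarations with
# ordered state sets, directed edges, topological validation.

#' Declare the variables and edges of a discrete Bayesian network
#'
#' @param variables Named list: variable name -> character vector of ordered
#'   state labels (at least two, unique).
#' @param edges Two-column character matrix or list of length-2 vectors,
#'   each `c(parent, child)`. May be empty.
#' @return An object of class `bn_structure` with the variables, an edge
#'   matrix, and a topological ordering.
#' @export
#' @examples
#' bn_structure(list(a = c("no", "yes"), b = c("no", "yes")),
#'              list(c("a", "b")))
bn_structure <- function(variables, edges = NULL) {
  if (!is.list(variables) || is.null(names(variables)) || any(names(variables) == "")) {
    stop_input("variables must be a named list of state vectors")
  }
  if (anyDuplicated(names(variables))) stop_input("duplicate variable names")
  for (v in names(variables)) {
    st <- variables[[v]]
    if (!is.character(st) || length(st) < 2 || anyDuplicated(st)) {
      stop_input("variable '", v, "' needs at least two unique state labels")
    }
  }
  if (is.null(edges) || length(edges) == 0) {
    em <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("parent", "child")))
  } else {
    if (is.list(edges)) edges <- do.call(rbind, edges)
    em <- matrix(as.character(edges), ncol = 2, dimnames = list(NULL, c("parent", "child")))
    dangling <- setdiff(unique(c(em)), names(variables))
    if (length(dangling)) {
      stop_input("edge endpoint(s) not declared as variables: ",
                 paste(dangling, collapse = ", "))
    }
    if (anyDuplicated(paste(em[, 1], em[, 2], sep = "\r"))) {
      stop_input("duplicate edges in structure")
    }
    if (any(em[, 1] == em[, 2])) stop_input("self-loop edge in structure")
  }
  s <- structure(list(variables = variables, edges = em), class = "bn_structure")
  s$order <- validate_dag(s)
  s
}

#' Validate acyclicity and return a topological ordering
#'
#' Runs Kahn's algorithm on the structure's edge list. If a cycle exists the
#' error message lists one offending cycle.
#'
#' @param structure A [bn_structure()] (the `order` element is ignored).
#' @return Character vector: the variables in a topological order (parents
#'   before children).
#' @export
validate_dag <- function(structure) {
  vars <- names(structure$variables)
  em <- structure$edges
  indeg <- stats::setNames(integer(length(vars)), vars)
  children <- stats::setNames(vector("list", length(vars)), vars)
  for (i in seq_len(nrow(em))) {
    indeg[em[i, 2]] <- indeg[em[i, 2]] + 1L
    children[[em[i, 1]]] <- c(children[[em[i, 1]]], em[i, 2])
  }
  order <- character(0)
  ready <- vars[indeg == 0]
  while (length(ready)) {
    v <- ready[1]
    ready <- ready[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) ready <- c(ready, ch)
    }
  }
  if (length(order) < length(vars)) {
    left <- setdiff(vars, order)
    # walk parent links among the leftover nodes until a vertex repeats
    parent_of <- function(v) em[em[, 2] == v & em[, 1] %in% left, 1][1]
    path <- left[1]
    repeat {
      nxt <- parent_of(path[1])
      if (nxt %in% path) {
        cyc <- c(nxt, rev(path[seq_len(match(nxt, path))]))
        stop_input("structure contains a cycle: ", paste(cyc, collapse = " -> "))
      }
      path <- c(nxt, path)
    }
  }
  order
}

# parents of each variable, in declaration order of the edge list
bn_parents <- function(structure, var) {
  em <- structure$edges
  em[em[, 2] == var, 1]
}

#' @export
print.bn_structure <- function(x, ...) {
  cat(sprintf("Bayesian network structure: %d variables, %d edges\n",
              length(x$variables), nrow(x$edges)))
  for (v in names(x$variables)) {
    pa <- bn_parents(x, v)
    cat(sprintf("  %s (%s)%s\n", v, paste(x$variables[[v]], collapse = "/"),
                if (length(pa)) paste0(" <- ", paste(pa, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Default study network structure
#'
#' The five ternary study variables with the mediating topology: noise
#' exposure (`lden`) and noise sensitivity (`sensitivity`) are exogenous
#' roots; both feed noise annoyance (`annoyance`) and acoustic comfort
#' (`comfort`); annoyance and comfort feed intention to leave (`itl`). There
#' is no edge between the two roots and no direct root-to-`itl` edge, but the
#' structure is plain data and fully configurable.
#'
#' @return A [bn_structure()] over the five study variables.
#' @export
#' @examples
#' study_structure()
study_structure <- function() {
  vars <- stats::setNames(rep(list(.states3), 5), .study_vars)
  bn_structure(vars, list(
    c("lden", "annoyance"), c("sensitivity", "annoyance"),
    c("lden", "comfort"), c("sensitivity", "comfort"),
    c("annoyance", "itl"), c("comfort", "itl")
  ))
}
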