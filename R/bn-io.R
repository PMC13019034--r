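# JSON I/O for network specifications. Schema:
#   {"variables":[{"name":..,"states":[..]}],
#    "edges":[["parent","child"], ...],
#    "cpts":{child:{"parents":[..],"prob":[..column-major..]}}}   (optional)
# read -> write -> read round-trips losslessly.

#' Read a network specification file
#'
#' @param path Path to a JSON network specification.
#' @return A [bn_structure()] if the file has no CPTs, otherwise a
#'   [discrete_bn()].
#' @export
read_network_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(spec$variables)) stop_input("network spec lacks 'variables'")
  vars <- list()
  for (v in spec$variables) {
    if (is.null(v$name) || is.null(v$states)) {
      stop_input("each variable needs 'name' and 'states'")
    }
    vars[[v$name]] <- unlist(v$states)
  }
  edges <- if (length(spec$edges)) lapply(spec$edges, unlist) else NULL
  struct <- bn_structure(vars, edges)
  if (is.null(spec$cpts) || length(spec$cpts) == 0) return(struct)
  cpts <- lapply(spec$cpts, function(cpt) {
    list(parents = as.character(unlist(cpt$parents)), prob = as.numeric(unlist(cpt$prob)))
  })
  discrete_bn(struct, cpts)
}

#' Write a network specification file
#'
#' @param x A [bn_structure()] or [discrete_bn()]; CPTs are included when
#'   present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(x, path) {
  struct <- if (inherits(x, "discrete_bn")) x$structure else x
  spec <- list(
    variables = lapply(names(struct$variables), function(v) {
      list(name = v, states = struct$variables[[v]])
    }),
    edges = lapply(seq_len(nrow(struct$edges)), function(i) unname(struct$edges[i, ]))
  )
  if (inherits(x, "discrete_bn")) {
    spec$cpts <- lapply(x$cpts, function(cpt) {
      list(parents = cpt$parents, prob = as.numeric(cpt$prob))
    })
  }
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
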