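#' Validate a directed acyclic graph
#'
#' Builds the dependency graph of a Bayesian network from an edge list and
#' verifies it is acyclic. The topological order (computed by Kahn's
#' algorithm with deterministic ties broken by node declaration order) is
#' cached on the object; cyclic input is rejected with an error naming a node
#' on the cycle.
#'
#' @param nodes Character vector of node names.
#' @param edges Two-column matrix or data frame of `parent -> child` pairs
#'   (columns `from`, `to`), or a list of length-2 character vectors. May be
#'   empty.
#' @return An object of class `bn_dag` with elements `nodes`, `edges`
#'   (two-column character matrix) and `order` (a topological order).
#' @examples
#' validate_dag(c("A", "B"), rbind(c("A", "B")))
#' @export
validate_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (!length(nodes)) stop2("a DAG needs at least one node")
  if (anyDuplicated(nodes)) {
    stop2("duplicated node names: ",
          paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  edges <- as_edge_matrix(edges)
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown)) {
    stop2("edge endpoint '", unknown[1], "' is not a declared node")
  }
  if (nrow(edges)) {
    if (any(edges[, 1L] == edges[, 2L])) {
      i <- which(edges[, 1L] == edges[, 2L])[1]
      stop2("self-edge on node '", edges[i, 1L], "'")
    }
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1]
      stop2("duplicate edge ", edges[i, 1L], " -> ", edges[i, 2L])
    }
  }
  order <- topological_order(nodes, edges)
  structure(list(nodes = nodes, edges = edges, order = order),
            class = "bn_dag")
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      (is.data.frame(edges) && nrow(edges) == 0L) || !length(edges)) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      if (length(e) != 2L) stop2("each edge must have exactly 2 endpoints")
      as.character(e)
    }))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  edges <- matrix(as.character(edges), ncol = 2L)
  colnames(edges) <- c("from", "to")
  edges
}

# Kahn's algorithm; ties broken by declaration order so results are
# reproducible under node-order permutation of an equivalent input.
topological_order <- function(nodes, edges) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  indeg <- integer(n)
  children <- vector("list", n)
  if (nrow(edges)) {
    from <- idx[edges[, 1L]]
    to <- idx[edges[, 2L]]
    for (k in seq_along(from)) {
      children[[from[k]]] <- c(children[[from[k]]], to[k])
      indeg[to[k]] <- indeg[to[k]] + 1L
    }
  }
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    v <- min(ready)
    ready <- setdiff(ready, v)
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) < n) {
    on_cycle <- setdiff(seq_len(n), order)
    stop2("cycle detected involving node '", nodes[on_cycle[1]], "'")
  }
  nodes[order]
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"),
        "\n")
  }
  invisible(x)
}

dag_parents <- function(dag, node) {
  unname(dag$edges[dag$edges[, 2L] == node, 1L])
}

dag_children <- function(dag, node) {
  unname(dag$edges[dag$edges[, 1L] == node, 2L])
}

#' Default hereditary-angioedema DAG edge list
#'
#' The shipped dependency structure over the default schema: demographics
#' feed comorbidities, demographics and comorbidities feed admission
#' severity, and all predictors feed the mortality-risk outcome. The
#' topology is configuration, not ground truth — analyses may replace it via
#' the model-config document.
#'
#' @return A two-column character matrix of `parent -> child` edges.
#' @export
default_ha_edges <- function() {
  rbind(
    cbind("age", c("hypertension", "diabetes", "autoimmune",
                   "severity", "mortality")),
    cbind("race", c("hypertension", "diabetes", "mortality")),
    c("income", "mortality"),
    c("region", "mortality"),
    c("insurance", "mortality"),
    cbind("hypertension", c("severity", "mortality")),
    cbind("autoimmune", c("severity", "mortality")),
    cbind("diabetes", c("severity", "mortality")),
    c("severity", "mortality")
  )
}

#' Default hereditary-angioedema DAG
#'
#' @return A validated `bn_dag` over the [default_ha_schema()] variables.
#' @export
default_ha_dag <- function() {
  validate_dag(schema_names(default_ha_schema()), default_ha_edges())
}
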