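#' Construct a conditional probability table
#'
#' A CPT stores, for every configuration of a node's parents, a probability
#' vector over the node's categories. Internally the table is a numeric
#' array whose first dimension is the child and whose remaining dimensions
#' follow the parent order; all layouts come from the schema's declared
#' category order.
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (possibly empty).
#' @param prob Numeric array of dimension `c(K_child, K_parent1, ...)`; each
#'   column over the child dimension must be a probability vector.
#' @param schema The `bn_schema` the variables belong to.
#' @return An object of class `bn_cpt`.
#' @export
new_cpt <- function(child, parents, prob, schema) {
  k <- schema_cardinality(schema, child)
  pdims <- vapply(parents, function(p) schema_cardinality(schema, p),
                  integer(1))
  dims <- c(k, unname(pdims))
  prob <- array(as.numeric(prob), dim = dims)
  dimnames(prob) <- c(list(schema_categories(schema, child)),
                      lapply(parents, function(p) schema_categories(schema, p)))
  names(dimnames(prob)) <- c(child, parents)
  if (any(prob < 0 | prob > 1)) {
    stop2("CPT for '", child, "' has entries outside [0, 1]")
  }
  sums <- colSums(matrix(prob, nrow = k))
  if (any(abs(sums - 1) > 1e-9)) {
    stop2("CPT rows for '", child, "' do not sum to 1 (max deviation ",
          format(max(abs(sums - 1))), ")")
  }
  structure(list(child = child, parents = as.character(parents), prob = prob),
            class = "bn_cpt")
}

# K_child x n_parent_config matrix view of the CPT.
cpt_matrix <- function(cpt) {
  matrix(cpt$prob, nrow = dim(cpt$prob)[1L])
}

# Column index of the parent configuration for each row of a code matrix.
# Layout matches the array flattening: first parent varies fastest.
parent_config_index <- function(cpt, codes) {
  if (!length(cpt$parents)) return(rep.int(1L, nrow(codes)))
  dims <- dim(cpt$prob)[-1L]
  idx <- rep.int(0L, nrow(codes))
  mult <- 1L
  for (j in seq_along(cpt$parents)) {
    idx <- idx + (codes[, cpt$parents[j]] - 1L) * mult
    mult <- mult * dims[j]
  }
  idx + 1L
}

#' @export
print.bn_cpt <- function(x, ...) {
  cat("CPT: P(", x$child,
      if (length(x$parents)) paste(" |", paste(x$parents, collapse = ", ")),
      ")\n", sep = "")
  print(x$prob, ...)
  invisible(x)
}

#' Assemble a discrete Bayesian network
#'
#' @param schema A `bn_schema`.
#' @param dag A `bn_dag` over the schema variables.
#' @param cpts Named list with one `bn_cpt` per node; each CPT's parents
#'   must equal the node's DAG parents.
#' @return An object of class `bn_net`.
#' @export
bayes_net <- function(schema, dag, cpts) {
  stopifnot(inherits(schema, "bn_schema"), inherits(dag, "bn_dag"))
  if (!setequal(dag$nodes, schema_names(schema))) {
    stop2("DAG nodes must match schema variables")
  }
  missing <- setdiff(dag$nodes, names(cpts))
  if (length(missing)) {
    stop2("missing CPT for node(s): ", paste(missing, collapse = ", "))
  }
  for (node in dag$nodes) {
    cpt <- cpts[[node]]
    if (!identical(sort(cpt$parents), sort(dag_parents(dag, node)))) {
      stop2("CPT parents for '", node, "' disagree with the DAG")
    }
  }
  structure(list(schema = schema, dag = dag, cpts = cpts[dag$nodes]),
            class = "bn_net")
}

#' @export
print.bn_net <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$edges), "edges, outcome =", x$schema$outcome, "\n")
  invisible(x)
}

#' Fit conditional probability tables by Bayesian updating
#'
#' For each node, counts `n_jk` of child state `k` under parent
#' configuration `j` are combined with a symmetric per-cell Dirichlet prior
#' of concentration `alpha`: the stored point estimate is the posterior mean
#' `(n_jk + alpha) / (n_j + K * alpha)`. Parent configurations never
#' observed therefore yield the uniform vector, and no entry is exactly 0 or
#' 1 whenever `alpha > 0` — the smoothing that keeps sparse strata from
#' producing impossible records. `alpha = 0` gives the maximum-likelihood
#' estimate (unobserved rows fall back to uniform).
#'
#' A warning is raised when a node's parent-configuration count exceeds
#' `n / 5`: such CPTs are severely underdetermined by the data and lean
#' heavily on the prior.
#'
#' @param dag A `bn_dag`.
#' @param schema A `bn_schema`.
#' @param data Cohort data frame covering all DAG nodes (validated against
#'   the schema).
#' @param alpha Dirichlet concentration per CPT cell; non-negative scalar,
#'   default 1.
#' @return A fitted `bn_net`.
#' @examples
#' schema <- cohort_schema(list(variable_spec("x", c("a", "b"))), "x")
#' dag <- validate_dag("x")
#' d <- data.frame(x = c("a", "a", "a", "b"))
#' fit <- fit_cpts_bayes(dag, schema, d, alpha = 1)
#' fit$cpts$x$prob  # (3+1)/(4+2), (1+1)/(4+2)
#' @export
fit_cpts_bayes <- function(dag, schema, data, alpha = 1) {
  stopifnot(inherits(dag, "bn_dag"), inherits(schema, "bn_schema"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop2("alpha must be a single non-negative number")
  }
  data <- validate_cohort(data, schema)
  n <- nrow(data)
  if (n == 0L) {
    warning("empty dataset: returning all-uniform CPTs", call. = FALSE)
  }
  codes <- cohort_codes(data, schema)
  sparse_nodes <- character(0)
  cpts <- lapply(dag$nodes, function(node) {
    parents <- dag_parents(dag, node)
    k <- schema_cardinality(schema, node)
    nconf <- prod(vapply(parents, function(p) schema_cardinality(schema, p),
                         integer(1)))
    if (n > 0L && length(parents) && nconf > n / 5) {
      sparse_nodes <<- c(sparse_nodes, node)
    }
    counts <- matrix(0, nrow = k, ncol = nconf)
    if (n > 0L) {
      skeleton <- structure(
        list(child = node, parents = parents,
             prob = array(0, dim = c(k, vapply(parents, function(p)
               schema_cardinality(schema, p), integer(1))))),
        class = "bn_cpt")
      conf <- parent_config_index(skeleton, codes)
      flat <- codes[, node] + k * (conf - 1L)
      counts <- matrix(tabulate(flat, nbins = k * nconf), nrow = k)
    }
    n_j <- colSums(counts)
    denom <- n_j + k * alpha
    prob <- sweep(counts + alpha, 2L, denom, "/")
    # alpha = 0 on an empty row gives 0/0; define those rows as uniform
    empty <- denom == 0
    if (any(empty)) prob[, empty] <- 1 / k
    new_cpt(node, parents, prob, schema)
  })
  names(cpts) <- dag$nodes
  if (length(sparse_nodes)) {
    warning("sparse CPT(s): parent-configuration count exceeds n/5 for ",
            paste(sparse_nodes, collapse = ", "),
            "; estimates lean heavily on the prior", call. = FALSE)
  }
  bayes_net(schema, dag, cpts)
}

# Joint probability for each row of an integer code matrix (vectorised).
joint_probability_codes <- function(bn, codes) {
  p <- rep.int(1, nrow(codes))
  for (node in bn$dag$nodes) {
    cpt <- bn$cpts[[node]]
    conf <- parent_config_index(cpt, codes)
    p <- p * cpt_matrix(cpt)[cbind(codes[, node], conf)]
  }
  p
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorised joint `prod_v P(v | parents(v))` at one complete
#' assignment of categories to variables.
#'
#' @param bn A `bn_net`.
#' @param assignment Named character vector or list mapping every variable to
#'   a category.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(bn, assignment) {
  assignment <- unlist(assignment)
  missing <- setdiff(bn$dag$nodes, names(assignment))
  if (length(missing)) {
    stop2("assignment is missing variable(s): ",
          paste(missing, collapse = ", "))
  }
  df <- as.data.frame(as.list(assignment[bn$dag$nodes]),
                      stringsAsFactors = FALSE)
  names(df) <- bn$dag$nodes
  codes <- cohort_codes(validate_cohort(df, bn$schema), bn$schema)
  joint_probability_codes(bn, codes)
}

#' Log-likelihood of a cohort under a fitted network
#'
#' Sum over records of the log joint probability. Finite whenever the
#' network was fitted with `alpha > 0`; a record with zero probability
#' (possible under a maximum-likelihood fit) yields `-Inf` with a warning.
#'
#' @param bn A `bn_net`.
#' @param data Cohort data frame conforming to the schema.
#' @return A single numeric value.
#' @export
log_likelihood <- function(bn, data) {
  data <- validate_cohort(data, bn$schema)
  p <- joint_probability_codes(bn, cohort_codes(data, bn$schema))
  if (any(p == 0)) {
    warning("record(s) with zero probability: log-likelihood is -Inf",
            call. = FALSE)
  }
  sum(log(p))
}
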