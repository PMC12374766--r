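# Small networks built in code, shared across test files.

# Two-node chain A -> B with binary nodes.
chain_bn <- function(p_a1 = 0.6, p_b1_a1 = 0.5, p_b1_a2 = 0.25) {
  schema <- cohort_schema(list(variable_spec("A", c("a1", "a2")),
                               variable_spec("B", c("b1", "b2"))),
                          outcome = "B")
  dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  bayes_net(schema, dag, list(
    A = new_cpt("A", character(0), c(p_a1, 1 - p_a1), schema),
    B = new_cpt("B", "A",
                array(rbind(c(p_b1_a1, p_b1_a2), c(1 - p_b1_a1, 1 - p_b1_a2)),
                      dim = c(2, 2)), schema)))
}

# Network with independent nodes (no edges).
independent_bn <- function(probs) {
  vars <- lapply(names(probs), function(nm)
    variable_spec(nm, paste0(nm, seq_along(probs[[nm]]))))
  schema <- cohort_schema(vars, outcome = names(probs)[length(probs)])
  dag <- validate_dag(names(probs))
  cpts <- lapply(names(probs), function(nm)
    new_cpt(nm, character(0), probs[[nm]], schema))
  names(cpts) <- names(probs)
  bayes_net(schema, dag, cpts)
}

# Random DAG + random Dirichlet CPTs; caller controls the RNG seed.
# State space stays small (<= `max_card`^`n_nodes`) so enumeration is cheap.
random_bn <- function(n_nodes = 6, max_card = 3, edge_prob = 0.4) {
  nms <- paste0("v", seq_len(n_nodes))
  cards <- 2L + sample.int(max_card - 1L, n_nodes, replace = TRUE) - 1L
  perm <- sample(n_nodes)  # hidden topological order
  edges <- NULL
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < edge_prob) {
        edges <- rbind(edges, c(nms[perm[i]], nms[perm[j]]))
      }
    }
  }
  schema <- cohort_schema(
    lapply(seq_len(n_nodes), function(i)
      variable_spec(nms[i], paste0("c", seq_len(cards[i])))),
    outcome = nms[n_nodes])
  dag <- validate_dag(nms, edges)
  cpts <- lapply(nms, function(node) {
    parents <- habnet:::dag_parents(dag, node)
    k <- length(schema$variables[[node]]$categories)
    nconf <- prod(vapply(parents, function(p)
      length(schema$variables[[p]]$categories), integer(1)))
    raw <- matrix(stats::rgamma(k * nconf, shape = 1), nrow = k)
    prob <- sweep(raw, 2, colSums(raw), "/")
    dims <- c(k, vapply(parents, function(p)
      length(schema$variables[[p]]$categories), integer(1)))
    new_cpt(node, parents, array(prob, dim = dims), schema)
  })
  names(cpts) <- nms
  bayes_net(schema, dag, cpts)
}

# Random evidence on a fitted random net: hard assignments on a subset.
random_hard_evidence <- function(bn, exclude, max_vars = 3) {
  cand <- setdiff(bn$dag$nodes, exclude)
  k <- sample(0:min(max_vars, length(cand)), 1)
  if (k == 0) return(NULL)
  vars <- sample(cand, k)
  vals <- vapply(vars, function(v)
    sample(bn$schema$variables[[v]]$categories, 1), character(1))
  hard_evidence(stats::setNames(vals, vars))
}

max_abs <- function(x, y) max(abs(x - y))
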