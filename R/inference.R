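#' Hard evidence
#'
#' Observed categories for a subset of variables, each known with certainty.
#'
#' @param ... Named arguments `variable = "category"`, or a single named
#'   character vector / list.
#' @return An object of class `bn_hard_evidence`.
#' @examples
#' hard_evidence(race = "black", region = "midwest")
#' @export
hard_evidence <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) ||
      (length(args) == 1L && (is.list(args[[1]]) ||
                              length(args[[1]]) > 1L) &&
       !is.null(names(args[[1]])))) {
    args <- as.list(args[[1]])
  }
  vals <- vapply(args, function(x) as.character(x)[1], character(1))
  if (length(vals) && (is.null(names(vals)) || any(!nzchar(names(vals))))) {
    stop2("hard evidence must be named variable = category")
  }
  if (anyDuplicated(names(vals))) {
    stop2("variable assigned twice in hard evidence: ",
          names(vals)[duplicated(names(vals))][1])
  }
  structure(vals, class = "bn_hard_evidence")
}

#' Virtual (soft) evidence
#'
#' Likelihood vectors over variable categories. The observation is treated
#' probabilistically: each evidenced variable contributes a nonnegative
#' likelihood vector (not required to sum to 1) that multiplies the joint
#' before normalisation, per Pearl's virtual-evidence construction. A
#' uniform vector is vacuous; an indicator vector reproduces hard evidence.
#'
#' @param ... Named arguments `variable = c(l1, ..., lK)`, or a single named
#'   list of numeric vectors.
#' @return An object of class `bn_virtual_evidence`.
#' @examples
#' virtual_evidence(hypertension = c(0.1, 0.9))
#' @export
virtual_evidence <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args))) {
    args <- args[[1]]
  }
  if (length(args) && (is.null(names(args)) || any(!nzchar(names(args))))) {
    stop2("virtual evidence must be named variable = likelihood vector")
  }
  if (anyDuplicated(names(args))) {
    stop2("variable given twice in virtual evidence: ",
          names(args)[duplicated(names(args))][1])
  }
  args <- lapply(args, as.numeric)
  for (v in names(args)) {
    l <- args[[v]]
    if (any(!is.finite(l)) || any(l < 0)) {
      stop2("likelihood vector for '", v, "' must be finite and nonnegative")
    }
    if (all(l == 0)) {
      stop2("likelihood vector for '", v, "' is all zero")
    }
  }
  structure(args, class = "bn_virtual_evidence")
}

#' Build a soft-evidence likelihood for one observed category
#'
#' Weight `w` on the observed category and `(1 - w) / (K - 1)` on each
#' alternative: the conservative counterpart of hard evidence, collapsing to
#' it at `w = 1` and to no evidence at `w = 1/K`.
#'
#' @param schema A `bn_schema`.
#' @param var Variable name.
#' @param category Observed category.
#' @param weight Likelihood weight on the observed category, in `(0, 1]`.
#' @return A `bn_virtual_evidence` with a single likelihood vector.
#' @export
soft_observation <- function(schema, var, category, weight = 0.9) {
  cats <- schema_categories(schema, var)
  if (!category %in% cats) {
    stop2("'", category, "' is not a category of '", var, "'")
  }
  if (weight <= 0 || weight > 1) stop2("weight must be in (0, 1]")
  k <- length(cats)
  l <- rep((1 - weight) / (k - 1), k)
  l[match(category, cats)] <- weight
  ev <- stats::setNames(list(l), var)
  virtual_evidence(ev)
}

# Split an evidence argument into validated hard assignments (named chr)
# and virtual likelihood vectors (named list), against the schema.
resolve_evidence <- function(bn, evidence, target) {
  hard <- character(0)
  virt <- list()
  if (!is.null(evidence)) {
    if (inherits(evidence, "bn_hard_evidence")) {
      hard <- unclass(evidence)
    } else if (inherits(evidence, "bn_virtual_evidence")) {
      virt <- unclass(evidence)
    } else if (is.list(evidence) &&
               all(vapply(evidence, function(e)
                 inherits(e, c("bn_hard_evidence", "bn_virtual_evidence")),
                 logical(1)))) {
      for (e in evidence) {
        if (inherits(e, "bn_hard_evidence")) hard <- c(hard, unclass(e))
        else virt <- c(virt, unclass(e))
      }
    } else {
      hard <- unclass(hard_evidence(evidence))
    }
  }
  all_ev <- c(names(hard), names(virt))
  if (anyDuplicated(all_ev)) {
    stop2("variable evidenced twice: ", all_ev[duplicated(all_ev)][1])
  }
  unknown <- setdiff(all_ev, bn$dag$nodes)
  if (length(unknown)) stop2("unknown evidence variable '", unknown[1], "'")
  if (target %in% all_ev) {
    stop2("target '", target, "' cannot carry evidence")
  }
  for (v in names(hard)) {
    cats <- schema_categories(bn$schema, v)
    if (!hard[[v]] %in% cats) {
      stop2("'", hard[[v]], "' is not a category of '", v, "'")
    }
  }
  for (v in names(virt)) {
    k <- schema_cardinality(bn$schema, v)
    if (length(virt[[v]]) != k) {
      stop2("likelihood vector for '", v, "' must have length ", k)
    }
  }
  list(hard = hard, virtual = virt)
}

new_query_result <- function(bn, target, dist, evidence, method) {
  structure(list(target = target,
                 distribution = stats::setNames(
                   dist, schema_categories(bn$schema, target)),
                 evidence = evidence,
                 method = method),
            class = "bn_query")
}

#' @export
print.bn_query <- function(x, ...) {
  cat("P(", x$target, " | evidence) by ", x$method, ":\n", sep = "")
  print(round(x$distribution, 6))
  invisible(x)
}

#' Posterior query by exhaustive enumeration
#'
#' Exact posterior of `target` obtained by summing the joint probability
#' over every completion consistent with the evidence and normalising.
#' Exponential in the number of variables; it exists as the transparent
#' ground-truth oracle against which [eliminate_query()] is verified.
#'
#' @param bn A fitted `bn_net`.
#' @param target Query variable name.
#' @param evidence `NULL`, a [hard_evidence()], a [virtual_evidence()], or a
#'   list mixing both.
#' @return A `bn_query` with the posterior distribution over `target`.
#' @export
enumerate_query <- function(bn, target, evidence = NULL) {
  if (!target %in% bn$dag$nodes) stop2("unknown target '", target, "'")
  ev <- resolve_evidence(bn, evidence, target)
  nodes <- bn$dag$nodes
  dims <- vapply(nodes, function(v) schema_cardinality(bn$schema, v),
                 integer(1))
  levels <- lapply(nodes, function(v) {
    if (v %in% names(ev$hard)) {
      match(ev$hard[[v]], schema_categories(bn$schema, v))
    } else {
      seq_len(dims[[v]])
    }
  })
  grid <- as.matrix(expand.grid(levels, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- nodes
  storage.mode(grid) <- "integer"
  w <- joint_probability_codes(bn, grid)
  for (v in names(ev$virtual)) {
    w <- w * ev$virtual[[v]][grid[, v]]
  }
  mass <- vapply(seq_len(dims[[target]]), function(k) {
    sum(w[grid[, target] == k])
  }, numeric(1))
  total <- sum(mass)
  if (total <= 0) stop2("impossible evidence: zero total probability")
  new_query_result(bn, target, mass / total, evidence, "enumeration")
}

#' Posterior query by variable elimination
#'
#' Exact inference by sum-product variable elimination over the network's
#' factors. Hard evidence slices factors; virtual evidence multiplies in
#' likelihood factors. The elimination order is the min-fill heuristic with
#' deterministic ties broken by schema declaration order, so runs are
#' reproducible. Agrees with [enumerate_query()] to numerical precision.
#'
#' @inheritParams enumerate_query
#' @return A `bn_query`.
#' @export
eliminate_query <- function(bn, target, evidence = NULL) {
  if (!target %in% bn$dag$nodes) stop2("unknown target '", target, "'")
  ev <- resolve_evidence(bn, evidence, target)
  dims <- vapply(bn$dag$nodes,
                 function(v) schema_cardinality(bn$schema, v), integer(1))
  factors <- lapply(bn$cpts, cpt_factor)
  for (v in names(ev$virtual)) {
    factors <- c(factors, list(new_factor(v, ev$virtual[[v]])))
  }
  for (v in names(ev$hard)) {
    code <- match(ev$hard[[v]], schema_categories(bn$schema, v))
    factors <- lapply(factors, factor_reduce, var = v, code = code)
  }
  hidden <- setdiff(bn$dag$nodes, c(target, names(ev$hard)))
  ord <- min_fill_order(lapply(factors, `[[`, "vars"), hidden, bn$dag$nodes)
  for (v in ord) {
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    prod <- Reduce(function(a, b) factor_product(a, b, dims), factors[touch])
    factors <- c(factors[!touch], list(factor_marginalize(prod, v)))
  }
  final <- Reduce(function(a, b) factor_product(a, b, dims), factors)
  stopifnot(identical(final$vars, target) || !length(final$vars))
  mass <- as.numeric(final$tbl)
  if (length(mass) != dims[[target]]) {
    stop2("internal error: elimination left wrong scope")
  }
  total <- sum(mass)
  if (total <= 0) stop2("impossible evidence: zero total probability")
  new_query_result(bn, target, mass / total, evidence, "elimination")
}

#' Posterior query under soft evidence
#'
#' Convenience wrapper running [eliminate_query()] (or the enumeration
#' oracle) under virtual evidence only. Uniform likelihoods reproduce the
#' no-evidence marginal; indicator likelihoods reproduce the matching hard
#' evidence query.
#'
#' @inheritParams enumerate_query
#' @param evidence A [virtual_evidence()].
#' @param method `"eliminate"` or `"enumerate"`.
#' @return A `bn_query`.
#' @export
query_soft <- function(bn, target, evidence, method = c("eliminate", "enumerate")) {
  method <- match.arg(method)
  if (!inherits(evidence, "bn_virtual_evidence")) {
    stop2("query_soft expects virtual_evidence()")
  }
  if (method == "eliminate") {
    eliminate_query(bn, target, evidence)
  } else {
    enumerate_query(bn, target, evidence)
  }
}

#' Single-category conditional risk sweep
#'
#' For every (predictor, category) pair, conditions the network on that
#' single observation and reports the probability of the designated
#' high-risk state of the target against the no-evidence baseline, as a
#' signed percentage-point delta. Mirrors the one-node-at-a-time what-if
#' analysis of mortality-risk drivers.
#'
#' @param bn A fitted `bn_net`.
#' @param target Outcome variable (default: the schema outcome).
#' @param high_state Category of `target` treated as the high-risk state.
#' @param mode `"hard"` for hard conditioning, `"soft"` for a
#'   [soft_observation()] with weight `weight`.
#' @param weight Soft-evidence weight on the observed category.
#' @return A data frame with columns `variable`, `category`, `baseline`,
#'   `conditioned`, `delta_pp` (percentage points), ordered by schema
#'   declaration.
#' @export
risk_sweep <- function(bn, target = bn$schema$outcome,
                       high_state = "high",
                       mode = c("hard", "soft"), weight = 0.9) {
  mode <- match.arg(mode)
  cats <- schema_categories(bn$schema, target)
  if (!high_state %in% cats) {
    stop2("'", high_state, "' is not a category of '", target, "'")
  }
  baseline <- eliminate_query(bn, target)$distribution[[high_state]]
  predictors <- setdiff(schema_names(bn$schema), target)
  rows <- list()
  for (v in predictors) {
    for (cat in schema_categories(bn$schema, v)) {
      evid <- if (mode == "hard") {
        hard_evidence(stats::setNames(cat, v))
      } else {
        soft_observation(bn$schema, v, cat, weight)
      }
      cond <- eliminate_query(bn, target, evid)$distribution[[high_state]]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, category = cat, baseline = baseline,
        conditioned = cond, delta_pp = (cond - baseline) * 100,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compound what-if scenario query
#'
#' Conditions on several variables at once (hard or virtual evidence) and
#' reports the high-risk probability of the target with the baseline
#' attached — e.g. race and region jointly, or race, region and age group.
#'
#' @inheritParams risk_sweep
#' @param evidence Evidence referencing at least one variable.
#' @param name Optional scenario label carried into the result.
#' @return A one-row data frame with columns `scenario`, `baseline`,
#'   `conditioned`, `delta_pp`.
#' @export
scenario_query <- function(bn, target = bn$schema$outcome,
                           high_state = "high", evidence, name = NA_character_) {
  ev <- resolve_evidence(bn, evidence, target)
  if (!length(ev$hard) && !length(ev$virtual)) {
    stop2("scenario evidence must reference at least one variable")
  }
  baseline <- eliminate_query(bn, target)$distribution[[high_state]]
  cond <- eliminate_query(bn, target, evidence)$distribution[[high_state]]
  data.frame(scenario = name, baseline = baseline, conditioned = cond,
             delta_pp = (cond - baseline) * 100, stringsAsFactors = FALSE)
}
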