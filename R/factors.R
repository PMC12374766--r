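# Internal factor algebra for exact inference. A factor is a list with
# `vars` (character, possibly empty) and `tbl` (numeric array, one dimension
# per variable in `vars` order; a scalar when `vars` is empty).

new_factor <- function(vars, tbl) {
  list(vars = as.character(vars), tbl = tbl)
}

cpt_factor <- function(cpt) {
  new_factor(c(cpt$child, cpt$parents), cpt$prob)
}

factor_dims <- function(f) {
  if (!length(f$vars)) integer(0) else dim(f$tbl) %||% length(f$tbl)
}

# Expand f's table onto the variable set `uv` (a superset of f$vars) with
# per-variable dimensions `dims` (named). Missing variables broadcast.
factor_extend <- function(f, uv, dims) {
  if (identical(f$vars, uv)) return(f$tbl)
  extra <- setdiff(uv, f$vars)
  base <- if (length(f$vars)) f$tbl else as.numeric(f$tbl)
  # f's variables vary fastest, extras appended, then permute into uv order
  a <- array(base, dim = c(dims[f$vars], dims[extra]))
  aperm(a, match(uv, c(f$vars, extra)))
}

factor_product <- function(f, g, dims) {
  if (!length(f$vars) && !length(g$vars)) {
    return(new_factor(character(0), as.numeric(f$tbl) * as.numeric(g$tbl)))
  }
  uv <- union(f$vars, g$vars)
  new_factor(uv, factor_extend(f, uv, dims) * factor_extend(g, uv, dims))
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  keep <- setdiff(seq_along(f$vars), i)
  if (!length(keep)) {
    return(new_factor(character(0), sum(f$tbl)))
  }
  a <- aperm(array(f$tbl, dim = factor_dims(f)), c(i, keep))
  m <- matrix(a, nrow = dim(a)[1L])
  new_factor(f$vars[keep],
             array(colSums(m), dim = factor_dims(f)[keep]))
}

# Condition on var = code (drop the dimension).
factor_reduce <- function(f, var, code) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[i]] <- code
  tbl <- do.call(`[`, c(list(array(f$tbl, dim = factor_dims(f))), idx,
                        list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), i)
  if (!length(keep)) {
    return(new_factor(character(0), as.numeric(tbl)))
  }
  new_factor(f$vars[keep], array(tbl, dim = factor_dims(f)[keep]))
}

# Multiply a likelihood vector into the factor along `var` (virtual
# evidence: Pearl's construction multiplies the node's factor set by the
# likelihood before normalisation).
factor_weight <- function(f, var, weights) {
  i <- match(var, f$vars)
  stopifnot(!is.na(i))
  dims <- factor_dims(f)
  perm <- c(i, setdiff(seq_along(f$vars), i))
  a <- aperm(array(f$tbl, dim = dims), perm)
  a <- a * weights  # first dimension varies fastest: recycles correctly
  new_factor(f$vars, aperm(a, order(perm)))
}

# Min-fill elimination order over the interaction graph induced by factor
# scopes; deterministic ties broken by `declaration` order.
min_fill_order <- function(scopes, eliminate, declaration) {
  adj <- stats::setNames(vector("list", length(declaration)), declaration)
  for (sc in scopes) {
    for (v in sc) adj[[v]] <- union(adj[[v]], setdiff(sc, v))
  }
  order_out <- character(0)
  remaining <- eliminate[order(match(eliminate, declaration))]
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- adj[[v]]
      if (length(nb) < 2L) return(0L)
      cnt <- 0L
      for (a in seq_len(length(nb) - 1L)) {
        for (b in (a + 1L):length(nb)) {
          if (!nb[b] %in% adj[[nb[a]]]) cnt <- cnt + 1L
        }
      }
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]  # which.min keeps the earliest tie
    nb <- adj[[v]]
    for (a in nb) {
      adj[[a]] <- union(setdiff(adj[[a]], v), setdiff(nb, a))
    }
    adj[[v]] <- NULL
    order_out <- c(order_out, v)
    remaining <- setdiff(remaining, v)
  }
  order_out
}
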