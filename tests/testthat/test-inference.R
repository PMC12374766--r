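test_that("root marginals and Bayes-rule posteriors are exact", {
  ind <- independent_bn(list(u = c(0.7, 0.3), w = c(0.5, 0.5)))
  expect_equal(unname(enumerate_query(ind, "u")$distribution), c(0.7, 0.3))

  # P(a1 | b1) = 0.6*0.5 / (0.6*0.5 + 0.4*0.25) = 0.75
  bn <- chain_bn(0.6, 0.5, 0.25)
  for (f in list(enumerate_query, eliminate_query)) {
    post <- f(bn, "A", hard_evidence(B = "b1"))$distribution
    expect_equal(post[["a1"]], 0.75, tolerance = 1e-12)
  }
})

test_that("variable elimination matches the enumeration oracle on random nets", {
  set.seed(77)
  worst <- 0
  for (i in 1:200) {
    bn <- random_bn(sample(3:7, 1), 3)
    target <- sample(bn$dag$nodes, 1)
    ev <- random_hard_evidence(bn, exclude = target)
    q1 <- tryCatch(enumerate_query(bn, target, ev), error = function(e) e)
    q2 <- tryCatch(eliminate_query(bn, target, ev), error = function(e) e)
    if (inherits(q1, "error")) {
      expect_true(inherits(q2, "error"))
      next
    }
    worst <- max(worst, max_abs(q1$distribution, q2$distribution))
  }
  expect_lt(worst, 1e-9)
})

test_that("hard conditioning obeys the law of total probability", {
  set.seed(55)
  bn <- random_bn(6, 3, edge_prob = 0.5)
  target <- bn$dag$nodes[1]
  for (v in setdiff(bn$dag$nodes, target)) {
    marg_v <- eliminate_query(bn, v)$distribution
    mix <- 0
    for (cat in names(marg_v)) {
      post <- eliminate_query(bn, target,
                              hard_evidence(stats::setNames(cat, v)))
      mix <- mix + marg_v[[cat]] * post$distribution
    }
    expect_lt(max_abs(mix, eliminate_query(bn, target)$distribution), 1e-9)
  }
})

test_that("evidence beyond the Markov blanket is screened off", {
  # chain A -> B -> C: given B, C carries no extra information about A
  schema <- cohort_schema(list(variable_spec("A", c("a1", "a2")),
                               variable_spec("B", c("b1", "b2")),
                               variable_spec("C", c("c1", "c2"))), "C")
  dag <- validate_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  bn <- bayes_net(schema, dag, list(
    A = new_cpt("A", character(0), c(0.6, 0.4), schema),
    B = new_cpt("B", "A", array(c(0.8, 0.2, 0.3, 0.7), c(2, 2)), schema),
    C = new_cpt("C", "B", array(c(0.9, 0.1, 0.4, 0.6), c(2, 2)), schema)))
  with_b <- enumerate_query(bn, "A", hard_evidence(B = "b1"))$distribution
  with_bc <- enumerate_query(bn, "A",
                             hard_evidence(B = "b1", C = "c2"))$distribution
  expect_equal(with_b, with_bc, tolerance = 1e-12)
})

test_that("impossible evidence errors instead of returning NaN", {
  schema <- cohort_schema(list(variable_spec("A", c("a1", "a2")),
                               variable_spec("B", c("b1", "b2"))), "B")
  dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  bn <- bayes_net(schema, dag, list(
    A = new_cpt("A", character(0), c(1, 0), schema),
    B = new_cpt("B", "A", array(c(1, 0, 0.5, 0.5), c(2, 2)), schema)))
  expect_error(enumerate_query(bn, "B", hard_evidence(A = "a2")),
               "impossible evidence")
  expect_error(eliminate_query(bn, "B", hard_evidence(A = "a2")),
               "impossible evidence")
})

test_that("query probabilities are invariant to consistent relabelling", {
  set.seed(101)
  bn <- random_bn(5, 3, edge_prob = 0.5)
  target <- bn$dag$nodes[2]
  ev_var <- bn$dag$nodes[4]
  ev_cat <- bn$schema$variables[[ev_var]]$categories[1]
  ref <- eliminate_query(bn, target,
                         hard_evidence(stats::setNames(ev_cat, ev_var)))

  relabel <- function(x) paste0("LBL_", toupper(x))
  schema2 <- cohort_schema(lapply(bn$schema$variables, function(v)
    variable_spec(v$name, relabel(v$categories))), bn$schema$outcome)
  cpts2 <- lapply(bn$cpts, function(cpt)
    new_cpt(cpt$child, cpt$parents, cpt$prob, schema2))
  bn2 <- bayes_net(schema2, bn$dag, cpts2)
  out <- eliminate_query(bn2, target,
                         hard_evidence(stats::setNames(relabel(ev_cat),
                                                       ev_var)))
  expect_equal(unname(out$distribution), unname(ref$distribution),
               tolerance = 1e-12)
})

test_that("evidence validation rejects malformed queries", {
  bn <- chain_bn()
  expect_error(eliminate_query(bn, "B", hard_evidence(B = "b1")),
               "cannot carry evidence")
  expect_error(eliminate_query(bn, "B", hard_evidence(Z = "b1")),
               "unknown evidence variable")
  expect_error(eliminate_query(bn, "B", hard_evidence(A = "nope")),
               "not a category")
  expect_error(eliminate_query(bn, "nope"), "unknown target")
  expect_error(hard_evidence(A = "a1", A = "a2"), "assigned twice")
})

test_that("risk sweep reports deltas against a reproducible baseline", {
  # independent outcome: every delta is exactly zero
  ind <- independent_bn(list(u = c(0.4, 0.6), y = c(0.7, 0.3)))
  sw <- risk_sweep(ind, target = "y", high_state = "y2")
  expect_equal(sw$delta_pp, rep(0, nrow(sw)), tolerance = 1e-9)

  # a net built to give P(y2 | u = u2) - P(y2) = +0.085 exactly
  schema <- cohort_schema(list(variable_spec("u", c("u1", "u2")),
                               variable_spec("y", c("y1", "y2"))), "y")
  dag <- validate_dag(c("u", "y"), rbind(c("u", "y")))
  p_u2 <- 0.5
  p_y2_u1 <- 0.30
  p_y2_u2 <- p_y2_u1 + 0.085 / (1 - p_u2)  # marginal + 8.5pp at u = u2
  bn <- bayes_net(schema, dag, list(
    u = new_cpt("u", character(0), c(1 - p_u2, p_u2), schema),
    y = new_cpt("y", "u", array(c(1 - p_y2_u1, p_y2_u1,
                                  1 - p_y2_u2, p_y2_u2), c(2, 2)), schema)))
  sw2 <- risk_sweep(bn, target = "y", high_state = "y2")
  expect_equal(sw2$delta_pp[sw2$variable == "u" & sw2$category == "u2"],
               8.5, tolerance = 1e-9)
  expect_equal(unique(sw2$baseline),
               eliminate_query(bn, "y")$distribution[["y2"]])
})

test_that("scenario queries agree with the sweep and with the oracle", {
  bn0 <- default_ha_ground_truth()
  sw <- risk_sweep(bn0)
  sc <- scenario_query(bn0, evidence = hard_evidence(hypertension = "yes"),
                       name = "htn")
  expect_equal(sc$conditioned,
               sw$conditioned[sw$variable == "hypertension" &
                              sw$category == "yes"], tolerance = 1e-12)

  compound <- list(hard_evidence(race = "black", region = "midwest"))
  sc2 <- scenario_query(bn0, evidence = compound, name = "bm")
  oracle <- enumerate_query(bn0, "mortality",
                            hard_evidence(race = "black",
                                          region = "midwest"))
  expect_equal(sc2$conditioned, oracle$distribution[["high"]],
               tolerance = 1e-9)
  expect_error(scenario_query(bn0, evidence = list()), "at least one")
})
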