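#' Serialise a fitted network to JSON
#'
#' Writes schema (ordered variables and outcome), edge list and every CPT
#' (flat probability vector in child-first layout) to a JSON document.
#' Numbers are written at full precision so that
#' [read_model_json()] round-trips the model bit-exactly.
#'
#' @param bn A `bn_net`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(bn, path) {
  doc <- list(
    format = "habnet-model",
    version = 1L,
    variables = lapply(bn$schema$variables, `[[`, "categories"),
    outcome = bn$schema$outcome,
    edges = apply(bn$dag$edges, 1L, function(e) paste(e[1], "->", e[2])),
    cpts = lapply(bn$cpts, function(cpt) {
      list(parents = cpt$parents, prob = as.numeric(cpt$prob))
    })
  )
  # digits = I(17) keeps the shortest exact decimal form: doubles survive
  # the write/read cycle bit-for-bit
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted network from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return A `bn_net`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "habnet-model")) {
    stop2("'", path, "' is not a habnet model document")
  }
  schema <- cohort_schema(
    lapply(names(doc$variables), function(nm)
      variable_spec(nm, doc$variables[[nm]])),
    outcome = doc$outcome)
  dag <- validate_dag(names(doc$variables), parse_edges(doc$edges))
  cpts <- lapply(names(doc$cpts), function(node) {
    new_cpt(node, doc$cpts[[node]]$parents, doc$cpts[[node]]$prob, schema)
  })
  names(cpts) <- names(doc$cpts)
  bayes_net(schema, dag, cpts)
}

parse_edges <- function(edges) {
  if (!length(edges)) return(NULL)
  parts <- strsplit(as.character(edges), "->", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    stop2("malformed edge '", edges[which(bad)[1]],
          "' (expected 'parent -> child')")
  }
  do.call(rbind, lapply(parts, trimws))
}

#' Read a schema + DAG model-configuration document
#'
#' A YAML (or JSON) document with three keys: `variables` (variable name to
#' ordered category list), `edges` (list of `"parent -> child"` strings) and
#' `outcome`. The shipped default lives at
#' `system.file("extdata", "ha_model_config.yaml", package = "habnet")`.
#'
#' @param path Document path (`.yaml`/`.yml` or `.json`).
#' @return List with elements `schema` (`bn_schema`) and `dag` (`bn_dag`).
#' @export
read_model_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("variables", "outcome")) {
    if (is.null(doc[[key]])) stop2("model config is missing '", key, "'")
  }
  schema <- cohort_schema(
    lapply(names(doc$variables), function(nm)
      variable_spec(nm, unlist(doc$variables[[nm]]))),
    outcome = doc$outcome)
  dag <- validate_dag(names(doc$variables), parse_edges(unlist(doc$edges)))
  list(schema = schema, dag = dag)
}

#' Read a scenario-configuration document
#'
#' YAML/JSON with a top-level `scenarios` list of
#' `{name, evidence, mode, weight}` entries. An evidence value may be a
#' single category (conditioned per `mode`) or a list of categories
#' (encoded as an indicator likelihood over the set — "one of these").
#'
#' @param path Document path.
#' @return List of scenario definition lists.
#' @export
read_scenarios <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scen <- doc$scenarios %||% doc
  lapply(scen, function(s) {
    if (is.null(s$name) || is.null(s$evidence)) {
      stop2("each scenario needs 'name' and 'evidence'")
    }
    s
  })
}

#' Default compound risk scenarios
#'
#' The four shipped multi-variable what-if scenarios: Black patients in the
#' Midwest; Black patients in the South; Black patients in the Midwest aged
#' 65 or above; and Hispanic patients covered by Medicare or Medicaid (the
#' payer pair is encoded as an indicator likelihood over the two
#' categories).
#'
#' @return List of scenario definitions as used by [run_analysis()].
#' @export
default_ha_scenarios <- function() {
  list(
    list(name = "black_midwest",
         evidence = list(race = "black", region = "midwest")),
    list(name = "black_south",
         evidence = list(race = "black", region = "south")),
    list(name = "black_midwest_ge65",
         evidence = list(race = "black", region = "midwest", age = "ge65")),
    list(name = "hispanic_public_payer",
         evidence = list(race = "hispanic",
                         insurance = c("medicare", "medicaid")))
  )
}

#' Turn a scenario evidence map into evidence objects
#'
#' Converts a named `variable = category` map (as found in scenario
#' documents) into [hard_evidence()] / [virtual_evidence()] objects. A
#' value with several categories becomes an indicator likelihood over the
#' set ("one of these"); single categories become hard evidence, or a
#' [soft_observation()] when `mode = "soft"`.
#'
#' @param schema A `bn_schema`.
#' @param evidence Named list mapping variables to one or more categories.
#' @param mode `"hard"` or `"soft"` conditioning for single categories.
#' @param weight Soft-evidence weight.
#' @return A list of evidence objects accepted by the query functions.
#' @export
build_scenario_evidence <- function(schema, evidence, mode = "hard",
                                    weight = 0.9) {
  hard <- character(0)
  virt <- list()
  for (v in names(evidence)) {
    vals <- unlist(evidence[[v]])
    cats <- schema_categories(schema, v)
    bad <- setdiff(vals, cats)
    if (length(bad)) {
      stop2("'", bad[1], "' is not a category of '", v, "'")
    }
    if (length(vals) > 1L) {
      virt[[v]] <- as.numeric(cats %in% vals)
    } else if (identical(mode, "soft")) {
      virt[[v]] <- unclass(soft_observation(schema, v, vals, weight))[[v]]
    } else {
      hard[v] <- vals
    }
  }
  out <- list()
  if (length(hard)) out <- c(out, list(hard_evidence(hard)))
  if (length(virt)) out <- c(out, list(virtual_evidence(virt)))
  out
}
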