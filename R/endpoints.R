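#' Define one endpoint of the benefit-risk value tree
#'
#' An endpoint is one node of the value tree used throughout the package:
#' a named time-to-first-event outcome, classified as a benefit (ischemic
#' event prevented by treatment) or a risk (bleeding event caused by it),
#' and flagged fatal or nonfatal. To avoid double-counting deaths, exactly
#' one endpoint per MCDA model is fatal: the composite of cardiovascular
#' death and fatal major bleeding in model 1, all-cause death in model 2;
#' every other endpoint is nonfatal by definition.
#'
#' @param name Endpoint label (character scalar).
#' @param role `"benefit"` or `"risk"`.
#' @param fatal Logical; is this the fatal endpoint of its model?
#' @param in_model1,in_model2 Logical; membership in MCDA models 1 and 2.
#' @return A one-row `data.frame` with columns `endpoint`, `role`, `fatal`,
#'   `in_model1`, `in_model2`.
#' @seealso [value_tree()], [voyager_value_tree()]
#' @export
endpoint_spec <- function(name, role = c("benefit", "risk"), fatal = FALSE,
                          in_model1 = TRUE, in_model2 = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role)
  data.frame(endpoint = name, role = role, fatal = isTRUE(fatal),
             in_model1 = isTRUE(in_model1), in_model2 = isTRUE(in_model2),
             stringsAsFactors = FALSE)
}

#' Assemble a value tree from endpoint specifications
#'
#' Binds endpoint specifications into a value tree and validates the
#' structural invariants: unique endpoint names and exactly one fatal
#' endpoint in each model that has any endpoints at all.
#'
#' @param ... One-row data frames from [endpoint_spec()] (or an equivalent
#'   data frame passed as a single argument).
#' @return A `data.frame` of class `br_value_tree`.
#' @export
value_tree <- function(...) {
  specs <- list(...)
  tree <- if (length(specs) == 1L && is.data.frame(specs[[1]]) &&
              nrow(specs[[1]]) > 1L) specs[[1]] else do.call(rbind, specs)
  required <- c("endpoint", "role", "fatal", "in_model1", "in_model2")
  if (!all(required %in% names(tree)))
    stop("value tree needs columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(tree$endpoint))
    stop("duplicate endpoint names in value tree")
  for (m in c("in_model1", "in_model2")) {
    nf <- sum(tree$fatal & tree[[m]])
    if (any(tree[[m]]) && nf != 1L)
      stop("each model must contain exactly one fatal endpoint (", m,
           " has ", nf, ")")
  }
  class(tree) <- c("br_value_tree", "data.frame")
  tree
}

#' @export
print.br_value_tree <- function(x, ...) {
  cat("Benefit-risk value tree (", nrow(x), " endpoints)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

model_endpoints <- function(tree, model) {
  stopifnot(model %in% c(1, 2))
  col <- if (model == 1) "in_model1" else "in_model2"
  tree$endpoint[tree[[col]]]
}

#' The default peripheral-artery-disease value tree
#'
#' Seven endpoints form MCDA model 1: the fatal composite (cardiovascular
#' death plus fatal major bleeding) and six nonfatal endpoints — major
#' amputation of vascular cause, intracranial-hemorrhage (ICH) major
#' bleeding, acute limb ischemia (ALI), ischemic stroke, myocardial
#' infarction (MI), and non-ICH major bleeding. Model 2 swaps the fatal
#' composite for all-cause death and is otherwise identical. Ischemic
#' endpoints are benefits (treatment prevents them), bleeding endpoints are
#' risks; the fatal endpoints, where the observed excess runs against
#' treatment, are carried on the risk side for NNT/NNH labelling.
#'
#' @return A `br_value_tree` with eight rows (seven per model).
#' @export
voyager_value_tree <- function() {
  value_tree(
    endpoint_spec("fatal_composite",       "risk",    fatal = TRUE,
                  in_model1 = TRUE,  in_model2 = FALSE),
    endpoint_spec("all_cause_death",       "risk",    fatal = TRUE,
                  in_model1 = FALSE, in_model2 = TRUE),
    endpoint_spec("nonfatal_amputation",   "benefit"),
    endpoint_spec("nonfatal_ich_bleed",    "risk"),
    endpoint_spec("nonfatal_ali",          "benefit"),
    endpoint_spec("nonfatal_stroke",       "benefit"),
    endpoint_spec("nonfatal_mi",           "benefit"),
    endpoint_spec("nonfatal_non_ich_bleed", "risk")
  )
}

#' Specify an endpoint weight through its health state utility
#'
#' MCDA weights derive from health state utility values (HSUVs): a state
#' with utility u in \[0,1\] (1 = perfect health, 0 = death) gets weight
#' w = 1 - u, so one weighted event equals w deaths. The fatal endpoint has
#' utility 0 and weight exactly 1. Uncertainty in the utility is described
#' by a distribution family used by the Monte Carlo layer.
#'
#' @param endpoint Endpoint name.
#' @param utility_mean Mean HSUV in \[0,1\].
#' @param utility_sd Standard deviation of the utility (>= 0).
#' @param family `"beta"`, `"truncated-normal"`, or `"fixed"`. With
#'   `utility_sd = 0` every family degenerates to the point weight.
#' @return A one-row `data.frame` with columns `endpoint`, `utility_mean`,
#'   `utility_sd`, `family`, `weight_mean`.
#' @export
weight_spec <- function(endpoint, utility_mean, utility_sd = 0,
                        family = c("beta", "truncated-normal", "fixed")) {
  family <- match.arg(family)
  stopifnot(length(utility_mean) == 1L, utility_mean >= 0, utility_mean <= 1,
            length(utility_sd) == 1L, utility_sd >= 0)
  data.frame(endpoint = endpoint, utility_mean = utility_mean,
             utility_sd = utility_sd, family = family,
             weight_mean = 1 - utility_mean, stringsAsFactors = FALSE)
}

#' Weight implied by a health state utility
#'
#' @param spec A weight specification from [weight_spec()] (or any data
#'   frame with a `utility_mean` column), or a bare numeric utility.
#' @return The mean weight `1 - utility_mean`.
#' @export
weight_from_utility <- function(spec) {
  u <- if (is.numeric(spec)) spec else spec$utility_mean
  stopifnot(all(u >= 0 & u <= 1))
  1 - u
}

#' Published utility weights for the default value tree
#'
#' Mean weights (1 - utility) as published: 1.00 for the fatal composite,
#' 0.59 amputation, 0.42 ICH bleeding, 0.36 ALI, 0.35 ischemic stroke,
#' 0.22 MI, 0.22 non-ICH bleeding. The publication's utility SDs live in
#' supplementary material that is not reproduced here, so the dispersion is
#' a package default: `utility_sd_nonfatal` (0.10, a typical between-study
#' spread for literature-derived HSUVs) for every nonfatal endpoint and 0
#' for the fatal endpoints, whose weight is exactly 1. All-cause death
#' (model 2) is included with utility 0.
#'
#' @param utility_sd_nonfatal Utility SD applied to each nonfatal endpoint.
#' @param family Distribution family for nonfatal weights.
#' @return A `data.frame` of weight specifications, one row per endpoint.
#' @export
voyager_weights <- function(utility_sd_nonfatal = 0.10,
                            family = c("beta", "truncated-normal", "fixed")) {
  family <- match.arg(family)
  u <- c(fatal_composite = 0, all_cause_death = 0,
         nonfatal_amputation = 0.41, nonfatal_ich_bleed = 0.58,
         nonfatal_ali = 0.64, nonfatal_stroke = 0.65,
         nonfatal_mi = 0.78, nonfatal_non_ich_bleed = 0.78)
  rows <- lapply(names(u), function(e) {
    fatal <- e %in% c("fatal_composite", "all_cause_death")
    weight_spec(e, u[[e]],
                utility_sd = if (fatal) 0 else utility_sd_nonfatal,
                family = if (fatal) "fixed" else family)
  })
  do.call(rbind, rows)
}

#' Published per-endpoint aggregate results (ITT analysis, model 1)
#'
#' The printed intention-to-treat per-arm incidence rates (per 10 000
#' patient-years), Wald rate differences with 95% CIs, and mean weights for
#' the seven model-1 endpoints. These aggregates are the input to the
#' desk-scale analysis path: deterministic MCDA scoring and Monte Carlo
#' uncertainty propagation can be run directly from this table without
#' patient-level data.
#'
#' @return A `data.frame` with columns `endpoint`, `rate_active`,
#'   `rate_control`, `delta`, `ci_lo`, `ci_hi`, `weight_mean`. Rates are
#'   active (rivaroxaban + aspirin) vs control (aspirin alone), scaled per
#'   10 000 patient-years.
#' @export
voyager_table1 <- function() {
  data.frame(
    endpoint = c("fatal_composite", "nonfatal_amputation",
                 "nonfatal_ich_bleed", "nonfatal_ali", "nonfatal_stroke",
                 "nonfatal_mi", "nonfatal_non_ich_bleed"),
    rate_active  = c(264.2, 120.5, 22.7, 191.0, 76.3, 141.0, 77.6),
    rate_control = c(227.7, 142.5, 20.2, 291.3, 90.4, 154.3, 51.9),
    delta        = c(36.5, -21.9, 2.5, -100.3, -14.1, -13.3, 25.7),
    ci_lo        = c(-12.1, -57.9, -11.9, -149.6, -42.6, -51.5, 0.5),
    ci_hi        = c(85.1, 14.1, 17.0, -51.0, 14.5, 24.8, 50.8),
    weight_mean  = c(1.00, 0.59, 0.42, 0.36, 0.35, 0.22, 0.22),
    stringsAsFactors = FALSE
  )
}
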