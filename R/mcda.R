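#' Per-endpoint contribution to the MCDA score difference
#'
#' The theoretical contribution of one endpoint is its between-arm rate
#' difference times its mean weight, `c = w * delta`, in utility death
#' equivalents per 10 000 patient-years.
#'
#' @param delta Rate difference (active - control, per 10 000
#'   patient-years), or a [rate_difference()] row.
#' @param w Weight in \[0,1\].
#' @return Numeric contribution(s).
#' @export
contribution <- function(delta, w) {
  if (is.data.frame(delta)) delta <- delta$delta
  stopifnot(all(w >= 0 & w <= 1))
  w * delta
}

#' Fit the utility-weighted MCDA benefit-risk model
#'
#' The core estimator of the package: a linear additive multi-criteria
#' decision analysis over a model's endpoints, with weights derived from
#' health state utilities (w = 1 - utility). The between-arm score
#' difference is
#' \deqn{\Delta S = \sum_i w_i \, \Delta r_i,}
#' where \eqn{\Delta r_i} is endpoint i's incidence-rate difference
#' (active - control, per 10 000 patient-years). Because the fatal
#' endpoint carries weight 1, \eqn{\Delta S} reads as a utility-equivalent
#' number of deaths per 10 000 patient-years; negative values mean
#' benefits outweigh risks in favour of the active treatment. No value
#' normalisation or range constraint is applied: the value functions are
#' linear by design.
#'
#' When per-arm rates are available the per-arm scores
#' \eqn{S_a = \sum_i w_i r_{a,i}} are reported too, and
#' `score_difference = score_active - score_control` exactly.
#'
#' @param rd Rate-difference table: [rate_table()],
#'   [aggregate_rate_table()], or any data frame with `endpoint` and
#'   `delta` (optionally `rate_active`, `rate_control`, `se`).
#' @param weights Weight specifications ([weight_spec()] rows /
#'   [voyager_weights()]), or a named numeric vector of weights.
#' @param model MCDA model (1 or 2) used to select endpoints when `tree`
#'   is given; otherwise all endpoints of `rd` enter.
#' @param tree Optional `br_value_tree` restricting `rd` to the model's
#'   endpoints.
#' @return An object of class `br_mcda` with elements `contributions`
#'   (named numeric), `score_active`, `score_control`, `score_difference`,
#'   `weights`, `rd`, `model`, and `units`.
#' @seealso [run_monte_carlo()] for uncertainty propagation,
#'   [one_way_sensitivity()], [temporal_mcda()]
#' @export
br_mcda <- function(rd, weights, model = 1, tree = NULL) {
  if (!is.null(tree)) {
    eps <- model_endpoints(tree, model)
    missing_ep <- setdiff(eps, rd$endpoint)
    if (length(missing_ep))
      stop("no rate difference for model endpoint(s): ",
           paste(missing_ep, collapse = ", "))
    rd <- rd[rd$endpoint %in% eps, , drop = FALSE]
  }
  w <- resolve_weights(weights, rd$endpoint)
  contr <- setNames(contribution(rd$delta, w), rd$endpoint)
  has_rates <- !is.null(rd$rate_active) && !anyNA(rd$rate_active)
  score_a <- if (has_rates) sum(w * rd$rate_active) else NA_real_
  score_c <- if (has_rates) sum(w * rd$rate_control) else NA_real_
  structure(list(contributions = contr,
                 score_active = score_a, score_control = score_c,
                 score_difference = sum(contr),
                 weights = setNames(w, rd$endpoint), rd = rd, model = model,
                 units = "utility death equivalents per 10 000 patient-years"),
            class = "br_mcda")
}

#' @rdname br_mcda
#' @export
mcda_score_difference <- br_mcda

# weights may be a weight_spec table or a named numeric vector; duplicates
# and missing endpoints are configuration errors
resolve_weights <- function(weights, endpoints) {
  if (is.data.frame(weights)) {
    if (anyDuplicated(weights$endpoint))
      stop("duplicate weight specification for: ",
           paste(unique(weights$endpoint[duplicated(weights$endpoint)]),
                 collapse = ", "))
    w <- setNames(weights$weight_mean, weights$endpoint)
  } else {
    if (is.null(names(w <- weights)))
      stop("weights must be named by endpoint")
    if (anyDuplicated(names(w))) stop("duplicate weight for an endpoint")
  }
  missing_w <- setdiff(endpoints, names(w))
  if (length(missing_w))
    stop("no weight for endpoint(s): ", paste(missing_w, collapse = ", "))
  out <- w[endpoints]
  stopifnot(all(out >= 0 & out <= 1))
  unname(out)
}

#' @export
print.br_mcda <- function(x, digits = 1, ...) {
  cat("Utility-weighted MCDA benefit-risk (model ", x$model, ")\n",
      sep = "")
  cat("Score difference (active - control): ",
      format(round(x$score_difference, digits), nsmall = digits), " ",
      x$units, "\n", sep = "")
  invisible(x)
}

#' @export
summary.br_mcda <- function(object, digits = 1, ...) {
  tab <- data.frame(endpoint = names(object$contributions),
                    delta = object$rd$delta,
                    weight = object$weights,
                    contribution = unname(object$contributions),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, score_difference = object$score_difference,
                 score_active = object$score_active,
                 score_control = object$score_control,
                 model = object$model, units = object$units,
                 digits = digits),
            class = "summary.br_mcda")
}

#' @export
print.summary.br_mcda <- function(x, ...) {
  cat("Utility-weighted MCDA benefit-risk (model ", x$model, ")\n\n",
      sep = "")
  tab <- x$table
  tab$delta <- round(tab$delta, x$digits)
  tab$contribution <- round(tab$contribution, x$digits)
  print.data.frame(tab, row.names = FALSE)
  cat("\nScore difference: ", round(x$score_difference, x$digits), " ",
      x$units, "\n", sep = "")
  if (!is.na(x$score_active))
    cat("Per-arm scores: active ", round(x$score_active, x$digits),
        ", control ", round(x$score_control, x$digits), "\n", sep = "")
  cat("(negative favours the active arm)\n")
  invisible(x)
}

#' @export
coef.br_mcda <- function(object, ...) object$contributions

#' Simulate score-difference draws from a fitted MCDA model
#'
#' Draws from the uncertainty distribution of the score difference —
#' Gaussian rate differences (CI-derived) or gamma rates (count-derived)
#' combined with the fitted weights — i.e. the Monte Carlo layer viewed
#' through the `simulate()` generic.
#'
#' @param object A `br_mcda` fit.
#' @param nsim Number of draws.
#' @param seed RNG seed.
#' @param weights Weight specifications; defaults to the fixed fitted
#'   weights.
#' @param ... Passed to [mc_config()].
#' @return Numeric vector of `nsim` score-difference draws.
#' @export
simulate.br_mcda <- function(object, nsim = 1000, seed = 1L,
                             weights = NULL, ...) {
  if (is.null(weights)) weights <- object$weights
  mc <- run_monte_carlo(object$rd, weights = weights, model = object$model,
                        config = mc_config(n_runs = nsim, seed = seed, ...))
  mc$draws
}

#' Monte Carlo confidence interval for the MCDA score difference
#'
#' Runs [run_monte_carlo()] on the fitted object's rate differences and
#' weight specifications and returns the percentile interval.
#'
#' @param object A `br_mcda` fit whose `rd` carries `se` (aggregate path)
#'   or per-arm counts.
#' @param parm Ignored (single parameter).
#' @param level Confidence level.
#' @param weights Weight specifications for uncertainty; defaults to the
#'   fixed fitted weights.
#' @param ... Passed to [mc_config()] (e.g. `n_runs`, `seed`).
#' @export
confint.br_mcda <- function(object, parm, level = 0.95, weights = NULL, ...) {
  if (is.null(weights)) weights <- object$weights
  mc <- run_monte_carlo(object$rd, weights = weights, model = object$model,
                        config = mc_config(...))
  q <- stats::quantile(mc$draws, c((1 - level) / 2, 1 - (1 - level) / 2))
  matrix(q, nrow = 1,
         dimnames = list("score_difference", names(q)))
}
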