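#' Forest-plot table of excess events per 10 000 patient-years
#'
#' Orders endpoints for benefit-risk display: fatal/irreversible endpoints
#' first, then benefits, then risks, each alphabetically — a deterministic
#' order across runs. Signed excess is active minus control; NNT/NNH is
#' appended.
#'
#' @param rd Rate-difference table.
#' @param tree A `br_value_tree` supplying roles and fatal flags.
#' @return Data frame `endpoint`, `group`, `excess`, `ci_lo`, `ci_hi`,
#'   `nn`, `nn_type`.
#' @export
forest_table <- function(rd, tree) {
  if (nrow(rd) == 0L) stop("empty rate-difference table")
  info <- tree[match(rd$endpoint, tree$endpoint), , drop = FALSE]
  group <- ifelse(info$fatal, "fatal/irreversible",
                  ifelse(info$role == "benefit", "benefit", "risk"))
  nn <- nnt(rd, tree)
  out <- data.frame(endpoint = rd$endpoint, group = group,
                    excess = rd$delta, ci_lo = rd$ci_lo, ci_hi = rd$ci_hi,
                    nn = nn$nn, nn_type = nn$type, stringsAsFactors = FALSE)
  ord <- order(match(out$group, c("fatal/irreversible", "benefit", "risk")),
               out$endpoint)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
plot.br_analysis <- function(x, which = c("forest", "tornado", "mc",
                                          "temporal"), ...) {
  which <- match.arg(which)
  if (which == "forest") {
    ft <- x$forest
    n <- nrow(ft)
    graphics::plot(NA, xlim = range(c(ft$ci_lo, ft$ci_hi, 0)),
                   ylim = c(0.5, n + 0.5), yaxt = "n",
                   xlab = "excess events per 10 000 patient-years",
                   ylab = "", main = paste("Benefit-risk forest,", x$scope$name))
    graphics::axis(2, at = rev(seq_len(n)), labels = ft$endpoint, las = 1,
                   cex.axis = 0.7)
    graphics::segments(ft$ci_lo, rev(seq_len(n)), ft$ci_hi, rev(seq_len(n)))
    graphics::points(ft$excess, rev(seq_len(n)), pch = 16)
    graphics::abline(v = 0, lty = 2)
  } else if (which == "tornado") plot(x$sensitivity, ...)
  else if (which == "mc") plot(x$mc, ...)
  else if (!is.null(x$temporal)) plot(x$temporal, ...)
  invisible(x)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full benefit-risk analysis pipeline
#'
#' Composes the stages end to end: scoping, first-event extraction,
#' rate differences, deterministic MCDA, Monte Carlo uncertainty, one-way
#' weight sensitivity, and (patient-level input only) the temporal
#' trajectory. Accepts either a patient-level trial (a `br_trial`) or a
#' pre-aggregated per-endpoint table (rates/CIs, see
#' [aggregate_rate_table()]); requesting the temporal analysis on
#' aggregate input is an error, since Kaplan-Meier curves need
#' patient-level times.
#'
#' @param data A `br_trial` or an aggregate data frame.
#' @param tree A `br_value_tree`.
#' @param weights Weight specifications.
#' @param scope A [scope_config()] (ignored for aggregate input).
#' @param model MCDA model, 1 or 2.
#' @param mc An [mc_config()]; for patient-level input the rate model
#'   defaults to `"gamma-by-counts"`.
#' @param temporal Logical: compute the temporal trajectory (patient-level
#'   input only).
#' @param grid_days Grid for the temporal analysis.
#' @return An object of class `br_analysis` bundling `rate_table`,
#'   `forest`, `mcda`, `mc`, `sensitivity`, `temporal`, and `provenance`
#'   (config hash, seed, n_runs, totals, timestamp).
#' @export
run_pipeline <- function(data, tree = voyager_value_tree(),
                         weights = voyager_weights(),
                         scope = scope_config("itt"), model = 1,
                         mc = NULL, temporal = NULL,
                         grid_days = seq(90, 1100, by = 91)) {
  patient_level <- inherits(data, "br_trial")
  if (is.null(temporal)) temporal <- patient_level
  if (temporal && !patient_level)
    stop("temporal analysis needs patient-level data; aggregate input ",
         "carries no event times")
  if (is.null(mc))
    mc <- mc_config(rate_model = if (patient_level) "gamma-by-counts"
                    else "normal-by-ci")
  if (patient_level) {
    scoped <- apply_scope(data, scope)
    fev <- first_events(scoped, tree)
    rd <- rate_table(fev, tree, model = model)
    py_total <- sum(scoped$patients$censor_days) / DAYS_PER_YEAR
  } else {
    rd <- aggregate_rate_table(data)
    rd <- rd[rd$endpoint %in% model_endpoints(tree, model), , drop = FALSE]
    fev <- NULL
    py_total <- NA_real_
  }
  fit <- br_mcda(rd, weights, model = model, tree = tree)
  mc_res <- run_monte_carlo(rd, weights, model = model, tree = tree,
                            config = mc)
  sens <- one_way_sensitivity(rd, weights, model = model, tree = tree)
  temp <- if (temporal)
    temporal_mcda(fev, tree, weights, model = model,
                  grid_days = grid_days, seed = mc$seed) else NULL
  structure(list(
    scope = scope, model = model, rate_table = rd,
    forest = forest_table(rd, tree), mcda = fit, mc = mc_res,
    sensitivity = sens, temporal = temp,
    provenance = list(
      input = if (patient_level) "patient-level" else "aggregate",
      config_hash = config_hash(list(tree = unclass(tree),
                                     weights = weights,
                                     scope = unclass(scope), model = model,
                                     mc = unclass(mc))),
      seed = mc$seed, n_runs = mc$n_runs,
      total_patient_years = py_total,
      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "br_analysis")
}

#' @export
print.br_analysis <- function(x, ...) {
  cat("Benefit-risk analysis bundle (scope ", x$scope$name, ", model ",
      x$model, ")\n", sep = "")
  print(x$mcda)
  print(x$mc)
  invisible(x)
}

bundle_payload <- function(bundle) {
  list(scope = bundle$scope$name, model = bundle$model,
       rate_table = bundle$rate_table, forest = bundle$forest,
       mcda = list(contributions = as.list(bundle$mcda$contributions),
                   score_active = bundle$mcda$score_active,
                   score_control = bundle$mcda$score_control,
                   score_difference = bundle$mcda$score_difference,
                   units = bundle$mcda$units),
       mc = list(mean_delta_s = bundle$mc$mean_delta_s,
                 ci_lo = bundle$mc$ci_lo, ci_hi = bundle$mc$ci_hi,
                 p_benefit = bundle$mc$p_benefit,
                 mean_contributions = as.list(bundle$mc$mean_contributions),
                 n_runs = bundle$mc$n_runs),
       sensitivity = as.data.frame(unclass(bundle$sensitivity)),
       temporal = if (!is.null(bundle$temporal))
         as.data.frame(unclass(bundle$temporal)),
       provenance = bundle$provenance[names(bundle$provenance) !=
                                        "timestamp"])
}

#' Write an analysis bundle to disk
#'
#' `results.json` holds the full-precision machine-readable payload (the
#' volatile timestamp is excluded, so identical runs produce identical
#' files); `forest.csv` and `mcda.csv` hold the display tables with
#' one-decimal rounding, the convention for per-10 000-patient-year
#' scales. Stored results are never rounded.
#'
#' @param bundle A `br_analysis`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(bundle_payload(bundle),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  ft <- bundle$forest
  ft[c("excess", "ci_lo", "ci_hi", "nn")] <-
    lapply(ft[c("excess", "ci_lo", "ci_hi", "nn")], round, 1)
  utils::write.csv(ft, file.path(dir, "forest.csv"), row.names = FALSE)
  ms <- summary(bundle$mcda)$table
  ms[c("delta", "contribution")] <-
    lapply(ms[c("delta", "contribution")], round, 1)
  utils::write.csv(ms, file.path(dir, "mcda.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read the value tree and weights as one YAML config
#'
#' @param tree A `br_value_tree`.
#' @param weights Weight specification table.
#' @param path YAML file path.
#' @return `read_br_config()` returns `list(tree, weights)`.
#' @export
write_br_config <- function(tree, weights, path) {
  yaml::write_yaml(list(value_tree = as.list(as.data.frame(tree)),
                        weights = as.list(weights)), path)
  invisible(path)
}

#' @rdname write_br_config
#' @export
read_br_config <- function(path) {
  x <- yaml::read_yaml(path)
  tree <- value_tree(data.frame(x$value_tree, stringsAsFactors = FALSE))
  weights <- data.frame(x$weights, stringsAsFactors = FALSE)
  list(tree = tree, weights = weights)
}
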