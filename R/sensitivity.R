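#' One-way weight-distribution sensitivity (tornado)
#'
#' For each nonfatal endpoint in turn, the MCDA score difference is
#' recomputed with that endpoint's weight moved to its mean plus or minus
#' two standard deviations (clamped to \[0,1\]) while all other weights
#' stay at their means. The fatal endpoint is never varied: its weight is
#' 1 by construction. Because the value model is additive and linear, the
#' bar half-width before clamping is exactly `2 * SD * |delta|`.
#'
#' @param rd Rate-difference table (see [br_mcda()]).
#' @param weights Weight specifications with `utility_sd` columns.
#' @param model MCDA model, with `tree` selecting endpoints.
#' @param tree Optional `br_value_tree`.
#' @return A data frame of class `br_tornado`, one row per varied
#'   endpoint: `endpoint`, `base`, `delta_s_low` (weight at mean - 2 SD),
#'   `delta_s_high` (mean + 2 SD), `width`, sorted widest first.
#' @export
one_way_sensitivity <- function(rd, weights, model = 1, tree = NULL) {
  stopifnot(is.data.frame(weights), "utility_sd" %in% names(weights))
  if (!is.null(tree))
    rd <- rd[rd$endpoint %in% model_endpoints(tree, model), , drop = FALSE]
  fit <- br_mcda(rd, weights, model = model)
  base <- fit$score_difference
  w <- weights[match(rd$endpoint, weights$endpoint), , drop = FALSE]
  vary <- !(w$utility_mean == 0 & w$utility_sd == 0)  # exclude fatal
  rows <- lapply(which(vary), function(i) {
    m <- w$weight_mean[i]; s <- w$utility_sd[i]
    w_lo <- min(max(m - 2 * s, 0), 1)
    w_hi <- min(max(m + 2 * s, 0), 1)
    data.frame(endpoint = rd$endpoint[i], base = base,
               delta_s_low = base + (w_lo - m) * rd$delta[i],
               delta_s_high = base + (w_hi - m) * rd$delta[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$delta_s_high - out$delta_s_low)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("br_tornado", "data.frame")
  out
}

#' @export
plot.br_tornado <- function(x, ...) {
  n <- nrow(x)
  lo <- pmin(x$delta_s_low, x$delta_s_high)
  hi <- pmax(x$delta_s_low, x$delta_s_high)
  ord <- rev(seq_len(n))  # widest on top
  graphics::plot(NA, xlim = range(c(lo, hi, x$base[1])), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "MCDA score difference",
                 ylab = "", main = "One-way weight sensitivity (+/- 2 SD)",
                 ...)
  graphics::axis(2, at = ord, labels = x$endpoint, las = 1, cex.axis = 0.7)
  graphics::rect(lo, ord - 0.3, hi, ord + 0.3, col = "grey80")
  graphics::abline(v = x$base[1], lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Temporal benefit-risk on a Kaplan-Meier grid
#'
#' Evaluates the MCDA balance at successive horizons using Kaplan-Meier
#' cumulative incidences instead of constant rates:
#' \deqn{\Delta S(t) = 10000 \sum_i w_i \,
#'   (F_{a,i}(t) - F_{c,i}(t)),}
#' in utility death equivalents per 10 000 patients by time t (a
#' per-population scale, distinct from the per-patient-year scale of the
#' rate-based score). Pointwise 95% bands come from Monte Carlo over
#' Gaussian perturbations of each cumulative incidence with its Greenwood
#' standard error, combined with the weight distributions; normal-theory
#' bands (`band = "normal"`, fixed weights) are available as a cheaper
#' alternative.
#'
#' @param fev First-event table from [first_events()].
#' @param tree A `br_value_tree`.
#' @param weights Weight specifications or named weight vector.
#' @param model MCDA model.
#' @param grid_days Evaluation times; the default is a 3-month (91-day)
#'   grid from day 90 to day 1100. Times beyond both arms' last observed
#'   time are dropped with a warning.
#' @param band `"mc"` or `"normal"`.
#' @param n_mc Monte Carlo draws per grid time for the `"mc"` band.
#' @param seed RNG seed for the band.
#' @param active,control Arm labels.
#' @return A data frame of class `br_temporal`: `grid_days`, `delta_s_t`,
#'   `ci_lo_t`, `ci_hi_t`, with the band method in attribute `"band"`.
#' @export
temporal_mcda <- function(fev, tree, weights, model = 1,
                          grid_days = seq(90, 1100, by = 91),
                          band = c("mc", "normal"), n_mc = 2000, seed = 1L,
                          active = "active", control = "control") {
  band <- match.arg(band)
  stopifnot(all(diff(grid_days) > 0))
  eps <- model_endpoints(tree, model)
  w_mean <- resolve_weights(weights, eps)
  curves_a <- lapply(eps, function(e) km_curve(fev, e, active))
  curves_c <- lapply(eps, function(e) km_curve(fev, e, control))
  t_last <- min(max(attr(fev, "patients")$censor_days[
    attr(fev, "patients")$arm == active]),
    max(attr(fev, "patients")$censor_days[
      attr(fev, "patients")$arm == control]))
  if (any(grid_days > t_last)) {
    warning("grid truncated at day ", round(t_last),
            " (last observed time)")
    grid_days <- grid_days[grid_days <= t_last]
  }
  k <- length(eps)
  nt <- length(grid_days)
  Fa <- Sa <- Fc <- Sc <- matrix(0, nt, k)
  for (j in seq_len(k)) {
    Fa[, j] <- km_step(curves_a[[j]], "cuminc")(grid_days)
    Sa[, j] <- km_step(curves_a[[j]], "se")(grid_days)
    Fc[, j] <- km_step(curves_c[[j]], "cuminc")(grid_days)
    Sc[, j] <- km_step(curves_c[[j]], "se")(grid_days)
  }
  point <- PY_SCALE * as.vector((Fa - Fc) %*% w_mean)
  if (band == "normal") {
    se <- PY_SCALE * sqrt((Sa^2 + Sc^2) %*% w_mean^2)
    lo <- point - Z95 * se
    hi <- point + Z95 * se
  } else {
    lo <- hi <- numeric(nt)
    with_seed(seed, {
      W <- draw_weight_matrix(
        if (is.data.frame(weights))
          weights[weights$endpoint %in% eps, , drop = FALSE]
        else setNames(w_mean, eps),
        eps, n_mc, "spec")
      for (ti in seq_len(nt)) {
        Da <- matrix(stats::rnorm(n_mc * k, rep(Fa[ti, ], each = n_mc),
                                  rep(Sa[ti, ], each = n_mc)), n_mc, k)
        Dc <- matrix(stats::rnorm(n_mc * k, rep(Fc[ti, ], each = n_mc),
                                  rep(Sc[ti, ], each = n_mc)), n_mc, k)
        ds <- PY_SCALE * rowSums(W * (Da - Dc))
        q <- stats::quantile(ds, c(0.025, 0.975))
        lo[ti] <- q[1]; hi[ti] <- q[2]
      }
    })
  }
  out <- data.frame(grid_days = grid_days, delta_s_t = point,
                    ci_lo_t = as.vector(lo), ci_hi_t = as.vector(hi))
  attr(out, "band") <- band
  class(out) <- c("br_temporal", "data.frame")
  out
}

#' @export
plot.br_temporal <- function(x, ...) {
  graphics::plot(x$grid_days, x$delta_s_t, type = "l", lwd = 2,
                 ylim = range(c(x$ci_lo_t, x$ci_hi_t, 0)),
                 xlab = "days since randomization",
                 ylab = "MCDA score difference (per 10 000 patients)",
                 main = "Temporal benefit-risk", ...)
  graphics::lines(x$grid_days, x$ci_lo_t, lty = 2)
  graphics::lines(x$grid_days, x$ci_hi_t, lty = 2)
  graphics::abline(h = 0, col = "grey50")
  invisible(x)
}
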