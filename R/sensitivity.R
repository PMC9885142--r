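# Deterministic sensitivity analyses: the ICER-versus-volume curve,
# one-way and two-way parameter sweeps, and threshold (bisection)
# searches for the parameters tied to the navigation system.

# Registry of sweepable parameters: where each lives inside the parameter
# set, its valid domain, and any coupling rule applied when it moves.
# cost_imn drags cost_tha along at twice its value by default because the
# salvage THA cost is defined as twice the primary IMN cost; nav_purchase
# keeps maintenance at its fixed fraction of purchase automatically.
.param_registry <- list(
  p_safe_nav         = list(group = "clinical",  domain = c(0, 1)),
  p_safe_trad        = list(group = "clinical",  domain = c(0, 1)),
  annual_fail_safe   = list(group = "clinical",  domain = c(0, 1)),
  annual_fail_unsafe = list(group = "clinical",  domain = c(0, 1)),
  p_periop_death_imn = list(group = "clinical",  domain = c(0, 1)),
  p_periop_death_tha = list(group = "clinical",  domain = c(0, 1)),
  p_death_first_year = list(group = "clinical",  domain = c(0, 1)),
  u_nav              = list(group = "utilities", domain = c(0, 1)),
  u_trad             = list(group = "utilities", domain = c(0, 1)),
  u_tha              = list(group = "utilities", domain = c(0, 1)),
  disutility_salvage = list(group = "utilities", domain = c(-1, 0)),
  cost_imn           = list(group = "costs",     domain = c(0, Inf)),
  cost_tha           = list(group = "costs",     domain = c(0, Inf)),
  nav_purchase       = list(group = "costs",     domain = c(0, Inf)),
  annual_volume      = list(group = "costs",     domain = c(1e-9, Inf))
)

.set_param <- function(params, name, value, tie_tha_cost = TRUE,
                       tie_periop = TRUE) {
  info <- .param_registry[[name]]
  if (is.null(info)) stop("unknown parameter `", name, "`", call. = FALSE)
  if (value < info$domain[1] || value > info$domain[2])
    stop(sprintf("value %g outside the domain [%g, %g] of `%s`",
                 value, info$domain[1], info$domain[2], name), call. = FALSE)
  params[[info$group]][[name]] <- value
  if (name == "cost_imn" && tie_tha_cost)
    params$costs$cost_tha <- 2 * value
  if (name == "p_periop_death_imn" && tie_periop)
    params$clinical$p_periop_death_tha <- value
  params
}

# both arms at current parameters; single source for all DSA evaluations
.evaluate_pair <- function(params, conventions, wtp = params$economics$wtp) {
  nav <- run_cohort("navigated", params, conventions, trace = FALSE)
  trad <- run_cohort("traditional", params, conventions, trace = FALSE)
  icer(nav, trad, wtp = wtp)
}

#' ICER as a function of annual surgical volume
#'
#' Only the per-patient navigation cost depends on the volume, so the
#' curve follows the closed form `ICER(V) = A + B / V` exactly: `B` is the
#' annualized navigation cost (purchase amortization plus maintenance)
#' divided by the incremental QALYs, and `A` collects the
#' volume-independent incremental costs.  Both are computed analytically
#' from a single cohort run per arm and returned alongside the evaluated
#' grid.
#'
#' @param params An [imn_parameters()] object.
#' @param volumes Annual surgical volumes (cases/year) to evaluate.
#' @param conventions A [model_conventions()] object.
#' @return A `one_way_result` for parameter `annual_volume` with the
#'   evaluation grid, the ICER at each volume, the fitted closed form
#'   (`A`, `B`) and the direction of the relationship.
#' @examples
#' icer_vs_volume(default_parameters(), c(100, 200, 300))
#' @export
icer_vs_volume <- function(params = default_parameters(),
                           volumes = c(100, 200, 300),
                           conventions = model_conventions()) {
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)
  nav0 <- run_cohort("navigated", params, conventions,
                     include_navigation_cost = FALSE, trace = FALSE)
  trad <- run_cohort("traditional", params, conventions, trace = FALSE)
  dq <- nav0$total_qaly - trad$total_qaly
  df0 <- if (conventions$discount_cycle_zero)
    1 / (1 + params$economics$discount_rate) else 1
  annualized <- params$costs$nav_purchase / params$costs$amortization_years +
    params$costs$nav_maintenance_rate * params$costs$nav_purchase
  A <- (nav0$total_cost - trad$total_cost) / dq
  B <- annualized * df0 / dq
  icers <- A + B / volumes
  structure(list(parameter = "annual_volume", grid = volumes, icers = icers,
                 A = A, B = B, delta_qaly = dq,
                 direction = if (B > 0) "negative" else "flat"),
            class = "one_way_result")
}

#' One-way deterministic sensitivity analysis
#'
#' Sweeps one parameter across a range (all else at base values),
#' recomputing both arms and the ICER at each grid point.  The direction
#' of the relationship with the ICER is classified from the sign of the
#' least-squares slope, as `"flat"` when the ICER moves by less than
#' `flat_tol` (relative to the base-case ICER) across the whole range.
#' When sweeping `cost_imn` the salvage THA cost moves with it at twice
#' its value (the costing rule of the model); disable with
#' `tie_tha_cost = FALSE`.  Sweeping `p_periop_death_imn` moves the THA
#' perioperative mortality with it (the model sets both to the same
#' published 6%).
#'
#' @param params An [imn_parameters()] object.
#' @param parameter Name of the parameter to sweep (see
#'   `navicer:::.param_registry` for valid names, plus `"annual_volume"`).
#' @param range Length-2 numeric range; default plus/minus 10% of the base
#'   value, clipped to the parameter's domain.
#' @param n_points Grid size.
#' @param conventions A [model_conventions()] object.
#' @param flat_tol Relative ICER span below which the relationship is
#'   classified `"flat"`.
#' @param tie_tha_cost,tie_periop Coupling rules (see Details).
#' @return A `one_way_result`: parameter name, grid, ICER per grid point,
#'   and `direction` in `positive`, `negative`, `flat`.
#' @export
one_way_dsa <- function(params = default_parameters(), parameter,
                        range = NULL, n_points = 11,
                        conventions = model_conventions(),
                        flat_tol = 0.02, tie_tha_cost = TRUE,
                        tie_periop = TRUE) {
  info <- .param_registry[[parameter]]
  if (is.null(info)) stop("unknown parameter `", parameter, "`", call. = FALSE)
  base <- params[[info$group]][[parameter]]
  if (is.null(range)) {
    range <- sort(c(base * 0.9, base * 1.1))
    range <- pmin(pmax(range, info$domain[1]), info$domain[2])
  }
  if (range[1] < info$domain[1] || range[2] > info$domain[2])
    stop(sprintf("range outside the domain [%g, %g] of `%s`",
                 info$domain[1], info$domain[2], parameter), call. = FALSE)
  grid <- seq(range[1], range[2], length.out = n_points)
  icers <- vapply(grid, function(v) {
    p <- .set_param(params, parameter, v, tie_tha_cost, tie_periop)
    .evaluate_pair(p, conventions)$icer
  }, numeric(1))
  base_icer <- .evaluate_pair(params, conventions)$icer
  span <- (max(icers, na.rm = TRUE) - min(icers, na.rm = TRUE)) / abs(base_icer)
  direction <- if (is.finite(span) && span < flat_tol) "flat"
  else if (unname(coef(lm(icers ~ grid))[2]) > 0) "positive" else "negative"
  structure(list(parameter = parameter, grid = grid, icers = icers,
                 base_icer = base_icer, span = span, direction = direction),
            class = "one_way_result")
}

#' @export
print.one_way_result <- function(x, ...) {
  cat(sprintf("one-way DSA on %s: direction %s\n", x$parameter, x$direction))
  print(data.frame(value = x$grid, icer = round(x$icers, 1)), row.names = FALSE)
  invisible(x)
}

#' Two-way sensitivity analysis: navigation cost versus safe-zone
#' probability
#'
#' Classifies each cell of a navigation-system-cost by
#' safe-zone-probability grid as favouring the navigated or the
#' traditional strategy at the willingness-to-pay threshold (all other
#' parameters at base values; maintenance stays at its fixed fraction of
#' the purchase price as the purchase price moves).
#'
#' @param params An [imn_parameters()] object.
#' @param cost_range Range of navigation purchase cost (CNY).
#' @param probability_range Range of `p_safe_nav`.
#' @param grid_size Points per axis.
#' @param conventions A [model_conventions()] object.
#' @return A `two_way_result`: axes `nav_purchase`, `p_safe_nav` and a
#'   logical matrix `navigated_ce` (`TRUE` where navigated IMN is
#'   cost-effective), rows indexed by cost, columns by probability.
#' @export
two_way_dsa <- function(params = default_parameters(),
                        cost_range = c(1e6, 2e7),
                        probability_range = c(0.74, 1.0),
                        grid_size = 21,
                        conventions = model_conventions()) {
  costs <- seq(cost_range[1], cost_range[2], length.out = grid_size)
  probs <- seq(probability_range[1], probability_range[2], length.out = grid_size)
  trad <- run_cohort("traditional", params, conventions, trace = FALSE)
  ce <- matrix(NA, length(costs), length(probs),
               dimnames = list(NULL, NULL))
  for (j in seq_along(probs)) {
    p1 <- .set_param(params, "p_safe_nav", probs[j])
    for (i in seq_along(costs)) {
      p2 <- .set_param(p1, "nav_purchase", costs[i])
      nav <- run_cohort("navigated", p2, conventions, trace = FALSE)
      ce[i, j] <- icer(nav, trad, wtp = params$economics$wtp)$cost_effective
    }
  }
  structure(list(nav_purchase = costs, p_safe_nav = probs, navigated_ce = ce,
                 wtp = params$economics$wtp), class = "two_way_result")
}

#' @export
print.two_way_result <- function(x, ...) {
  cat(sprintf("two-way DSA (%d x %d grid): navigated cost-effective in %d cells at WTP %s\n",
              nrow(x$navigated_ce), ncol(x$navigated_ce), sum(x$navigated_ce),
              format(x$wtp, big.mark = ",")))
  invisible(x)
}

#' Threshold search by bisection
#'
#' Finds the value of a parameter at which the navigated strategy's ICER
#' over the traditional strategy equals the willingness-to-pay threshold,
#' i.e. the root of the incremental net monetary benefit.  Monotonicity of
#' the NMB over the bracket is verified on a coarse grid before bisecting
#' (non-monotone brackets raise an error asking the caller to split the
#' bracket).  When even the favourable end of the bracket is not
#' cost-effective, the explicit no-solution sentinel is returned rather
#' than a value.
#'
#' @param params An [imn_parameters()] object.
#' @param target_parameter Parameter to solve for (any registry name,
#'   including `"annual_volume"`).
#' @param volume Annual surgical volume context (cases/year); overrides
#'   `params$costs$annual_volume` unless the target is the volume itself.
#' @param bracket Length-2 search interval.
#' @param wtp Willingness-to-pay threshold (CNY/QALY).
#' @param conventions A [model_conventions()] object.
#' @param icer_tol Solve until the ICER at the candidate is within this
#'   many CNY/QALY of `wtp` (or the bracket shrinks below `1e-6` of its
#'   width).
#' @return A `threshold_result`: `parameter`, `volume`, `bracket`,
#'   `threshold` (`NA` when no solution exists in the bracket),
#'   `no_solution` flag, `direction` (`"greater_than"` if the strategy is
#'   cost-effective above the threshold, `"less_than"` if below) and the
#'   achieved ICER.
#' @examples
#' threshold_search(default_parameters(), "annual_volume",
#'                  bracket = c(50, 300))
#' @export
threshold_search <- function(params = default_parameters(), target_parameter,
                             volume = params$costs$annual_volume,
                             bracket, wtp = params$economics$wtp,
                             conventions = model_conventions(),
                             icer_tol = 1) {
  if (target_parameter != "annual_volume")
    params <- .set_param(params, "annual_volume", volume)
  nmb_at <- function(v) {
    p <- .set_param(params, target_parameter, v)
    .evaluate_pair(p, conventions, wtp = wtp)$nmb_at_wtp
  }
  icer_at <- function(v) {
    p <- .set_param(params, target_parameter, v)
    .evaluate_pair(p, conventions, wtp = wtp)$icer
  }
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])

  grid <- seq(bracket[1], bracket[2], length.out = 17)
  g <- vapply(grid, nmb_at, numeric(1))
  dg <- diff(g)
  if (any(dg > 1e-9) && any(dg < -1e-9))
    stop("incremental NMB is not monotone over the bracket; ",
         "split the bracket and search each part", call. = FALSE)
  increasing <- g[length(g)] >= g[1]
  direction <- if (increasing) "greater_than" else "less_than"

  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- g[1]; f_hi <- g[length(g)]
  if (f_lo * f_hi > 0) {
    no_solution <- max(f_lo, f_hi) < 0  # never cost-effective in bracket
    return(structure(list(parameter = target_parameter, volume = volume,
                          bracket = bracket, threshold = NA_real_,
                          no_solution = no_solution,
                          always_cost_effective = !no_solution,
                          direction = direction, icer_at_threshold = NA_real_,
                          wtp = wtp), class = "threshold_result"))
  }
  width <- hi - lo
  repeat {
    mid <- (lo + hi) / 2
    f_mid <- nmb_at(mid)
    ic <- icer_at(mid)
    if ((!is.na(ic) && abs(ic - wtp) < icer_tol) ||
        (hi - lo) < 1e-6 * width) break
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  structure(list(parameter = target_parameter, volume = volume,
                 bracket = bracket, threshold = mid, no_solution = FALSE,
                 always_cost_effective = FALSE, direction = direction,
                 icer_at_threshold = ic, wtp = wtp),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$no_solution) {
    cat(sprintf("threshold on %s (volume %g): no solution in [%g, %g]\n",
                x$parameter, x$volume, x$bracket[1], x$bracket[2]))
  } else if (isTRUE(x$always_cost_effective)) {
    cat(sprintf("threshold on %s (volume %g): cost-effective across [%g, %g]\n",
                x$parameter, x$volume, x$bracket[1], x$bracket[2]))
  } else {
    cat(sprintf("threshold on %s (volume %g): %s %s (ICER there %s)\n",
                x$parameter, x$volume,
                if (x$direction == "greater_than") ">" else "<",
                format(signif(x$threshold, 7), big.mark = ","),
                format(round(x$icer_at_threshold), big.mark = ",")))
  }
  invisible(x)
}

#' Tornado-style summary across model parameters
#'
#' Runs [one_way_dsa()] for every registry parameter and tabulates the
#' ICER span and direction of each.
#'
#' @inheritParams one_way_dsa
#' @param parameters Which parameters to include.
#' @return A data frame sorted by decreasing ICER span.
#' @export
tornado_summary <- function(params = default_parameters(),
                            parameters = names(.param_registry),
                            conventions = model_conventions(), ...) {
  rows <- lapply(parameters, function(nm) {
    ow <- one_way_dsa(params, nm, conventions = conventions, ...)
    data.frame(parameter = nm, icer_low = min(ow$icers),
               icer_high = max(ow$icers), span = ow$span,
               direction = ow$direction)
  })
  out <- do.call(rbind, rows)
  out[order(-out$span), , drop = FALSE]
}
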