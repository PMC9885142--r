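# Randomized parameter scenarios for property-based testing: plausible
# perturbations of the base case that always produce a valid parameter
# set and finite model outputs.

#' Scenario specification for randomized parameter sets
#'
#' Per-parameter plausible ranges, by default plus/minus 50% of the base
#' value clipped to each parameter's domain (probabilities and utilities
#' to `[0, 1]`).  Disutility ranges over `[-0.3, 0]` and the safe-zone
#' probabilities are kept above one half so that scenario arms remain
#' recognizable.
#'
#' @param params Base [imn_parameters()] used to centre the ranges.
#' @param spread Relative half-width of each range.
#' @return A named list of length-2 numeric ranges (class
#'   `scenario_spec`).
#' @export
scenario_spec <- function(params = default_parameters(), spread = 0.5) {
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  rng <- function(base, lo = NULL, hi = NULL) {
    r <- c(base * (1 - spread), base * (1 + spread))
    if (!is.null(lo)) r[1] <- max(r[1], lo)
    if (!is.null(hi)) r[2] <- min(r[2], hi)
    r
  }
  cl <- params$clinical; ut <- params$utilities; co <- params$costs
  structure(list(
    p_periop_death_imn = clip01(rng(cl$p_periop_death_imn)),
    p_death_first_year = clip01(rng(cl$p_death_first_year)),
    annual_fail_safe   = clip01(rng(cl$annual_fail_safe)),
    annual_fail_unsafe = clip01(rng(cl$annual_fail_unsafe)),
    p_safe_nav         = rng(cl$p_safe_nav, lo = 0.5, hi = 1),
    p_safe_trad        = rng(cl$p_safe_trad, lo = 0.5, hi = 1),
    u_nav              = clip01(rng(ut$u_nav)),
    u_trad             = clip01(rng(ut$u_trad)),
    u_tha              = clip01(rng(ut$u_tha)),
    disutility_salvage = c(-0.3, 0),
    cost_imn           = rng(co$cost_imn),
    cost_tha           = rng(co$cost_tha),
    nav_purchase       = rng(co$nav_purchase),
    annual_volume      = rng(co$annual_volume, lo = 1),
    q_background       = c(0.005, 0.15),
    gompertz_slope     = c(0, 0.12)
  ), class = "scenario_spec")
}

#' Draw a random parameter set
#'
#' Uniform draws within the scenario ranges; the background mortality is a
#' Gompertz life table with randomized level and slope.  Every returned
#' set passes [validate_parameters()].
#'
#' Uses the current RNG state; `set.seed()` upstream for reproducibility.
#'
#' @param spec A [scenario_spec()].
#' @param params Base parameters supplying everything not in the spec.
#' @return A validated `imn_parameters` object.
#' @export
random_parameter_set <- function(spec = scenario_spec(),
                                 params = default_parameters()) {
  draw <- function(r) runif(1, r[1], r[2])
  cl <- params$clinical
  cl$p_periop_death_imn <- draw(spec$p_periop_death_imn)
  cl$p_periop_death_tha <- cl$p_periop_death_imn
  cl$p_death_first_year <- max(draw(spec$p_death_first_year), cl$p_periop_death_imn)
  cl$annual_fail_safe <- draw(spec$annual_fail_safe)
  cl$annual_fail_unsafe <- max(draw(spec$annual_fail_unsafe), cl$annual_fail_safe)
  cl$p_safe_nav <- draw(spec$p_safe_nav)
  cl$p_safe_trad <- draw(spec$p_safe_trad)
  ut <- params$utilities
  ut$u_nav <- draw(spec$u_nav)
  ut$u_trad <- draw(spec$u_trad)
  ut$u_tha <- draw(spec$u_tha)
  ut$disutility_salvage <- -draw(-rev(spec$disutility_salvage))
  co <- params$costs
  co$cost_imn <- draw(spec$cost_imn)
  co$cost_tha <- draw(spec$cost_tha)
  co$nav_purchase <- draw(spec$nav_purchase)
  co$annual_volume <- draw(spec$annual_volume)
  lt <- gompertz_life_table(draw(spec$q_background), draw(spec$gompertz_slope),
                            ages = params$economics$start_age + 0:10)
  validate_parameters(structure(
    list(clinical = cl, utilities = ut, costs = co,
         economics = params$economics, life_table = lt),
    class = "imn_parameters"))
}
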