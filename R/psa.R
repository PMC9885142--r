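# Probabilistic sensitivity analysis: Monte-Carlo sampling of the
# parameter distributions, paired cohort evaluation per draw, summary
# ICER, and cost-effectiveness acceptability curves.

#' Draw parameter samples for the PSA
#'
#' One independent draw per distributed parameter and sample.  A draw of a
#' shared parameter (failure rates, THA utility and cost, IMN cost) is
#' used by both strategies within a sample, so the arms differ only
#' through the arm-specific parameters (safe-zone probabilities and
#' fixation utilities) and the navigation cost.
#'
#' Uses the current RNG state; seed upstream (or via [run_psa()]) for
#' reproducibility.
#'
#' @param n Number of samples.
#' @param dists Named list of [dist_spec()]s, as from
#'   [psa_distributions()].
#' @param point_mass Optional character vector of parameter names to hold
#'   at their quoted mean (degenerate draws), mainly for testing.
#' @return Data frame with one column per distributed parameter and `n`
#'   rows.
#' @export
draw_psa_samples <- function(n, dists = psa_distributions(),
                             point_mass = character()) {
  stopifnot(n >= 1)
  cols <- lapply(names(dists), function(nm) {
    if (nm %in% point_mass) rep(dists[[nm]]$mean, n) else rdist(n, dists[[nm]])
  })
  setNames(as.data.frame(cols), names(dists))
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_samples` parameter sets from the PSA distributions, evaluates
#' both strategies with the cohort engine for every draw (all non-sampled
#' parameters at base values), and summarizes: the PSA ICER as the ratio
#' of means `mean(delta_cost) / mean(delta_qaly)` (the conventional,
#' stable estimator; the mean of per-sample ratios is also reported), and
#' the acceptance fraction as the share of samples with positive net
#' monetary benefit at the WTP threshold.
#'
#' @param params Base [imn_parameters()]; `annual_volume` is taken from
#'   `volume`.
#' @param volume Annual surgical volume (cases/year).
#' @param n_samples Number of Monte-Carlo samples.
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @param wtp Willingness-to-pay threshold (CNY/QALY).
#' @param conventions A [model_conventions()] object.
#' @param dists PSA distributions, as from [psa_distributions()].
#' @return A `psa_result` with per-sample `delta_cost`/`delta_qaly`,
#'   `icer_ratio_of_means`, `icer_mean_of_ratios`, `acceptance` at `wtp`,
#'   and the run metadata (`n_samples`, `seed`, `volume`, `wtp`).
#' @export
run_psa <- function(params = default_parameters(), volume = 200,
                    n_samples = 1000, seed = 1, wtp = 140000,
                    conventions = model_conventions(),
                    dists = psa_distributions()) {
  stopifnot(n_samples >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params$costs$annual_volume <- volume
  samples <- draw_psa_samples(n_samples, dists)

  dc <- dq <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    p <- params
    for (nm in names(samples)) {
      grp <- .param_registry[[nm]]$group
      p[[grp]][[nm]] <- samples[[nm]][i]
    }
    nav <- run_cohort("navigated", p, conventions, trace = FALSE)
    trad <- run_cohort("traditional", p, conventions, trace = FALSE)
    dc[i] <- nav$total_cost - trad$total_cost
    dq[i] <- nav$total_qaly - trad$total_qaly
  }

  per_sample_ratio <- dc / dq
  structure(list(samples = samples, delta_cost = dc, delta_qaly = dq,
                 icer_ratio_of_means = mean(dc) / mean(dq),
                 icer_mean_of_ratios = mean(per_sample_ratio[is.finite(per_sample_ratio)]),
                 acceptance = mean(wtp * dq - dc > 0),
                 n_samples = n_samples, seed = seed, volume = volume,
                 wtp = wtp), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d samples at volume %g (seed %d)\n",
              x$n_samples, x$volume, x$seed))
  cat(sprintf("  ICER (ratio of means): %s per QALY\n",
              format(round(x$icer_ratio_of_means), big.mark = ",")))
  cat(sprintf("  acceptance at WTP %s: %.1f%%\n",
              format(x$wtp, big.mark = ","), 100 * x$acceptance))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on a grid, the fraction of PSA
#' samples with positive net monetary benefit - computed from the one
#' stored sample set (no re-sampling across the grid).
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid WTP values (CNY/QALY).
#' @return A `ceac_curve` data frame with columns `wtp`, `acceptance`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 400000, by = 10000)) {
  stopifnot(inherits(psa, "psa_result"))
  acc <- vapply(wtp_grid,
                function(w) mean(w * psa$delta_qaly - psa$delta_cost > 0),
                numeric(1))
  structure(data.frame(wtp = wtp_grid, acceptance = acc),
            class = c("ceac_curve", "data.frame"))
}
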