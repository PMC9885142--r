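# Reference-case reporting, artifact export, run manifests, and the
# command-line dispatcher used by the inst/cli wrapper script.

#' Reference-case analysis
#'
#' Runs both strategies at a given annual surgical volume and summarizes
#' the comparison.
#'
#' @param params An [imn_parameters()] object.
#' @param conventions A [model_conventions()] object.
#' @param volume Annual surgical volume (cases/year).
#' @return List with `navigated`, `traditional` (strategy outcomes) and
#'   `cea` (the [icer()] comparison).
#' @examples
#' reference_case()$cea
#' @export
reference_case <- function(params = default_parameters(),
                           conventions = model_conventions(),
                           volume = params$costs$annual_volume) {
  params$costs$annual_volume <- volume
  nav <- run_cohort("navigated", params, conventions)
  trad <- run_cohort("traditional", params, conventions)
  list(navigated = nav, traditional = trad,
       cea = icer(nav, trad, wtp = params$economics$wtp))
}

#' Run manifest
#'
#' Metadata identifying a run: command, seed, package version, timestamp,
#' the calibration constants in force and an MD5 checksum of the config
#' file (when one was used).
#'
#' @param command Character label of the command executed.
#' @param seed Integer seed (or `NA`).
#' @param config_path Optional path to the configuration file.
#' @return A named list.
#' @export
run_manifest <- function(command, seed = NA_integer_, config_path = NULL) {
  list(command = command,
       package = "navicer",
       version = as.character(packageVersion("navicer")),
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config_checksum = if (!is.null(config_path) && file.exists(config_path))
         unname(tools::md5sum(config_path)) else NA_character_,
       calibration = calibrated_constants())
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

.outcome_as_list <- function(o)
  list(strategy = o$strategy, total_cost = o$total_cost,
       total_qaly = o$total_qaly, salvage_rate = o$salvage_rate,
       salvage_operations = o$salvage_operations)

.parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument `", a, "`", call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag --", key, " needs a value", call. = FALSE)
    flags[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line dispatcher
#'
#' Entry point behind the `inst/cli/navicer` wrapper script.  Commands:
#' `calibrate`, `reference`, `volume-curve`, `one-way`, `two-way`,
#' `threshold`, `psa`, `ceac`, `report`.  Flags: `--config PATH`,
#' `--volume INT`, `--wtp NUM`, `--seed INT`, `--n INT`,
#' `--parameter NAME`, `--out DIR`.  Artifacts (CSV/JSON) and a
#' `manifest.json` are written to the output directory.
#'
#' @param args Character vector of command-line arguments; defaults to
#'   the actual command line.
#' @return Integer exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: navicer <command> [--config PATH] [--volume INT] [--wtp NUM]",
    "       [--seed INT] [--n INT] [--parameter NAME] [--out DIR]",
    "commands: calibrate reference volume-curve one-way two-way threshold",
    "          psa ceac report", sep = "\n")
  status <- tryCatch({
    if (length(args) == 0) stop("no command given", call. = FALSE)
    command <- args[1]
    flags <- .parse_cli_flags(args[-1])
    out_dir <- if (!is.null(flags$out)) flags$out else "."
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else 1L
    volume <- if (!is.null(flags$volume)) as.numeric(flags$volume) else 200
    wtp <- if (!is.null(flags$wtp)) as.numeric(flags$wtp) else 140000
    n <- if (!is.null(flags$n)) as.integer(flags$n) else 1000L
    params <- if (!is.null(flags$config)) load_parameters(flags$config)
              else default_parameters()
    params$costs$annual_volume <- volume
    params$economics$wtp <- wtp
    conv <- model_conventions()

    switch(command,
      "calibrate" = {
        cal <- calibrate_model(params = params, allow_failure = TRUE)
        calibration_to_json(cal, file.path(out_dir, "calibration.json"))
      },
      "reference" = {
        rc <- reference_case(params, conv, volume)
        .write_json(list(navigated = .outcome_as_list(rc$navigated),
                         traditional = .outcome_as_list(rc$traditional),
                         cea = unclass(rc$cea)),
                    file.path(out_dir, "reference.json"))
      },
      "volume-curve" = {
        vc <- icer_vs_volume(params, volumes = seq(50, 400, by = 10),
                             conventions = conv)
        write.csv(data.frame(volume = vc$grid, icer = vc$icers),
                  file.path(out_dir, "volume_curve.csv"), row.names = FALSE)
        .write_json(list(A = vc$A, B = vc$B, delta_qaly = vc$delta_qaly),
                    file.path(out_dir, "volume_curve_fit.json"))
      },
      "one-way" = {
        pm <- flags$parameter
        if (is.null(pm)) stop("one-way needs --parameter", call. = FALSE)
        ow <- one_way_dsa(params, pm, conventions = conv)
        write.csv(data.frame(parameter = pm, value = ow$grid, icer = ow$icers,
                             direction = ow$direction),
                  file.path(out_dir, paste0("oneway_", pm, ".csv")),
                  row.names = FALSE)
      },
      "two-way" = {
        tw <- two_way_dsa(params, conventions = conv)
        long <- expand.grid(nav_purchase = tw$nav_purchase,
                            p_safe_nav = tw$p_safe_nav)
        long$navigated_ce <- as.vector(tw$navigated_ce)
        write.csv(long, file.path(out_dir, "twoway.csv"), row.names = FALSE)
      },
      "threshold" = {
        pm <- flags$parameter
        if (is.null(pm)) stop("threshold needs --parameter", call. = FALSE)
        br <- switch(pm,
                     annual_volume = c(50, 1000),
                     p_safe_nav = c(params$clinical$p_safe_trad, 1),
                     u_nav = c(0.5, 1),
                     nav_purchase = c(1e5, 5e7),
                     stop("no default bracket for `", pm, "`", call. = FALSE))
        th <- threshold_search(params, pm, volume = volume, bracket = br,
                               wtp = wtp, conventions = conv)
        .write_json(unclass(th), file.path(out_dir, paste0("threshold_", pm, ".json")))
      },
      "psa" = {
        ps <- run_psa(params, volume = volume, n_samples = n, seed = seed,
                      wtp = wtp, conventions = conv)
        write.csv(cbind(ps$samples, delta_cost = ps$delta_cost,
                        delta_qaly = ps$delta_qaly),
                  file.path(out_dir, "psa_samples.csv"), row.names = FALSE)
        .write_json(list(icer_ratio_of_means = ps$icer_ratio_of_means,
                         icer_mean_of_ratios = ps$icer_mean_of_ratios,
                         acceptance = ps$acceptance, n_samples = ps$n_samples,
                         seed = ps$seed, volume = ps$volume, wtp = ps$wtp),
                    file.path(out_dir, "psa_summary.json"))
        write.csv(as.data.frame(ceac(ps)), file.path(out_dir, "ceac.csv"),
                  row.names = FALSE)
      },
      "ceac" = {
        ps <- run_psa(params, volume = volume, n_samples = n, seed = seed,
                      wtp = wtp, conventions = conv)
        write.csv(as.data.frame(ceac(ps)), file.path(out_dir, "ceac.csv"),
                  row.names = FALSE)
      },
      "report" = {
        rc <- reference_case(params, conv, volume)
        vc <- icer_vs_volume(params, conventions = conv)
        ths <- lapply(c(100, 200, 300), function(v)
          unclass(threshold_search(params, "nav_purchase", volume = v,
                                   bracket = c(1e5, 5e7), wtp = wtp,
                                   conventions = conv)))
        ps <- run_psa(params, volume = volume, n_samples = n, seed = seed,
                      wtp = wtp, conventions = conv)
        .write_json(list(
          reference = list(navigated = .outcome_as_list(rc$navigated),
                           traditional = .outcome_as_list(rc$traditional),
                           cea = unclass(rc$cea)),
          icer_by_volume = data.frame(volume = vc$grid, icer = vc$icers),
          purchase_thresholds = ths,
          psa = list(acceptance = ps$acceptance,
                     icer_ratio_of_means = ps$icer_ratio_of_means)),
          file.path(out_dir, "report.json"))
      },
      stop("unknown command `", command, "`", call. = FALSE))

    .write_json(run_manifest(command, seed, flags$config),
                file.path(out_dir, "manifest.json"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(usage)
    1L
  })
  invisible(status)
}
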