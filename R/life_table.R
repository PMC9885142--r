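# Background-mortality life tables.  The model needs annual death
# probabilities (qx) by integer age; lookups clamp at the table
# boundaries.  The published model cites a national census life table that
# is not reproduced, so the package generates stand-ins: a flat table at
# the calibrated background rate for reproduction runs, and Gompertz
# tables for robustness tests.

#' Construct a life table
#'
#' @param age Integer ages, sorted ascending.
#' @param qx Annual death probabilities in `[0, 1]`, one per age.
#' @return A `life_table` data frame with columns `age`, `qx`.
#' @export
life_table <- function(age, qx) {
  stopifnot(length(age) == length(qx), !is.unsorted(age))
  if (any(qx < 0 | qx > 1)) stop("`qx` values must lie in [0, 1]", call. = FALSE)
  structure(data.frame(age = as.integer(age), qx = as.numeric(qx)),
            class = c("life_table", "data.frame"))
}

as_life_table <- function(x) {
  if (inherits(x, "life_table")) return(x)
  stopifnot(is.list(x) || is.data.frame(x))
  life_table(x$age, x$qx)
}

#' Flat life table
#'
#' Constant annual death probability across an age range; the stand-in
#' used for reproduction runs, where the single rate is resolved by
#' [calibrate_conventions()].
#'
#' @param q Annual death probability.
#' @param ages Integer age range to cover.
#' @return A `life_table`.
#' @export
flat_life_table <- function(q, ages = 70:80) life_table(ages, rep(q, length(ages)))

#' Gompertz life table
#'
#' Exponentially increasing mortality,
#' `qx(age) = min(1, q0 * exp(slope * (age - min(ages))))` - the classical
#' shape of adult human mortality, used to generate plausible age-graded
#' tables for property tests.
#'
#' @param q0 Annual death probability at the first age; in (0, 1).
#' @param slope Per-year log-hazard increment (>= 0 gives non-decreasing
#'   qx).
#' @param ages Integer ages to cover.
#' @return A `life_table`.
#' @examples
#' gompertz_life_table(0.03, 0.09, 70:75)
#' @export
gompertz_life_table <- function(q0, slope = 0.09, ages = 70:80) {
  if (q0 <= 0 || q0 >= 1) stop("`q0` must lie in (0, 1)", call. = FALSE)
  life_table(ages, pmin(1, q0 * exp(slope * (ages - min(ages)))))
}

#' Look up the annual death probability at an age
#'
#' Ages outside the table clamp to the nearest boundary row.
#'
#' @param lt A `life_table`.
#' @param age Integer age(s).
#' @return Annual death probabilities.
#' @export
lookup_qx <- function(lt, age) {
  lt <- as_life_table(lt)
  idx <- pmin(pmax(findInterval(age, lt$age), 1L), nrow(lt))
  lt$qx[idx]
}

#' Read / write a life table as CSV
#'
#' CSV with header `age,qx`.
#'
#' @param path File path.
#' @return `read_life_table` returns a `life_table`; `write_life_table`
#'   returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  d <- read.csv(path)
  if (!all(c("age", "qx") %in% names(d)))
    stop("life table CSV must have columns `age` and `qx`", call. = FALSE)
  life_table(d$age, d$qx)
}

#' @rdname read_life_table
#' @param lt A `life_table`.
#' @export
write_life_table <- function(lt, path) {
  write.csv(as.data.frame(as_life_table(lt)), path, row.names = FALSE)
  invisible(path)
}
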