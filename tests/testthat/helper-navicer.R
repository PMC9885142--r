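# Shared fixtures.  The calibration is deterministic but takes a couple of
# seconds, so acceptance/calibration tests share one memoized result.
.fixtures <- new.env(parent = emptyenv())

calibrated_fixture <- function() {
  if (is.null(.fixtures$cal)) .fixtures$cal <- calibrate_model()
  .fixtures$cal
}

# parameters with simplified dynamics for hand-checkable engine tests
quiet_params <- function(...) {
  default_parameters(
    clinical = list(p_periop_death_imn = 0, p_periop_death_tha = 0,
                    p_death_first_year = 0, annual_fail_safe = 0,
                    annual_fail_unsafe = 0),
    life_table = flat_life_table(0, ages = 70:80),
    ...
  )
}
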