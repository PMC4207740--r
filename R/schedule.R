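#' Light-dark schedule
#'
#' Describes the lighting cycle a recording is aligned to. Zeitgeber time (ZT)
#' is measured in hours since lights-on: under the standard 12:12 cycle the
#' light phase (L) spans ZT0-12 and the dark phase (D) ZT12-24.
#'
#' @param lights_on_zt Hour at which lights come on; 0 by convention.
#' @param light_hours,dark_hours Duration of the light and dark phase in hours.
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule()
#' @export
light_schedule <- function(lights_on_zt = 0, light_hours = 12, dark_hours = 12) {
  stopifnot(light_hours > 0, dark_hours > 0)
  structure(
    list(
      lights_on_zt = lights_on_zt,
      light_hours = light_hours,
      dark_hours = dark_hours,
      cycle_hours = light_hours + dark_hours
    ),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf(
    "<light_schedule> %g h light / %g h dark (ZT0 = lights-on)\n",
    x$light_hours, x$dark_hours
  ))
  invisible(x)
}

# TRUE for ZT hours falling in the light phase.
in_light_phase <- function(zt, schedule = light_schedule()) {
  ztc <- (zt - schedule$lights_on_zt) %% schedule$cycle_hours
  ztc < schedule$light_hours
}
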