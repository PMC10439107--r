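#' Inkjet print settings
#'
#' Parameters of the gantry inkjet rig: lateral speeds, piston (nozzle)
#' height, drop mass and free-flight speed, and the peak-and-hold valve
#' actuation profile (peak current `I_p` for `t_p`, then holding current
#' `I_h` for `t_h`, which shapes drop volume). Valve timing values travel
#' through the schedule untouched.
#'
#' @param x_speed,y_speed Gantry speeds, mm/s.
#' @param piston_height Nozzle-to-substrate height, mm.
#' @param drop_mass_ug Drop mass, ug.
#' @param drop_speed Free-flight drop speed estimate, mm/s.
#' @param peak_current_mA,peak_time_ms,hold_current_mA,hold_time_ms
#'   Peak-and-hold actuation parameters.
#' @param pixel_pitch Bitmap pixel pitch, mm/px.
#' @return Object of class `print_settings`.
#' @export
print_settings <- function(x_speed = 50, y_speed = 200, piston_height = 20,
                           drop_mass_ug = 390, drop_speed = 1000,
                           peak_current_mA = 500, peak_time_ms = 0.5,
                           hold_current_mA = 100, hold_time_ms = 1,
                           pixel_pitch = 2) {
  vals <- c(x_speed, y_speed, piston_height, drop_mass_ug, drop_speed,
            peak_current_mA, peak_time_ms, pixel_pitch)
  if (any(vals <= 0) || hold_time_ms < 0 || hold_current_mA < 0) {
    stop("parameter error: print settings must be positive ",
         "(hold time/current may be zero)")
  }
  structure(list(x_speed = x_speed, y_speed = y_speed,
                 piston_height = piston_height, drop_mass_ug = drop_mass_ug,
                 drop_speed = drop_speed, peak_current_mA = peak_current_mA,
                 peak_time_ms = peak_time_ms, hold_current_mA = hold_current_mA,
                 hold_time_ms = hold_time_ms, pixel_pitch = pixel_pitch),
            class = "print_settings")
}

#' Drop deflection correction
#'
#' A drop released from a moving head inherits the lateral velocity and
#' drifts by `lateral_velocity * piston_height / drop_speed` during its time
#' of flight. The actuation position is advanced by this offset opposite to
#' the travel direction so the drop lands on the trigger position.
#'
#' @param lateral_velocity Head speed, mm/s (sign-free magnitude).
#' @param piston_height Nozzle height, mm.
#' @param drop_speed Drop free-flight speed, mm/s.
#' @return Offset magnitude in mm.
#' @examples
#' deflection_correction(50, 20, 1000)  # 1 mm
#' @export
deflection_correction <- function(lateral_velocity, piston_height,
                                  drop_speed) {
  if (drop_speed <= 0) stop("parameter error: drop_speed must be > 0")
  if (piston_height <= 0) stop("parameter error: piston_height must be > 0")
  lateral_velocity * piston_height / drop_speed
}

#' Rasterize a pattern bitmap into a valve-event schedule
#'
#' Interprets the bitmap line by line, top to bottom, firing one drop per
#' white pixel at the pixel center. The scan direction is inverted after
#' every printed line (empty lines are skipped without inversion). Each
#' event records the trigger position (target pixel center) and the
#' deflection-corrected actuation position.
#'
#' @param bitmap Logical matrix (white = `TRUE` = print), e.g. from
#'   [render_bitmap] or [read_pbm].
#' @param settings A [print_settings]; its `pixel_pitch` maps pixels to mm.
#' @param geometry Optional [sample_geometry]; corrected landing positions
#'   outside its face raise a warning listing the offending pixels.
#' @return Object of class `print_schedule`: list with `events` (data.frame:
#'   `line`, `direction`, `trigger_x`, `trigger_y`, `corrected_x`,
#'   `corrected_y`, `t_p`, `I_p`, `t_h`, `I_h`, `drop_mass`), `settings`,
#'   `source_bitmap_shape`.
#' @export
rasterize <- function(bitmap, settings = print_settings(), geometry = NULL) {
  if (is.numeric(bitmap)) {
    u <- unique(as.vector(bitmap))
    if (!all(u %in% c(0, 1))) {
      stop("format error: bitmap must be binary (0/1 or logical)")
    }
    bitmap <- bitmap == 1
  }
  stopifnot(is.logical(bitmap), is.matrix(bitmap))
  pitch <- settings$pixel_pitch
  offset <- deflection_correction(settings$x_speed, settings$piston_height,
                                  settings$drop_speed)
  events <- list()
  direction <- 1L
  for (r in seq_len(nrow(bitmap))) {
    cols <- which(bitmap[r, ])
    if (length(cols) == 0) next
    if (direction < 0) cols <- rev(cols)
    tx <- (cols - 0.5) * pitch
    ty <- rep((r - 0.5) * pitch, length(cols))
    events[[length(events) + 1]] <- data.frame(
      line = r - 1L, direction = direction,
      trigger_x = tx, trigger_y = ty,
      corrected_x = tx - direction * offset, corrected_y = ty,
      t_p = settings$peak_time_ms, I_p = settings$peak_current_mA,
      t_h = settings$hold_time_ms, I_h = settings$hold_current_mA,
      drop_mass = settings$drop_mass_ug)
    direction <- -direction
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(line = integer(0), direction = integer(0),
               trigger_x = numeric(0), trigger_y = numeric(0),
               corrected_x = numeric(0), corrected_y = numeric(0),
               t_p = numeric(0), I_p = numeric(0), t_h = numeric(0),
               I_h = numeric(0), drop_mass = numeric(0))
  if (!is.null(geometry) && nrow(events) > 0) {
    out <- events$trigger_x < 0 | events$trigger_x > geometry$length |
      events$trigger_y < 0 | events$trigger_y > geometry$width
    if (any(out)) {
      warning("out-of-bounds landing positions for pixels at lines ",
              paste(unique(events$line[out]), collapse = ", "))
    }
  }
  structure(list(events = events, settings = settings,
                 source_bitmap_shape = dim(bitmap)),
            class = "print_schedule")
}

#' Total deposited ink mass of a schedule
#'
#' @param schedule A [print_schedule].
#' @return Total mass in ug (`n_events * drop_mass`).
#' @export
schedule_mass <- function(schedule) {
  sum(schedule$events$drop_mass)
}

#' Simulate drop deposition from a schedule
#'
#' Models the corrected actuation plus free-flight drift (which lands each
#' drop back on its trigger position) and adds isotropic Gaussian placement
#' jitter. With `jitter_sd_mm = 0` the realized centers equal the trigger
#' (deflection-corrected landing) positions exactly.
#'
#' @param schedule A [print_schedule].
#' @param jitter_sd_mm Per-axis Gaussian jitter sd, mm.
#' @param seed Integer seed (deterministic output per seed).
#' @return data.frame with `x`, `y` realized dot centers (mm).
#' @export
simulate_deposition <- function(schedule, jitter_sd_mm = 0, seed = 1) {
  if (jitter_sd_mm < 0) stop("parameter error: jitter_sd_mm must be >= 0")
  ev <- schedule$events
  offset <- deflection_correction(schedule$settings$x_speed,
                                  schedule$settings$piston_height,
                                  schedule$settings$drop_speed)
  x <- ev$corrected_x + ev$direction * offset
  y <- ev$corrected_y
  if (jitter_sd_mm > 0 && nrow(ev) > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    x <- x + stats::rnorm(nrow(ev), 0, jitter_sd_mm)
    y <- y + stats::rnorm(nrow(ev), 0, jitter_sd_mm)
  }
  data.frame(x = x, y = y)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a schedule as CSV
#'
#' One row per valve event, in firing order.
#'
#' @param schedule A [print_schedule].
#' @param path File path.
#' @export
schedule_to_csv <- function(schedule, path) {
  utils::write.csv(schedule$events, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.print_schedule <- function(x, ...) {
  cat("<print_schedule>", nrow(x$events), "valve events from a",
      paste(x$source_bitmap_shape, collapse = "x"), "px bitmap\n")
  invisible(x)
}
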