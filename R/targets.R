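#' Task conditions
#'
#' The four visuomotor mapping conditions: standard (`"S"`), plane-change
#' (`"PC"`), feedback-reversal (`"FR"`) and their combination (`"PC+FR"`).
#' In the two feedback-reversal conditions the cursor moves opposite to the
#' finger, so the finger must travel to the location mirrored through the
#' central target.
#'
#' @export
vm_conditions <- function() c("S", "PC", "FR", "PC+FR")

#' Target directions
#' @export
vm_directions <- function() c("up", "down", "left", "right")

.direction_units <- function() {
  rbind(
    up    = c(0, 1),
    down  = c(0, -1),
    left  = c(-1, 0),
    right = c(1, 0)
  )
}

#' Build the centre-out target layout for one condition
#'
#' Places four peripheral targets at `amplitude_mm` from the central target
#' (up, down, left, right) and derives the *finger-space* targets: the
#' locations the finger itself must reach. Under a feedback reversal
#' (`"FR"`, `"PC+FR"`) the cursor moves opposite to the finger, so the
#' finger-space target is the peripheral target mirrored through the centre;
#' under `"S"` and `"PC"` finger and cursor targets coincide.
#'
#' @param condition one of [vm_conditions()].
#' @param amplitude_mm distance from centre to each peripheral target (mm).
#' @param diameter_mm target diameter (mm).
#' @return an object of class `vm_layout`: condition, centre, amplitude,
#'   diameter, and 4x2 matrices `peripherals` and `finger_targets` with rows
#'   `up`, `down`, `left`, `right`.
#' @examples
#' lay <- target_layout("FR")
#' lay$finger_targets["up", ]  # mirrored to the "down" location
#' @export
target_layout <- function(condition, amplitude_mm = 75, diameter_mm = 20) {
  if (length(condition) != 1L || !condition %in% vm_conditions()) {
    stop("unknown condition '", paste(condition, collapse = ","),
         "'; expected one of ", paste(vm_conditions(), collapse = ", "))
  }
  stopifnot(amplitude_mm > 0, diameter_mm > 0)
  center <- c(0, 0)
  periph <- .direction_units() * amplitude_mm
  periph[, 1] <- periph[, 1] + center[1]
  periph[, 2] <- periph[, 2] + center[2]
  colnames(periph) <- c("x", "y")
  finger <- periph
  if (condition %in% c("FR", "PC+FR")) {
    # mirror through the centre: finger target = center - (peripheral - center)
    finger <- 2 * matrix(center, 4, 2, byrow = TRUE) - periph
    colnames(finger) <- c("x", "y")
  }
  structure(
    list(condition = condition, center = center,
         amplitude = amplitude_mm, diameter = diameter_mm,
         peripherals = periph, finger_targets = finger),
    class = "vm_layout"
  )
}

#' Layouts for all four conditions
#'
#' @inheritParams target_layout
#' @return named list of `vm_layout`, one per condition.
#' @export
make_layouts <- function(amplitude_mm = 75, diameter_mm = 20) {
  out <- lapply(vm_conditions(), target_layout,
                amplitude_mm = amplitude_mm, diameter_mm = diameter_mm)
  names(out) <- vm_conditions()
  out
}

#' @export
print.vm_layout <- function(x, ...) {
  cat("<vm_layout> condition", x$condition,
      "| amplitude", x$amplitude, "mm | diameter", x$diameter, "mm\n")
  invisible(x)
}
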