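#' @keywords internal
"_PACKAGE"

# ---- Label taxonomy -------------------------------------------------------
#
# Three levels of classification:
#   level 1: chair | stairs | walking
#   level 2: chair -> sit_down | stand_up ; stairs -> stairs_ascending |
#            stairs_descending ; walking has no level-2 split
#   level 3: stance | swing for the three gait contexts (stairs up, stairs
#            down, walking); chair has no phases
#
# Class order within a node is fixed and documented: it is the tie-break
# order wherever probabilities tie.

#' Activity and phase label taxonomy
#'
#' Constants describing the three-level label taxonomy used throughout the
#' package: the four simulated activities, the level-1 activity classes, the
#' level-2 direction classes and the level-3 gait phases, plus the mapping
#' from simulator activity to level-1 class.
#'
#' @return `har_taxonomy()` returns a list with elements `activities`,
#'   `level1`, `level2_chair`, `level2_stairs`, `level3`, and
#'   `activity_to_level1` (named character vector).
#' @examples
#' har_taxonomy()$level1
#' @export
har_taxonomy <- function() {
  list(
    activities        = c("chair", "stairs_up", "stairs_down", "walking"),
    level1            = c("chair", "stairs", "walking"),
    level2_chair      = c("sit_down", "stand_up"),
    level2_stairs     = c("stairs_ascending", "stairs_descending"),
    level3            = c("stance", "swing"),
    activity_to_level1 = c(chair = "chair", stairs_up = "stairs",
                           stairs_down = "stairs", walking = "walking")
  )
}

# Sensor enumeration; also the fixed ordering of sensor blocks in the
# 24-channel layout.
SENSOR_IDS <- c("left_thigh", "left_shank", "right_thigh", "right_shank")

#' Canonical 24-channel names
#'
#' The fixed channel ordering used by every trial and window image: sensors
#' in the order left thigh, left shank, right thigh, right shank; within a
#' sensor, accelerometer before gyroscope; within a modality, x, y, z.
#'
#' @return Character vector of 24 names like `"left_thigh.acc_x"`.
#' @export
channel_names <- function() {
  as.vector(vapply(SENSOR_IDS, function(s) {
    paste0(s, ".", c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z"))
  }, character(6)))
}

# ---- Seed fan-out ---------------------------------------------------------

#' Derive a stage seed from a master seed
#'
#' One master seed fans out to per-stage seeds through a deterministic
#' counter scheme, so that independently seeded stages (simulation,
#' balancing, training folds) are reproducible without sharing one RNG
#' stream. The tags are hashed with a small multiplicative scheme into a
#' positive 31-bit integer.
#'
#' @param master integer master seed.
#' @param ... character or integer tags identifying the stage
#'   (e.g. `"train"`, participant id, fold number).
#' @return A positive integer seed strictly below 2^31.
#' @examples
#' derive_seed(1, "simulate", "P01")
#' @export
derive_seed <- function(master, ...) {
  tags <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(tags)) h <- (h * 31 + v) %% 2147483647
  as.integer((h + abs(as.numeric(master))) %% 2147483647 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
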