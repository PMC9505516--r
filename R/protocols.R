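#' Build an electrode array
#'
#' Three applicator geometries are supported:
#' \describe{
#'   \item{`hex6`}{six rod electrodes on a regular hexagon without a central
#'     electrode; opposite-center distance 9 mm (circumradius 4.5 mm), rod
#'     contact radius 1 mm, so the edge-to-edge gap between adjacent
#'     electrodes is 2.5 mm.}
#'   \item{`hex7`}{`hex6` plus a central electrode (classical applicator).}
#'   \item{`mea6`}{six spring-loaded pins on a hexagonal mesh at 3.5 mm
#'     center-to-center spacing, pin contact radius 0.35 mm (multi-electrode
#'     array used with low-voltage long pulses).}
#' }
#' Rim electrodes are numbered 1..6 counter-clockwise starting on the +x
#' axis; the central electrode of `hex7` is id 7. Adjacency covers rim
#' neighbors (and rim-center pairs for `hex7`); opposite pairs are the three
#' hexagon diagonals.
#'
#' @param arrangement one of `"hex6"`, `"hex7"`, `"mea6"`.
#' @param circumradius optional override of the center-to-electrode distance
#'   (m).
#' @param contact_radius optional override of the electrode contact radius
#'   (m).
#' @return object of class `electrode_array` with elements `electrodes`
#'   (data frame: id, x, y, contact_radius), `arrangement`, `adjacency`,
#'   `opposite_pairs` (2-column matrices of electrode ids).
#' @export
build_array <- function(arrangement = c("hex6", "hex7", "mea6"),
                        circumradius = NULL, contact_radius = NULL) {
  arrangement <- match.arg(arrangement)
  if (is.null(circumradius))
    circumradius <- switch(arrangement, hex6 = 4.5e-3, hex7 = 4.5e-3,
                           mea6 = 3.5e-3)
  if (is.null(contact_radius))
    contact_radius <- switch(arrangement, hex6 = 1.0e-3, hex7 = 1.0e-3,
                             mea6 = 0.35e-3)
  stopifnot(circumradius > 0, contact_radius > 0)
  ang <- (0:5) * pi / 3
  el <- data.frame(id = 1:6,
                   x = circumradius * cos(ang),
                   y = circumradius * sin(ang),
                   contact_radius = contact_radius)
  adjacency <- cbind(1:6, c(2:6, 1L))
  opposite <- cbind(1:3, 4:6)
  if (arrangement == "hex7") {
    el <- rbind(el, data.frame(id = 7L, x = 0, y = 0,
                               contact_radius = contact_radius))
    adjacency <- rbind(adjacency, cbind(1:6, 7L))
  }
  # regular hexagon: side length equals circumradius, so adjacent
  # center-to-center distance is the circumradius itself
  min_cc <- circumradius
  if (2 * contact_radius >= min_cc)
    stop(sprintf(
      "contact discs overlap: diameter %.3g m >= adjacent spacing %.3g m",
      2 * contact_radius, min_cc))
  structure(list(electrodes = el, arrangement = arrangement,
                 adjacency = adjacency, opposite_pairs = opposite),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %s: %d electrodes, contact radius %.3g mm\n",
              x$arrangement, nrow(x$electrodes),
              x$electrodes$contact_radius[1] * 1e3))
  invisible(x)
}

#' Pulse-train parameters
#'
#' Describes the pulse train delivered at every activation step of a
#' protocol: amplitude `Ap` (V), single-pulse duration `Tp` (s), number of
#' pulses per burst `NrP`, number of bursts `NrB`, pulse repetition rate
#' `PRR` (Hz) within a burst and burst repetition rate `BRR` (Hz).
#'
#' @param Ap pulse amplitude (V), > 0.
#' @param Tp single-pulse duration (s), > 0.
#' @param NrP pulses per burst, >= 1.
#' @param PRR pulse repetition rate (Hz), > 0.
#' @param NrB number of bursts, >= 1 (default 1).
#' @param BRR burst repetition rate (Hz); required meaningful when `NrB > 1`.
#' @return object of class `pulse_train`.
#' @export
pulse_train <- function(Ap, Tp, NrP, PRR, NrB = 1L, BRR = NA_real_) {
  stopifnot(Ap > 0, Tp > 0, NrP >= 1, PRR > 0, NrB >= 1)
  if (Tp > 1 / PRR)
    stop("pulse duration exceeds the pulse repetition period (Tp > 1/PRR)")
  if (NrB > 1 && (is.na(BRR) || NrP / PRR > 1 / BRR))
    stop("burst of NrP pulses at PRR does not fit in the burst period 1/BRR")
  structure(list(Ap = Ap, Tp = Tp, NrP = as.integer(NrP),
                 NrB = as.integer(NrB), PRR = PRR, BRR = BRR),
            class = "pulse_train")
}

#' Default pulse train of a named protocol
#'
#' The hexagonal-array protocols (`classical`, `alternative`) use high-voltage
#' short pulses: 560 V amplitude, 100 us pulse duration, bursts of 4 pulses at
#' 5 kHz pulse repetition rate, bursts following at 50 Hz. The low-voltage
#' multi-electrode-array protocol (`mea_lv`) uses 60 V, 150 ms pulses at a
#' 2.82 Hz repetition rate, one pulse per activation step.
#'
#' @param name protocol name: `"classical"`, `"alternative"` or `"mea_lv"`.
#' @return a [pulse_train()].
#' @export
default_train <- function(name = c("alternative", "classical", "mea_lv")) {
  name <- match.arg(name)
  if (name == "mea_lv")
    pulse_train(Ap = 60, Tp = 0.150, NrP = 1L, PRR = 2.82)
  else
    pulse_train(Ap = 560, Tp = 100e-6, NrP = 4L, PRR = 5000, NrB = 1L,
                BRR = 50)
}

new_protocol_step <- function(anodes, cathodes, amplitude) {
  anodes <- as.integer(anodes); cathodes <- as.integer(cathodes)
  if (length(anodes) == 0 || length(cathodes) == 0)
    stop("a protocol step needs at least one anode and one cathode")
  if (length(intersect(anodes, cathodes)) > 0)
    stop("anode and cathode sets must be disjoint")
  if (amplitude <= 0) stop("'amplitude' must be positive")
  list(anodes = anodes, cathodes = cathodes, amplitude = amplitude)
}

#' Generate a pulse delivery protocol for an electrode array
#'
#' Produces the ordered list of electrode activation steps (anode/cathode
#' sets plus amplitude) of one of the three standard protocols:
#' \describe{
#'   \item{`classical`}{(requires `hex7`) pulses between all adjacent
#'     electrode pairs — the 6 rim-rim neighbors and the 6 rim-center pairs —
#'     each delivered in both polarities: 24 steps.}
#'   \item{`alternative`}{(requires `hex6`) pulses between the 6 rim-adjacent
#'     pairs in both polarities, then across the 3 hexagon diagonals in both
#'     polarities: 18 steps. The diagonal pulses compensate for the missing
#'     central electrode.}
#'   \item{`mea_lv`}{(requires `mea6`) the 6 rim-adjacent pairs in both
#'     polarities: 12 steps.}
#' }
#' Steps are ordered around the rim with immediate polarity reversal of each
#' pair (step 2 is step 1 reversed, and so on), then diagonals likewise.
#'
#' @param array an [build_array()] result.
#' @param name protocol name, see above.
#' @param amplitude per-step voltage (V); defaults to the protocol's default
#'   train amplitude.
#' @param diagonal_mode for `alternative`: `"single"` (default) pulses each
#'   diagonal as one anode / one cathode; `"paired"` drives two opposite
#'   adjacent pairs together (two anodes vs two cathodes on facing hexagon
#'   edges). Both yield 6 diagonal steps.
#' @param train optional [pulse_train()]; defaults to [default_train()].
#' @return object of class `protocol` with `steps`, `train`, `name`, `array`.
#' @export
generate_protocol <- function(array,
                              name = c("alternative", "classical", "mea_lv"),
                              amplitude = NULL,
                              diagonal_mode = c("single", "paired"),
                              train = NULL) {
  stopifnot(inherits(array, "electrode_array"))
  name <- match.arg(name)
  diagonal_mode <- match.arg(diagonal_mode)
  need <- switch(name, classical = "hex7", alternative = "hex6",
                 mea_lv = "mea6")
  if (array$arrangement != need)
    stop(sprintf("protocol '%s' requires a %s array (got %s)",
                 name, need, array$arrangement))
  if (is.null(train)) train <- default_train(name)
  if (is.null(amplitude)) amplitude <- train$Ap
  both <- function(a, c) list(new_protocol_step(a, c, amplitude),
                              new_protocol_step(c, a, amplitude))
  steps <- list()
  rim <- lapply(1:6, function(i) both(i, if (i < 6) i + 1L else 1L))
  steps <- c(steps, unlist(rim, recursive = FALSE))
  if (name == "classical") {
    ctr <- lapply(1:6, function(i) both(i, 7L))
    steps <- c(steps, unlist(ctr, recursive = FALSE))
  }
  if (name == "alternative") {
    diag <- if (diagonal_mode == "single")
      lapply(1:3, function(i) both(i, i + 3L))
    else
      lapply(1:3, function(i) {
        a <- c(i, if (i < 6) i + 1L else 1L)
        b <- ((a + 2L) %% 6L) + 1L  # the opposite hexagon edge
        both(a, b)
      })
    steps <- c(steps, unlist(diag, recursive = FALSE))
  }
  structure(list(steps = steps, train = train, name = name, array = array),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %s on %s: %d steps at %g V\n", x$name,
              x$array$arrangement, length(x$steps), x$steps[[1]]$amplitude))
  invisible(x)
}

#' Number of activation steps of a protocol
#' @param protocol a [generate_protocol()] result.
#' @export
n_steps <- function(protocol) length(protocol$steps)

#' Pulse-generator output envelope
#'
#' Bounds of the square-pulse generator: amplitude 80-600 V, pulse duration
#' 10-1000 us, pulse repetition rate 0.1-5000 Hz. All bounds inclusive.
#'
#' @return named list of `c(lo, hi)` bounds for `Ap` (V), `Tp` (s), `PRR`
#'   (Hz).
#' @export
device_envelope <- function() {
  list(Ap = c(80, 600), Tp = c(10e-6, 1000e-6), PRR = c(0.1, 5000))
}

#' Validate a pulse train against the device output envelope
#'
#' Checks amplitude, pulse duration and pulse repetition rate against the
#' generator's capability envelope. Violations are returned as data, not
#' raised as errors: a train may legitimately target a different generator.
#'
#' @param train a [pulse_train()].
#' @param envelope bounds as returned by [device_envelope()].
#' @return data frame with zero rows if the train fits the envelope;
#'   otherwise one row per breached bound (columns `parameter`, `value`,
#'   `lower`, `upper`).
#' @export
validate_against_device <- function(train, envelope = device_envelope()) {
  stopifnot(inherits(train, "pulse_train"))
  out <- data.frame(parameter = character(), value = numeric(),
                    lower = numeric(), upper = numeric())
  for (p in names(envelope)) {
    v <- train[[p]]
    b <- envelope[[p]]
    if (v < b[1] || v > b[2])
      out <- rbind(out, data.frame(parameter = p, value = v,
                                   lower = b[1], upper = b[2]))
  }
  out
}

#' Classify electrode-skin contact from impedance
#'
#' Reproduces the three-range contact check performed before pulse delivery:
#' impedance below the lower bound indicates a short (no skin contact),
#' impedance above the upper bound an open circuit, and the band in between
#' proper skin contact.
#'
#' @param z measured impedance (Ohm), >= 0; vectorized.
#' @param bounds `c(low, high)` thresholds (Ohm), `low < high`. The defaults
#'   (100 Ohm, 10 kOhm) are configurable plumbing, not device constants.
#' @return factor with levels `too_low`, `contact`, `too_high`.
#' @export
classify_contact_impedance <- function(z, bounds = c(100, 1e4)) {
  if (any(z < 0)) stop("'z' must be non-negative")
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  out <- ifelse(z < bounds[1], "too_low",
                ifelse(z > bounds[2], "too_high", "contact"))
  factor(out, levels = c("too_low", "contact", "too_high"))
}

#' Export a protocol to JSON
#'
#' @param protocol a [generate_protocol()] result.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
protocol_to_json <- function(protocol, path = NULL) {
  stopifnot(inherits(protocol, "protocol"))
  obj <- list(
    name = protocol$name,
    arrangement = protocol$array$arrangement,
    train = unclass(protocol$train),
    steps = lapply(protocol$steps, function(s)
      list(anodes = s$anodes, cathodes = s$cathodes,
           amplitude = s$amplitude)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Import a protocol from JSON
#'
#' @param path file path or JSON string as produced by [protocol_to_json()].
#' @return a `protocol` object (the electrode array is rebuilt from the
#'   recorded arrangement with default geometry).
#' @export
protocol_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tr <- obj$train
  train <- pulse_train(Ap = tr$Ap, Tp = tr$Tp, NrP = tr$NrP, PRR = tr$PRR,
                       NrB = if (is.null(tr$NrB)) 1L else tr$NrB,
                       BRR = if (is.null(tr$BRR)) NA_real_ else tr$BRR)
  steps <- lapply(obj$steps, function(s)
    new_protocol_step(unlist(s$anodes), unlist(s$cathodes), s$amplitude))
  structure(list(steps = steps, train = train, name = obj$name,
                 array = build_array(obj$arrangement)),
            class = "protocol")
}
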