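# Analog front-end and sensor-cavity design calculators: pure closed-form
# design-verification functions; nothing here simulates transients.

#' Load resistor for a piezoelectric sensor's parasitic capacitance
#'
#' A piezoelectric element loaded by a resistor forms a first-order high-pass
#' with corner `f_c = 1 / (2 pi R C_p)`. Given the parasitic capacitance and
#' the desired corner this returns the required load resistance
#' `R = 1 / (2 pi f_c C_p)`.
#'
#' @param C_p Parasitic capacitance in farads.
#' @param f_c Desired corner frequency in Hz.
#' @return Resistance in ohms.
#' @examples
#' load_resistor(8000e-12, 1) / 1e6  # about 20 Mohm
#' @export
load_resistor <- function(C_p, f_c) {
  if (!is.finite(C_p) || C_p <= 0) stop("load_resistor: C_p must be > 0", call. = FALSE)
  if (!is.finite(f_c) || f_c <= 0) stop("load_resistor: f_c must be > 0", call. = FALSE)
  1 / (2 * pi * f_c * C_p)
}

#' Voltage gain of the amplifier stage
#'
#' The stage gain is set by a resistor pair: `Vout = Vin * R2 / R3`.
#'
#' @param R2,R3 Resistances in ohms, both positive.
#' @return Dimensionless gain `R2 / R3`.
#' @export
amplifier_gain <- function(R2, R3) {
  if (!is.finite(R2) || R2 <= 0 || !is.finite(R3) || R3 <= 0) {
    stop("amplifier_gain: resistances must be > 0", call. = FALSE)
  }
  R2 / R3
}

#' Construct a second-order Sallen-Key stage
#'
#' @param R_a,R_b Resistances in ohms.
#' @param C_a,C_b Capacitances in farads.
#' @param topology `"highpass"` or `"lowpass"`.
#' @return An object of class `sallen_key_stage`.
#' @export
sallen_key_stage <- function(R_a, R_b, C_a, C_b,
                             topology = c("highpass", "lowpass")) {
  topology <- match.arg(topology)
  vals <- c(R_a = R_a, R_b = R_b, C_a = C_a, C_b = C_b)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("sallen_key_stage: all component values must be positive", call. = FALSE)
  }
  structure(list(R_a = R_a, R_b = R_b, C_a = C_a, C_b = C_b,
                 topology = topology),
            class = "sallen_key_stage")
}

#' Cut-off frequency of a Sallen-Key stage
#'
#' Identical expression for both topologies:
#' `f_c = 1 / (2 pi sqrt(R_a C_a R_b C_b))`.
#'
#' @param stage A [sallen_key_stage()].
#' @return Frequency in Hz.
#' @export
sallen_key_cutoff <- function(stage) {
  stopifnot(inherits(stage, "sallen_key_stage"))
  1 / (2 * pi * sqrt(stage$R_a * stage$C_a * stage$R_b * stage$C_b))
}

#' Magnitude of the Sallen-Key transfer function at a frequency
#'
#' Evaluates the unity-gain second-order transfer function at `s = j 2 pi f`.
#' High-pass: `H(s) = s^2 / (s^2 + s (1/(R_a C_a) + 1/(R_a C_b)) + 1/(R_a C_a R_b C_b))`.
#' Low-pass: `H(s) = (1/(R_a C_a R_b C_b)) / (s^2 + s (1/(R_b C_a) + 1/(R_a C_a)) + 1/(R_a C_a R_b C_b))`.
#' For equal components both give `|H(f_c)| = 1/2` (Q = 1/2).
#'
#' @param stage A [sallen_key_stage()].
#' @param f Frequency in Hz, positive; vectorised.
#' @return Dimensionless magnitude `|H|`.
#' @export
sallen_key_magnitude <- function(stage, f) {
  stopifnot(inherits(stage, "sallen_key_stage"))
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("sallen_key_magnitude: f must be > 0", call. = FALSE)
  }
  s <- 1i * 2 * pi * f
  w0sq <- 1 / (stage$R_a * stage$C_a * stage$R_b * stage$C_b)
  if (stage$topology == "highpass") {
    a1 <- 1 / (stage$R_a * stage$C_a) + 1 / (stage$R_a * stage$C_b)
    h <- s^2 / (s^2 + a1 * s + w0sq)
  } else {
    a1 <- 1 / (stage$R_b * stage$C_a) + 1 / (stage$R_a * stage$C_a)
    h <- w0sq / (s^2 + a1 * s + w0sq)
  }
  Mod(h)
}

#' Construct a sensor cavity model
#'
#' Small acoustic cavity behind the piezoelectric plate: adiabatic compression
#' of the trapped air gives a linear restoring force on the moving air column,
#' so the cavity behaves as a Helmholtz-type resonator.
#'
#' @param V Cavity volume before pressurisation (m^3).
#' @param S Section area of the moving column (m^2).
#' @param L Column (neck) length (m).
#' @param P_A Static pressure (Pa), default one atmosphere.
#' @param gamma Ratio of specific heats, about 1.4 for air.
#' @param rho_air Air density (kg/m^3), default 1.2.
#' @return An object of class `cavity_model`.
#' @export
cavity_model <- function(V, S, L, P_A = 101325, gamma = 1.4, rho_air = 1.2) {
  vals <- c(V = V, S = S, L = L, P_A = P_A, gamma = gamma, rho_air = rho_air)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("cavity_model: all fields must be positive", call. = FALSE)
  }
  structure(as.list(vals), class = "cavity_model")
}

#' Restoring acceleration of the cavity air column
#'
#' Linear small-signal law `a(x) = -(gamma S P_A / (rho_air V L)) x`: a
#' displacement of the column compresses the cavity adiabatically and the
#' pressure excess pushes back. The small-signal regime `|x| << V/S` is
#' assumed, not enforced.
#'
#' @param displacement Column displacement in metres (vectorised).
#' @param cav A [cavity_model()].
#' @return Acceleration in m/s^2, opposite in sign to the displacement.
#' @export
cavity_acceleration <- function(displacement, cav) {
  stopifnot(inherits(cav, "cavity_model"))
  k <- cav$gamma * cav$S * cav$P_A / (cav$rho_air * cav$V * cav$L)
  -k * displacement
}

#' Natural frequency of the sensor cavity
#'
#' Direct consequence of the linear restoring law:
#' `f0 = (1 / 2 pi) sqrt(gamma S P_A / (rho_air V L))`. For millimetre-scale
#' cavities this lands in the tens of kHz, far above the pulse band, which is
#' why the cavity does not colour the pulse waveform.
#'
#' @param cav A [cavity_model()].
#' @return Frequency in Hz.
#' @export
cavity_natural_frequency <- function(cav) {
  stopifnot(inherits(cav, "cavity_model"))
  k <- cav$gamma * cav$S * cav$P_A / (cav$rho_air * cav$V * cav$L)
  sqrt(k) / (2 * pi)
}
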