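#' Pore geometry/conductance model parameters
#'
#' The access-resistance (Hille) model relates the conductance `g` of a
#' water-filled cylindrical pore to its diameter `d`.  Total pore
#' resistance is the cylindrical ohmic term plus one convergence
#' (access) resistance of rho/(2 d) at each mouth:
#'
#'   1/g = 4 rho l / (pi d^2) + rho / d
#'
#' with `l` the pore length and `rho` the solution resistivity.
#'
#' @param l_nm Channel (pore) length in nm; `0` gives the pure
#'   access-resistance limit.
#' @param rho_ohm_cm Solution resistivity in ohm cm.
#' @return A list of class `pore_model`.
#' @examples
#' m <- pore_model()                 # l = 5.4 nm, rho = 80 ohm cm
#' hille_diameter(320, m)            # ~1.46 nm
#' @export
pore_model <- function(l_nm = 5.4, rho_ohm_cm = 80) {
  stopifnot(is.numeric(l_nm), length(l_nm) == 1, l_nm >= 0,
            is.numeric(rho_ohm_cm), length(rho_ohm_cm) == 1, rho_ohm_cm > 0)
  structure(list(l_nm = l_nm, rho_ohm_cm = rho_ohm_cm), class = "pore_model")
}

# rho * g has units of length; in nm: ohm cm * pS = 1e-2 ohm m * 1e-12 S
# = 1e-14 m = 1e-5 nm.
rho_g_nm <- function(g_pS, rho_ohm_cm) rho_ohm_cm * g_pS * 1e-5

#' Pore diameter from single-channel conductance
#'
#' Positive root of the access-resistance pore equation
#' `1/g = 4 rho l/(pi d^2) + rho/d`, i.e.
#' `d = a/2 + sqrt(a^2/4 + 4 a l/pi)` with `a = rho g` expressed as a
#' length.  For `l = 0` this reduces to `d = rho g` exactly.
#'
#' @param g_pS Ionic conductance, pS (scalar or vector, all > 0).
#' @param model A [pore_model()].
#' @return Pore diameter(s) in nm.
#' @examples
#' hille_diameter(c(135, 320, 540), pore_model(5.4, 80))
#' @export
hille_diameter <- function(g_pS, model = pore_model()) {
  stopifnot(inherits(model, "pore_model"), is.numeric(g_pS))
  if (any(!is.finite(g_pS)) || any(g_pS <= 0))
    stop("conductance must be positive and finite")
  a <- rho_g_nm(g_pS, model$rho_ohm_cm)
  a / 2 + sqrt(a^2 / 4 + 4 * a * model$l_nm / pi)
}

#' Single-channel conductance from pore diameter
#'
#' Algebraic inverse of [hille_diameter()]:
#' `g = 1 / (4 rho l/(pi d^2) + rho/d)`, returned in pS.
#'
#' @param d_nm Pore diameter, nm (scalar or vector, all > 0).
#' @param model A [pore_model()].
#' @return Conductance(s) in pS.
#' @export
hille_conductance <- function(d_nm, model = pore_model()) {
  stopifnot(inherits(model, "pore_model"), is.numeric(d_nm))
  if (any(!is.finite(d_nm)) || any(d_nm <= 0))
    stop("diameter must be positive and finite")
  rho_m <- model$rho_ohm_cm * 1e-2          # ohm m
  d_m <- d_nm * 1e-9
  l_m <- model$l_nm * 1e-9
  r_ohm <- rho_m * (4 * l_m / (pi * d_m^2) + 1 / d_m)
  1e12 / r_ohm
}
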