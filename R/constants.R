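# Physical constants used throughout the package (kcal/mol energy scale).

#' Physical constants
#'
#' Constants used by the selectivity arithmetic: the molar gas constant in
#' kcal/(mol K), the Boltzmann/Planck ratio k_B/h in 1/(s K), and the
#' Hartree to kcal/mol conversion factor (CODATA).
#'
#' @format A named list with elements `R` (kcal mol^-1 K^-1),
#'   `kB_over_h` (s^-1 K^-1), `hartree_to_kcal` (kcal/mol per Hartree) and
#'   `T_default` (K).
#' @export
confsel_constants <- list(
  R               = 1.987204e-3,
  kB_over_h       = 2.083661e10,
  hartree_to_kcal = 627.5094740631,
  T_default       = 298.15
)

# RT in kcal/mol at temperature T (K)
rt_kcal <- function(T = confsel_constants$T_default) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    abort_contract("temperature must be a single finite value > 0 K")
  confsel_constants$R * T
}

# Structured condition helpers. All user-facing errors carry a class under
# "confsel_error" so callers (and the CLI) can distinguish user errors from
# genuine bugs.
confsel_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "confsel_error", "error")))
}
abort_parse       <- function(msg) confsel_abort(msg, "confsel_parse_error")
abort_composition <- function(msg) confsel_abort(msg, "confsel_composition_error")
abort_contract    <- function(msg) confsel_abort(msg, "confsel_contract_error")
abort_config      <- function(msg) confsel_abort(msg, "confsel_config_error")
abort_mismatch    <- function(msg) confsel_abort(msg, "confsel_mismatch_error")
abort_lookup      <- function(msg) confsel_abort(msg, "confsel_lookup_error")
abort_io          <- function(msg) confsel_abort(msg, "confsel_io_error")

# Single-bond covalent radii in Angstrom (Cordero-style table) for bond
# perception: atoms i, j are bonded iff d(i,j) <= tol * (r_i + r_j).
.covalent_radii <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  Ar = 1.06,
  K = 2.03, Ca = 1.76, Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39,
  Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22, Ga = 1.22,
  Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16,
  Rb = 2.20, Sr = 1.95, Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54,
  Tc = 1.47, Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44,
  In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40,
  Cs = 2.44, Ba = 2.15, La = 2.07, W = 1.62, Re = 1.51, Os = 1.44,
  Ir = 1.41, Pt = 1.36, Au = 1.36, Hg = 1.32, Tl = 1.45, Pb = 1.46,
  Bi = 1.48
)

#' Single-bond covalent radius of an element
#'
#' @param element Character vector of element symbols (case sensitive,
#'   standard periodic-table capitalization).
#' @return Numeric vector of radii in Angstrom.
#' @export
#' @examples
#' covalent_radius(c("H", "C", "I"))
covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r))
    abort_lookup(sprintf("unknown element symbol(s): %s",
                         paste(unique(element[is.na(r)]), collapse = ", ")))
  unname(r)
}

is_element <- function(element) element %in% names(.covalent_radii)
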