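#' Standard atomic weights
#'
#' Atomic masses (unified atomic mass units) for the elements that occur in
#' drug-like small molecules, pinned in the package so descriptor values are
#' reproducible independently of any external mass table. Values follow the
#' IUPAC 2021 standard atomic weights, abridged to five significant figures.
#'
#' @format Named numeric vector, element symbol to mass in amu.
#' @keywords internal
ATOMIC_MASSES <- c(
  H  = 1.008,   He = 4.0026,  Li = 6.94,    Be = 9.0122,  B  = 10.81,
  C  = 12.011,  N  = 14.007,  O  = 15.999,  F  = 18.998,  Ne = 20.180,
  Na = 22.990,  Mg = 24.305,  Al = 26.982,  Si = 28.085,  P  = 30.974,
  S  = 32.06,   Cl = 35.45,   Ar = 39.948,  K  = 39.098,  Ca = 40.078,
  Cr = 51.996,  Mn = 54.938,  Fe = 55.845,  Co = 58.933,  Ni = 58.693,
  Cu = 63.546,  Zn = 65.38,   Ga = 69.723,  Ge = 72.630,  As = 74.922,
  Se = 78.971,  Br = 79.904,  Mo = 95.95,   Ru = 101.07,  Rh = 102.91,
  Pd = 106.42,  Ag = 107.87,  Cd = 112.41,  Sn = 118.71,  Sb = 121.76,
  Te = 127.60,  I  = 126.90,  Ba = 137.33,  Pt = 195.08,  Au = 196.97,
  Hg = 200.59,  Pb = 207.2,   Bi = 208.98
)

#' Look up standard atomic masses by element symbol
#'
#' @param symbols Character vector of element symbols (case sensitive,
#'   e.g. `"C"`, `"Cl"`).
#' @return Numeric vector of atomic masses in amu.
#' @examples
#' atomic_mass(c("C", "H", "O"))
#' @export
atomic_mass <- function(symbols) {
  m <- ATOMIC_MASSES[symbols]
  if (anyNA(m)) {
    bad <- unique(symbols[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}
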