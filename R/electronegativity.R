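# Pauling electronegativities used to weight the nodes of the molecular
# graph. The table is part of the package contract: descriptor values
# change if it changes, so treat edits as breaking.
.pauling <- c(
  H  = 2.20, Li = 0.98, Be = 1.57, B  = 2.04, C  = 2.55, N  = 3.04,
  O  = 3.44, F  = 3.98, Na = 0.93, Mg = 1.31, Al = 1.61, Si = 1.90,
  P  = 2.19, S  = 2.58, Cl = 3.16, K  = 0.82, Ca = 1.00, Sc = 1.36,
  Ti = 1.54, V  = 1.63, Cr = 1.66, Mn = 1.55, Fe = 1.83, Co = 1.88,
  Ni = 1.91, Cu = 1.90, Zn = 1.65, Ga = 1.81, Ge = 2.01, As = 2.18,
  Se = 2.55, Br = 2.96, Rb = 0.82, Sr = 0.95, Mo = 2.16, Ru = 2.20,
  Rh = 2.28, Pd = 2.20, Ag = 1.93, Cd = 1.69, In = 1.78, Sn = 1.96,
  Sb = 2.05, Te = 2.10, I  = 2.66, Cs = 0.79, Ba = 0.89, W  = 2.36,
  Pt = 2.28, Au = 2.54, Hg = 2.00, Tl = 1.62, Pb = 2.33, Bi = 2.02
)

#' Pauling electronegativity lookup
#'
#' Returns the Pauling electronegativity for each element symbol. Charged
#' atoms use the neutral element's value; the table covers the main-group
#' and common transition elements found in drug-like molecules.
#'
#' @param symbols Character vector of element symbols (e.g. `"C"`, `"Cl"`).
#' @return Numeric vector of electronegativities, named by symbol.
#' @examples
#' pauling_chi(c("C", "N", "O"))
#' @export
pauling_chi <- function(symbols) {
  chi <- .pauling[symbols]
  if (anyNA(chi)) {
    missing <- unique(symbols[is.na(chi)])
    stop(alma_error(
      sprintf("no electronegativity tabulated for element(s): %s",
              paste(missing, collapse = ", ")),
      class = "alma_config_error"))
  }
  names(chi) <- symbols
  chi
}

# Condition constructors shared across the package: data errors (bad files,
# bad values, failed lookups) map to CLI exit 3, everything else to 4.
alma_error <- function(message, class = "alma_data_error", call = NULL) {
  structure(
    class = c(class, "alma_error", "error", "condition"),
    list(message = message, call = call))
}
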