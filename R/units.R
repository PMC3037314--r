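#' Convert between nanomolar concentrations and molecule counts
#'
#' Compartment volumes are in cubic micrometres, so a concentration of
#' `conc` nM in a volume `V` corresponds to
#' `conc * 1e-9 mol/L * V * 1e-15 L * N_Avogadro` molecules. For a typical
#' bacterial cell volume of 1.5 um^3, 25 nM is about 22.58 molecules --
#' counts this low are exactly why molecular shot noise matters here.
#'
#' @param conc concentration in nM (non-negative).
#' @param count expected molecule count (non-negative, need not be integer).
#' @param V compartment volume in um^3 (positive).
#' @return `molecules_from_concentration()` returns the expected molecule
#'   count (a real number, deliberately not rounded);
#'   `concentration_from_molecules()` is its inverse and returns nM.
#' @examples
#' molecules_from_concentration(25, 1.5) # ~22.58
#' concentration_from_molecules(1, 1.5)  # ~1.107 nM
#' @export
molecules_from_concentration <- function(conc, V) {
  stopifnot(is.numeric(conc), is.numeric(V))
  if (any(conc < 0)) stop("concentration must be non-negative")
  if (any(V <= 0)) stop("volume must be positive")
  conc * 1e-9 * V * 1e-15 * .avogadro
}

#' @rdname molecules_from_concentration
#' @export
concentration_from_molecules <- function(count, V) {
  stopifnot(is.numeric(count), is.numeric(V))
  if (any(count < 0)) stop("molecule count must be non-negative")
  if (any(V <= 0)) stop("volume must be positive")
  count / (1e-9 * V * 1e-15 * .avogadro)
}

# 2019 SI definition
.avogadro <- 6.02214076e23
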