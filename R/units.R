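# Internal unit conventions: lengths in Angstrom, times in ps inside the
# package; ns only at reporting boundaries (time series, change points).

#: 1 cm^2/s = 1e16 A^2/s = 1e4 A^2/ps
A2PS_PER_CM2S <- 1e4

#' Convert a diffusion coefficient between cm^2/s and A^2/ps
#'
#' All trajectory-level arithmetic in the package is done in Angstrom and
#' picoseconds; diffusion coefficients are reported in cm^2/s, the unit used
#' throughout the water-simulation literature (1 cm^2/s = 1e4 A^2/ps).
#'
#' @param D numeric, diffusion coefficient(s).
#' @return numeric of the same length, converted.
#' @examples
#' cm2s_to_A2ps(5.95e-5)  # 0.595 A^2/ps
#' @export
cm2s_to_A2ps <- function(D) D * A2PS_PER_CM2S

#' @rdname cm2s_to_A2ps
#' @export
A2ps_to_cm2s <- function(D) D / A2PS_PER_CM2S

# Boltzmann constant, J/K
.kB <- 1.380649e-23
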