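# Element constants for stopping-power evaluation: atomic number Z, standard
# atomic weight A (g/mol) and mean excitation energy I (eV) from the standard
# tabulation used for dosimetry work.
.elements <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K", "Ca"),
  Z = c(1, 6, 7, 8, 11, 15, 16, 17, 19, 20),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 30.974, 32.06, 35.45,
        39.098, 40.078),
  I_eV = c(19.2, 78.0, 82.0, 95.0, 149.0, 173.0, 180.0, 174.0, 190.0, 191.0),
  stringsAsFactors = FALSE
)

#' Define an absorbing medium for proton transport
#'
#' A medium is defined by its density and elemental composition (mass
#' fractions).  The effective Z/A and the mean excitation energy I are derived
#' by Bragg additivity unless I is supplied explicitly (condensed-phase values
#' such as 75 eV for liquid water differ from the gas-additivity estimate).
#'
#' @param name Label for the medium.
#' @param density Mass density in g/cm^3.
#' @param composition Named numeric vector of mass fractions by element
#'   symbol (e.g. `c(H = 0.112, O = 0.888)`).  Must sum to 1 within 1e-6.
#' @param mean_excitation_energy Optional mean excitation energy I in eV.
#'   When `NULL`, derived from the composition by Bragg additivity on ln I.
#' @return An object of class `medium` with fields `name`, `density`,
#'   `composition`, `mean_excitation_energy` (eV) and `z_over_a`.
#' @seealso [builtin_medium()] for the media used in the experiments.
#' @export
#' @examples
#' m <- medium("water", 1.0, c(H = 0.111894, O = 0.888106), 75)
#' mass_stopping_power(m, 100)
medium <- function(name, density, composition, mean_excitation_energy = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("`density` must be a positive scalar (g/cm^3)")
  if (is.null(names(composition)) || !is.numeric(composition))
    stop("`composition` must be a named numeric vector of mass fractions")
  unknown <- setdiff(names(composition), .elements$symbol)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(composition < 0))
    stop("mass fractions must be non-negative")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mass fractions must sum to 1 within 1e-6 (got ",
         format(sum(composition)), ")")
  idx <- match(names(composition), .elements$symbol)
  za <- .elements$Z[idx] / .elements$A[idx]
  z_over_a <- sum(composition * za)
  if (is.null(mean_excitation_energy)) {
    # Bragg additivity on ln I, weighted by electron fraction w * Z/A
    mean_excitation_energy <-
      exp(sum(composition * za * log(.elements$I_eV[idx])) / z_over_a)
  }
  if (mean_excitation_energy <= 0)
    stop("`mean_excitation_energy` must be > 0 (eV)")
  structure(
    list(name = name, density = density,
         composition = composition,
         mean_excitation_energy = mean_excitation_energy,
         z_over_a = z_over_a),
    class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s: rho = %.4g g/cm^3, Z/A = %.5f, I = %.4g eV\n",
              x$name, x$density, x$z_over_a, x$mean_excitation_energy))
  comp <- paste(sprintf("%s %.4f", names(x$composition), x$composition),
                collapse = ", ")
  cat("  composition (mass fractions):", comp, "\n")
  invisible(x)
}

# Mass fractions of DMSO, (CH3)2SO, from the molecular formula.
.dmso_fractions <- local({
  m <- c(C = 2 * 12.011, H = 6 * 1.008, O = 15.999, S = 32.06)
  m / sum(m)
})

#' Built-in media
#'
#' Media used in the modelled experiments: liquid water (I = 75 eV),
#' DMSO (the photosensitiser solvent, density 1.10 g/cm^3), polystyrene
#' (cuvette material), dry gelatin (protein-like composition for the dry-gel
#' samples) and an ICRU-like average soft tissue.
#'
#' @param name One of `"water"`, `"dmso"`, `"polystyrene"`, `"gelatin"`,
#'   `"soft_tissue"`.
#' @return A [medium()] object.
#' @export
#' @examples
#' builtin_medium("dmso")
builtin_medium <- function(name = c("water", "dmso", "polystyrene",
                                    "gelatin", "soft_tissue")) {
  name <- match.arg(name)
  switch(name,
    water = medium("water", 1.000, c(H = 0.111894, O = 0.888106), 75),
    dmso = medium("dmso", 1.10, .dmso_fractions),
    polystyrene = medium("polystyrene", 1.06,
                         c(C = 0.922582, H = 0.077418), 68.7),
    # dry protein (collagen-like) elemental make-up
    gelatin = medium("gelatin", 1.35,
                     c(H = 0.0661, C = 0.4590, N = 0.1630, O = 0.2990,
                       S = 0.0129)),
    soft_tissue = medium("soft_tissue", 1.06,
                         c(H = 0.102, C = 0.143, N = 0.034, O = 0.708,
                           Na = 0.002, P = 0.003, S = 0.003, Cl = 0.002,
                           K = 0.003)))
}
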