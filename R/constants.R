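#' Model constants
#'
#' Physical constants and model-wide reference values used throughout the
#' SSIP solvation model: the working temperature, the gas constant, the
#' solvent-solvent entropy constant of the 1:1 complexation expression
#' (+6 kJ/mol, experimentally determined in carbon tetrachloride), and the
#' benchmark total SSIP concentration of a pure liquid (about 220 M, the
#' value that anchors the number of interaction points assigned per
#' molecule).
#'
#' @param temperature Temperature in kelvin. Default 298.15 K.
#' @param gas_constant Gas constant in J mol^-1 K^-1. Default 8.3145.
#' @param reference_ss_entropy The constant of the solvent-competition
#'   expression for 1:1 complexation, in kJ mol^-1. Default 6.0.
#' @param target_ssip_concentration Benchmark SSIP concentration of a pure
#'   liquid in mol L^-1. Default 220.
#' @return An object of class `model_constants`.
#' @examples
#' mc <- model_constants()
#' rt_kj(mc) # 2.479 kJ/mol at 298.15 K
#' @export
model_constants <- function(temperature = 298.15,
                            gas_constant = 8.3145,
                            reference_ss_entropy = 6.0,
                            target_ssip_concentration = 220) {
  stopifnot(temperature > 0, gas_constant > 0, target_ssip_concentration > 0)
  structure(
    list(
      temperature = temperature,
      gas_constant = gas_constant,
      reference_ss_entropy = reference_ss_entropy,
      target_ssip_concentration = target_ssip_concentration
    ),
    class = "model_constants"
  )
}

#' Thermal energy RT in kJ/mol
#'
#' @param constants A [model_constants()] object.
#' @return RT in kJ mol^-1 (2.479 at the default 298.15 K).
#' @export
rt_kj <- function(constants = model_constants()) {
  constants$gas_constant * constants$temperature / 1000
}

#' @export
print.model_constants <- function(x, ...) {
  cat("SSIP model constants:\n")
  cat(sprintf("  T                    : %.2f K\n", x$temperature))
  cat(sprintf("  R                    : %.4f J/mol/K  (RT = %.4f kJ/mol)\n",
              x$gas_constant, rt_kj(x)))
  cat(sprintf("  RT ln[S.S] reference : %.1f kJ/mol\n", x$reference_ss_entropy))
  cat(sprintf("  [SSIP] benchmark     : %.0f M\n", x$target_ssip_concentration))
  invisible(x)
}
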