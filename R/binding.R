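#' Mass-action binding equilibrium for a 1:1 complex
#'
#' Solves `K_D = [A][B]/[AB]` for the complex concentration at given total
#' concentrations, i.e. the root of
#' `[AB]^2 - (A + B + K_D) [AB] + A B = 0` with `0 <= [AB] <= min(A, B)`.
#'
#' @param total_A,total_B total concentrations of the two partners, mol/L.
#' @param K_D dissociation constant, mol/L. `Inf` (or very large) gives the
#'   no-binding limit, 0 the stoichiometric limit `min(A, B)`.
#' @return Complex concentration `[AB]`, mol/L.
#' @examples
#' solve_binding_equilibrium(1e-7, 1e-7, 1e-7)  # 100*(3 - sqrt(5))/2 nM
#' @export
solve_binding_equilibrium <- function(total_A, total_B, K_D) {
  if (any(c(total_A, total_B, K_D) < 0) ||
      any(is.na(c(total_A, total_B, K_D))))
    stop("concentrations and K_D must be nonnegative")
  if (total_A == 0 || total_B == 0) return(0)
  if (is.infinite(K_D)) return(0)
  s <- total_A + total_B + K_D
  # numerically stable smaller quadratic root: 2AB / (s + sqrt(s^2 - 4AB))
  disc <- s^2 - 4 * total_A * total_B
  disc <- max(disc, 0)
  ab <- 2 * total_A * total_B / (s + sqrt(disc))
  min(ab, total_A, total_B)
}

#' Diffusion coefficient of a 1:1 complex from its partners
#'
#' Stokes-Einstein with additive hydrodynamic volumes: the complex radius is
#' `(R_A^3 + R_B^3)^(1/3)`, so `D_AB = (D_A^-3 + D_B^-3)^(-1/3)`.
#'
#' @param D_A,D_B partner diffusion coefficients, um^2/s.
#' @return Complex diffusion coefficient, um^2/s.
#' @export
complex_diffusion <- function(D_A, D_B) {
  (D_A^-3 + D_B^-3)^(-1 / 3)
}
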