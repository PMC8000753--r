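#' Transversely isotropic elastic constants for trabecular bone
#'
#' One distinguished (longitudinal) axis aligned with the spike/loading
#' direction, modulus `E2`, and an isotropic transverse plane with modulus
#' `E1`. Defaults are the cancellous-bone constants used throughout:
#' E1 = 608, E2 = 771, G1 = 260, G2 = 269 MPa, nu1 = 0.17, nu2 = 0.15, and an
#' ultimate compressive strength sigma_c = 25 MPa (the embedding-force limit
#' stress).
#'
#' @param E1 Transverse Young's modulus, MPa.
#' @param E2 Longitudinal Young's modulus, MPa.
#' @param G1 Transverse shear modulus, MPa.
#' @param G2 Longitudinal shear modulus, MPa.
#' @param nu1 Transverse Poisson's ratio.
#' @param nu2 Longitudinal Poisson's ratio.
#' @param sigma_c Ultimate compressive strength, MPa.
#' @return Object of class `elastic_constants`.
#' @export
elastic_constants <- function(E1 = 608, E2 = 771, G1 = 260, G2 = 269,
                              nu1 = 0.17, nu2 = 0.15, sigma_c = 25) {
  if (any(c(E1, E2, G1, G2) <= 0)) stop("moduli must be positive")
  if (any(c(nu1, nu2) <= -1) || any(c(nu1, nu2) >= 0.5)) {
    stop("Poisson ratios must lie in (-1, 0.5)")
  }
  stopifnot(sigma_c > 0)
  out <- structure(list(E1 = E1, E2 = E2, G1 = G1, G2 = G2,
                        nu1 = nu1, nu2 = nu2, sigma_c = sigma_c),
                   class = "elastic_constants")
  ev <- eigen(stiffness_matrix(out), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("constants give a non-positive-definite stiffness")
  out
}

#' Scaffold (Ti-6Al-4V) material constants
#'
#' Retained for completeness; the embedding model treats the scaffold as
#' rigid because its modulus (116 GPa) is two orders of magnitude above the
#' bone's, so the apex footprints carry a prescribed displacement instead.
#'
#' @param E Young's modulus, GPa.
#' @param nu Poisson's ratio.
#' @param yield_strength Yield strength, MPa.
#' @return Object of class `scaffold_material`.
#' @export
scaffold_material <- function(E = 116, nu = 0.34, yield_strength = 1010) {
  stopifnot(E > 0, nu > 0, nu < 0.5, yield_strength > 0)
  structure(list(E = E, nu = nu, yield_strength = yield_strength),
            class = "scaffold_material")
}

#' 6x6 stiffness matrix of a transversely isotropic material
#'
#' Voigt order (11, 22, 33, 23, 13, 12) with engineering shear strains; axis
#' 3 (z) is the longitudinal `E2` direction and the plane of isotropy is
#' perpendicular to it. Built by inverting the compliance
#' `eps = S sigma` with `S13 = S23 = -nu2/E2`, `S12 = -nu1/E1`, shear
#' compliances `1/G2` (out-of-plane) and `1/G1` (in-plane). In the isotropic
#' limit (`E1 = E2`, `nu1 = nu2`, `G1 = G2 = E/(2(1+nu))`) it reduces to the
#' Lame form exactly.
#'
#' @param constants An [elastic_constants()].
#' @return 6x6 symmetric positive-definite matrix, MPa.
#' @export
stiffness_matrix <- function(constants) {
  stopifnot(inherits(constants, "elastic_constants"))
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- 1 / constants$E1
  S[3, 3] <- 1 / constants$E2
  S[1, 2] <- S[2, 1] <- -constants$nu1 / constants$E1
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -constants$nu2 / constants$E2
  S[4, 4] <- S[5, 5] <- 1 / constants$G2
  S[6, 6] <- 1 / constants$G1
  C <- solve(S)
  (C + t(C)) / 2
}

#' Huber-von Mises-Hencky equivalent stress
#'
#' `sqrt(0.5 * ((s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2) + 3 * (t23^2 + t13^2 + t12^2))`.
#'
#' @param stress A symmetric 3x3 stress tensor, a length-6 Voigt vector
#'   (11, 22, 33, 23, 13, 12), or an n x 6 matrix of Voigt rows. MPa.
#' @return Scalar (or length-n vector) of equivalent stress, MPa; always >= 0.
#' @export
hmh_stress <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3, 3))) {
    stress <- c(stress[1, 1], stress[2, 2], stress[3, 3],
                stress[2, 3], stress[1, 3], stress[1, 2])
  }
  if (is.null(dim(stress))) stress <- matrix(stress, nrow = 1)
  stopifnot(ncol(stress) == 6L)
  s1 <- stress[, 1]; s2 <- stress[, 2]; s3 <- stress[, 3]
  sqrt(0.5 * ((s1 - s2)^2 + (s2 - s3)^2 + (s3 - s1)^2) +
         3 * (stress[, 4]^2 + stress[, 5]^2 + stress[, 6]^2))
}
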