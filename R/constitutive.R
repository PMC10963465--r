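#' Layer material: constrained-mixture HGO constants for one wall layer
#'
#' One aortic wall layer (media or adventitia) is modeled as a constrained
#' mixture of isotropic neo-Hookean elastin and two symmetric families of
#' one-dimensional collagen fibers with exponential (Holzapfel-Gasser-Ogden)
#' stiffening and no dispersion. Strain energies per unit constituent density
#' fraction are
#' \deqn{\psi^e = \frac{c_{10}}{\rho_0^e}(I_1 - 3), \qquad
#'       \psi^c = \frac{k_1}{\rho_0^c}\frac{1}{2k_2}
#'         \sum_{i=4,6}\left[e^{k_2 (I_i-1)^2} - 1\right],}
#' with the tension-only switch \eqn{I_i \mapsto \max(I_i, 1)}: fibers bear
#' load in tensile stretch only.
#'
#' Densities are dimensionless fractions of the initial mixture, so that
#' \eqn{\rho^i \psi^i} recovers the intended layer stiffness at time zero;
#' each layer contains only elastin and two equal collagen families,
#' \eqn{\rho_0^e + 2\rho_0^c = 1}.
#'
#' @param c10 Elastin shear modulus, MPa.
#' @param k1 Collagen stiffness, MPa.
#' @param k2 Dimensionless collagen fiber stiffening exponent.
#' @param alpha Mean fiber angle from the circumferential direction, radians,
#'   for the symmetric +/- pair; in \[0, pi/2\].
#' @param rho0_e Initial elastin fraction.
#' @param rho0_c Initial collagen fraction per fiber family.
#' @param layer Label, "media" or "adventitia".
#' @return An object of class `layer_material`.
#' @export
layer_material <- function(c10, k1, k2, alpha, rho0_e, rho0_c,
                           layer = "media") {
  if (!all(is.finite(c(c10, k1, k2, alpha, rho0_e, rho0_c)))) {
    stop("layer_material: all constants must be finite", call. = FALSE)
  }
  if (c10 <= 0 || k2 <= 0 || k1 < 0) {
    stop("layer_material: require c10 > 0, k2 > 0, k1 >= 0", call. = FALSE)
  }
  if (alpha < 0 || alpha > pi / 2) {
    stop("layer_material: alpha must lie in [0, pi/2]", call. = FALSE)
  }
  if (abs(rho0_e + 2 * rho0_c - 1) > 1e-12) {
    stop("layer_material: rho0_e + 2*rho0_c must equal 1 ",
         "(layer contains only elastin and collagen)", call. = FALSE)
  }
  structure(list(c10 = c10, k1 = k1, k2 = k2, alpha = alpha,
                 rho0_e = rho0_e, rho0_c = rho0_c, layer = layer),
            class = "layer_material")
}

#' Default medial and adventitial materials
#'
#' Constants selected for a pulse wave velocity of 6 m/s in a middle-aged
#' human aorta, with layer coupling c10A = 0.34 c10M and k1A = 1.17 k1M from
#' published elastin/collagen area fractions. Initial fractions: media
#' elastin 0.46, collagen 0.27 per family; adventitia elastin 0.20, collagen
#' 0.40 per family.
#'
#' @return A `layer_material`.
#' @export
medial_material <- function() {
  layer_material(c10 = 0.015, k1 = 0.12, k2 = 6.9, alpha = 0.79,
                 rho0_e = 0.46, rho0_c = 0.27, layer = "media")
}

#' @rdname medial_material
#' @export
adventitial_material <- function() {
  layer_material(c10 = 0.34 * 0.015, k1 = 1.17 * 0.12, k2 = 6.9, alpha = 1.4,
                 rho0_e = 0.20, rho0_c = 0.40, layer = "adventitia")
}

#' Fourth and sixth invariants of an elastic right Cauchy-Green tensor
#'
#' The two fiber families are M = (cos alpha, +/- sin alpha, 0) in
#' (theta, z, r) ordering; I4 = M . C M for the + family, I6 for the mirror.
#'
#' @param C_elas Symmetric positive-definite 3x3 matrix (elastic right
#'   Cauchy-Green tensor) in (theta, z, r) ordering.
#' @param alpha Mean fiber angle, radians.
#' @return Named numeric vector `c(I4 = , I6 = )`.
#' @export
fiber_invariants <- function(C_elas, alpha) {
  if (!is.matrix(C_elas) || any(dim(C_elas) != 3L)) {
    stop("fiber_invariants: C_elas must be a 3x3 matrix", call. = FALSE)
  }
  if (max(abs(C_elas - t(C_elas))) > 1e-8 * max(1, max(abs(C_elas)))) {
    stop("fiber_invariants: C_elas must be symmetric", call. = FALSE)
  }
  # chol() fails on non-positive-definite input: propagate as numeric error
  tryCatch(chol(C_elas),
           error = function(e) stop("fiber_invariants: C_elas is not positive definite",
                                    call. = FALSE))
  m4 <- c(cos(alpha), sin(alpha), 0)
  m6 <- c(cos(alpha), -sin(alpha), 0)
  c(I4 = drop(m4 %*% C_elas %*% m4), I6 = drop(m6 %*% C_elas %*% m6))
}

#' Constituent strain energies per unit constituent density
#'
#' Evaluates the elastin and collagen strain-energy functions of a layer at
#' given elastic invariants. Collagen energy sums both fiber families and
#' applies the tension-only switch (invariants below 1 contribute nothing).
#'
#' @param mat A [layer_material()].
#' @param I1 First invariant of the elastic right Cauchy-Green tensor.
#' @param I4,I6 Fourth and sixth invariants (squared elastic fiber stretches).
#' @return Named numeric vector `c(psi_e = , psi_c = )`, MPa per unit density
#'   fraction.
#' @export
constituent_strain_energy <- function(mat, I1, I4, I6 = I4) {
  psi_e <- (mat$c10 / mat$rho0_e) * (I1 - 3)
  e4 <- max(I4, 1) - 1
  e6 <- max(I6, 1) - 1
  expo <- mat$k2 * c(e4, e6)^2
  if (any(expo > 700)) {
    stop("constituent_strain_energy: overflow in collagen exponent ",
         "(material failure)", call. = FALSE)
  }
  psi_c <- if (mat$k1 > 0) {
    (mat$k1 / mat$rho0_c) / (2 * mat$k2) * sum(exp(expo) - 1)
  } else 0
  c(psi_e = psi_e, psi_c = psi_c)
}

#' Collagen fiber Cauchy stress
#'
#' Scalar Cauchy stress borne along the fiber direction by one collagen
#' family, per unit constituent density fraction:
#' \eqn{\sigma^{c,f} = 2 (k_1/\rho_0^c)\, I_4 (I_4 - 1) e^{k_2 (I_4-1)^2}}
#' with \eqn{I_4 = \lambda_e^2}, and 0 for \eqn{\lambda_e \le 1}
#' (tension-only).
#'
#' @param lambda_e Elastic fiber stretch (> 0). Vectorized.
#' @param mat A [layer_material()].
#' @return Fiber Cauchy stress, MPa.
#' @export
fiber_cauchy_stress <- function(lambda_e, mat) {
  if (any(lambda_e <= 0)) {
    stop("fiber_cauchy_stress: lambda_e must be > 0", call. = FALSE)
  }
  if (mat$k1 == 0) return(numeric(length(lambda_e)))
  I4 <- pmax(lambda_e^2, 1)
  2 * (mat$k1 / mat$rho0_c) * I4 * (I4 - 1) * exp(mat$k2 * (I4 - 1)^2)
}

#' @rdname fiber_cauchy_stress
#' @details `fiber_stress_tangent()` returns
#'   \eqn{d\sigma^{c,f}/d\lambda_e}; it is 0 below the slack limit.
#' @export
fiber_stress_tangent <- function(lambda_e, mat) {
  I4 <- lambda_e^2
  out <- numeric(length(lambda_e))
  if (mat$k1 == 0) return(out)
  taut <- I4 > 1
  if (any(taut)) {
    i4 <- I4[taut]
    dsdI4 <- 2 * (mat$k1 / mat$rho0_c) * exp(mat$k2 * (i4 - 1)^2) *
      ((2 * i4 - 1) + 2 * mat$k2 * i4 * (i4 - 1)^2)
    out[taut] <- dsdI4 * 2 * lambda_e[taut]
  }
  out
}

#' Invert the fiber stress-stretch relation
#'
#' Solves `fiber_cauchy_stress(lambda, mat) == sigma` for the elastic fiber
#' stretch on the tensile branch. Used by the remodeling update, which relaxes
#' the fiber stress toward its homeostatic value and maps the relaxed stress
#' back to a stretch. Monotone Newton iteration with bisection fallback.
#'
#' @param sigma Target fiber Cauchy stress, MPa (>= 0).
#' @param mat A [layer_material()].
#' @return Elastic fiber stretch (>= 1).
#' @export
fiber_stress_inverse <- function(sigma, mat) {
  if (!is.finite(sigma) || sigma < 0) {
    stop("fiber_stress_inverse: sigma must be finite and >= 0", call. = FALSE)
  }
  if (sigma == 0 || mat$k1 == 0) return(1)
  f_at <- function(l) fiber_cauchy_stress(l, mat) - sigma
  # bracket [lo, hi]; an overflowing (Inf) stress counts as f > 0
  lo <- 1
  hi <- 1.05
  fhi <- f_at(hi)
  while (is.finite(fhi) && fhi < 0 && hi < 1e3) {
    lo <- hi
    hi <- hi * 1.3
    fhi <- f_at(hi)
  }
  lam <- (lo + hi) / 2
  for (it in seq_len(100)) {
    f <- f_at(lam)
    if (is.finite(f)) {
      if (abs(f) <= 1e-12 * sigma) break
      if (f > 0) hi <- lam else lo <- lam
      df <- fiber_stress_tangent(lam, mat)
      cand <- if (is.finite(df) && df > 0) lam - f / df else NA_real_
      lam_new <- if (is.finite(cand) && cand > lo && cand < hi) cand else
        (lo + hi) / 2
    } else {
      hi <- lam
      lam_new <- (lo + hi) / 2
    }
    if (abs(lam_new - lam) < 1e-15 * lam) { lam <- lam_new; break }
    lam <- lam_new
  }
  lam
}

#' Homeostatic collagen fiber stress
#'
#' The stress corresponding to the imposed homeostatic collagen fiber
#' deposition strain (10% by default): the set point the stress-mediated
#' turnover drives fiber stress toward.
#'
#' @param mat A [layer_material()].
#' @param deposition_stretch Collagen deposition stretch (default 1.10).
#' @return Homeostatic fiber Cauchy stress, MPa.
#' @export
homeostatic_fiber_stress <- function(mat, deposition_stretch = 1.10) {
  fiber_cauchy_stress(deposition_stretch, mat)
}

#' Total mixture strain energy at a material point
#'
#' \eqn{\psi^{tot} = \sum_i \rho^i \psi^i(F^i_{elas})} with
#' \eqn{F^i_{elas} = F H^i}, where the per-constituent map \eqn{H^i}
#' collects the inverse inelastic deformation (remodeling, growth) and the
#' deposition prestretch. Tensors are in (theta, z, r) ordering.
#'
#' @param F Total 3x3 deformation gradient.
#' @param constituents List of constituents; each a list with `rho` (current
#'   density fraction), `type` ("elastin" or "collagen"), `mat`
#'   (a [layer_material()]), `H` (3x3 matrix, default identity), and for
#'   collagen `M` (unit fiber direction in the reference of `H`).
#' @return Mixture strain energy density, MPa.
#' @export
mixture_energy <- function(F, constituents) {
  tot <- 0
  for (cn in constituents) {
    H <- if (is.null(cn$H)) diag(3) else cn$H
    Fe <- F %*% H
    if (cn$type == "elastin") {
      I1 <- sum(Fe^2)
      tot <- tot + cn$rho * (cn$mat$c10 / cn$mat$rho0_e) * (I1 - 3)
    } else {
      v <- Fe %*% cn$M
      I4 <- max(sum(v^2), 1)
      tot <- tot + cn$rho * (cn$mat$k1 / cn$mat$rho0_c) / (2 * cn$mat$k2) *
        (exp(cn$mat$k2 * (I4 - 1)^2) - 1)
    }
  }
  tot
}

#' Mixture Cauchy stress at a material point
#'
#' Analytic Cauchy stress of the constrained mixture,
#' \eqn{\sigma = J^{-1} \sum_i \rho^i
#'   \partial\psi^i/\partial F^i_{elas}\, (H^i)^T F^T - p I}.
#' Incompressibility is enforced exactly through the reaction pressure `p`,
#' which is determined by the structural solver's boundary conditions, not by
#' the material point; with `p = 0` the returned tensor is the extra
#' (constitutively determined) stress whose deviatoric part is
#' pressure-independent.
#'
#' @inheritParams mixture_energy
#' @param p Hydrostatic reaction pressure, MPa.
#' @return Symmetric 3x3 Cauchy stress tensor, MPa.
#' @export
mixture_cauchy_stress <- function(F, constituents, p = 0) {
  for (cn in constituents) {
    if (cn$rho < 0) stop("mixture_cauchy_stress: negative density", call. = FALSE)
  }
  J <- det(F)
  P <- matrix(0, 3, 3)
  for (cn in constituents) {
    H <- if (is.null(cn$H)) diag(3) else cn$H
    Fe <- F %*% H
    if (cn$type == "elastin") {
      dpsi_dFe <- 2 * (cn$mat$c10 / cn$mat$rho0_e) * Fe
    } else {
      v <- Fe %*% cn$M
      I4 <- sum(v^2)
      if (I4 <= 1 || cn$mat$k1 == 0) next
      dpsi_dI4 <- (cn$mat$k1 / cn$mat$rho0_c) * (I4 - 1) *
        exp(cn$mat$k2 * (I4 - 1)^2)
      dpsi_dFe <- 2 * dpsi_dI4 * (v %*% t(cn$M))
    }
    P <- P + cn$rho * dpsi_dFe %*% t(H)
  }
  sig <- (P %*% t(F)) / J - p * diag(3)
  (sig + t(sig)) / 2
}
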