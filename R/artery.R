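#' Artery wall material (reduced polynomial hyperelastic model)
#'
#' Sixth-order reduced polynomial strain energy
#' `W = sum_{i=1..6} C_i0 * (I1 - 3)^i`, depending only on the first strain
#' invariant. The circumferential Cauchy stress is obtained with
#' incompressible uniaxial kinematics (`I1 = lambda^2 + 2/lambda`):
#' `sigma(lambda) = 2 * (lambda^2 - 1/lambda) * sum_i i * C_i0 * (I1 - 3)^(i-1)`.
#'
#' The resistance stress `sigma_res` is the stress at the circumferential
#' resistance stretch `lambda_res` (default 1.4, i.e. a 40% diameter
#' expansion) and normalizes the wall-resistance force.
#'
#' Default coefficients are the normal-wall values (MPa):
#' C10 = 6.52e-3, C20 = 4.89e-2, C30 = 9.26e-3, C40 = 7.60e-1,
#' C50 = -4.30e-1, C60 = 8.69e-2.
#'
#' @param coeffs numeric vector of 6 coefficients C10..C60 (MPa)
#' @param lambda_res circumferential resistance stretch (default 1.4)
#' @param nu Poisson ratio entering the wall-resistance force (default 0.35)
#' @return object of class `artery_material` with `coeffs`, `lambda_res`,
#'   `nu`, `sigma_res` (MPa, cached)
#' @examples
#' mat <- artery_material()
#' mat$sigma_res          # ~0.455 MPa
#' cauchy_stress(1, mat)  # exactly 0
#' @export
artery_material <- function(coeffs = c(C10 = 6.52e-3, C20 = 4.89e-2,
                                       C30 = 9.26e-3, C40 = 7.60e-1,
                                       C50 = -4.30e-1, C60 = 8.69e-2),
                            lambda_res = 1.4, nu = 0.35) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != 6L || anyNA(coeffs))
    stopf("artery_material: exactly 6 finite coefficients C10..C60 required")
  if (lambda_res <= 1) stopf("artery_material: lambda_res must exceed 1")
  mat <- structure(list(coeffs = coeffs, lambda_res = lambda_res, nu = nu,
                        sigma_res = NA_real_),
                   class = "artery_material")
  mat$sigma_res <- cauchy_stress(lambda_res, mat)
  if (mat$sigma_res <= 0)
    stopf("artery_material: sigma_res = %.3e MPa at lambda = %.2f is not positive",
          mat$sigma_res, lambda_res)
  mat
}

#' @export
print.artery_material <- function(x, ...) {
  cat(sprintf("<artery_material> C10..C60 = %s MPa\n  lambda_res = %.2f, sigma_res = %.6f MPa, nu = %.2f\n",
              paste(signif(x$coeffs, 4), collapse = ", "),
              x$lambda_res, x$sigma_res, x$nu))
  invisible(x)
}

#' Circumferential Cauchy stress of the wall at stretch lambda
#'
#' @param lambda stretch ratio(s), must be >= 1 (compression out of scope)
#' @param material an [artery_material]
#' @return stress in MPa, zero at lambda = 1
#' @export
cauchy_stress <- function(lambda, material) {
  if (any(lambda < 1)) stopf("cauchy_stress: lambda < 1 (compression out of scope)")
  x <- lambda^2 + 2 / lambda - 3          # I1 - 3
  dW <- 0
  for (i in 6:1) dW <- dW * x + i * material$coeffs[i]   # Horner on sum i*Ci0*x^(i-1)
  2 * (lambda^2 - 1 / lambda) * dW
}

#' Wall resistance stress
#' @param material an [artery_material]
#' @return sigma_res = cauchy_stress(lambda_res) in MPa
#' @export
resistance_stress <- function(material) cauchy_stress(material$lambda_res, material)

#' Contact detection between stent vertices and the paired arterial wall
#'
#' A stent vertex is in contact once its distance to the paired artery vertex
#' drops below the strut diameter. Flags are sticky: once a vertex makes
#' contact it stays in contact (prevents chatter at the threshold); the step
#' at which each vertex first touched is recorded.
#'
#' @param stent_pos n x 3 current stent vertex positions (mm)
#' @param artery_pos m x 3 current artery vertex positions (mm)
#' @param pairing integer vector: artery vertex index per stent vertex
#' @param d_strut contact threshold (mm); the strut diameter
#' @param prev previous contact state (or NULL at initiation)
#' @param step current step index (recorded at first contact)
#' @return list with `flag` (logical), `distance` (mm),
#'   `first_step` (integer, NA until touched)
#' @export
detect_contact <- function(stent_pos, artery_pos, pairing, d_strut,
                           prev = NULL, step = 0L) {
  if (any(pairing < 1L | pairing > nrow(artery_pos)))
    stopf("detect_contact: pairing index out of range")
  d <- row_norm(stent_pos - artery_pos[pairing, , drop = FALSE])
  new_flag <- d < d_strut
  if (is.null(prev)) {
    flag <- new_flag
    first <- ifelse(flag, step, NA_integer_)
  } else {
    flag <- prev$flag | new_flag
    first <- prev$first_step
    first[is.na(first) & flag] <- step
  }
  list(flag = flag, distance = d, first_step = first)
}

#' External (wall resistance) driving force
#'
#' Zero until contact; for contacted vertices the inward force
#' `F_ext = nu * sigma_vsl / (2 * sigma_res) * ||(N2 - N1) x (N3 - N1)|| * (-n)`,
#' where the cross-product magnitude is twice the neighbor-triangle area and
#' `sigma_vsl = cauchy_stress(lambda_cur)` is evaluated per vertex from the
#' current circumferential stretch `lambda_cur` (current / initial local
#' lumen diameter). Stretches below 1 at a contact vertex contribute zero
#' stress (with a warning). Vertices with clipped neighborhoods use their
#' mean neighbor cross-product magnitude scale of the full-degree vertices.
#'
#' @param sm stent `simplexmesh` (connectivity provider)
#' @param pos n x 3 current stent vertex positions (mm)
#' @param normals n x 3 outward unit normals
#' @param lambda_cur per-vertex circumferential stretch of the paired wall
#' @param contacts contact state from [detect_contact()]
#' @param material an [artery_material]
#' @param warn warn on lambda_cur < 1 at contact (default TRUE)
#' @return n x 3 matrix of force vectors (N), inward along -n
#' @export
external_force <- function(sm, pos, normals, lambda_cur, contacts, material,
                           warn = TRUE) {
  n <- nrow(pos)
  F <- matrix(0, n, 3L)
  idx <- which(contacts$flag)
  if (!length(idx)) return(F)
  lam <- lambda_cur[idx]
  sub <- lam < 1
  if (any(sub) && warn)
    warnf("external_force: lambda < 1 at %d contact vertices; treating stress as 0", sum(sub))
  lam[sub] <- 1
  sigma <- cauchy_stress(lam, material)

  nb <- sm$neighbors[idx, , drop = FALSE]
  full <- rowSums(!is.na(nb)) == 3L
  area2 <- rep(NA_real_, length(idx))
  if (any(full)) {
    N1 <- pos[nb[full, 1L], , drop = FALSE]
    N2 <- pos[nb[full, 2L], , drop = FALSE]
    N3 <- pos[nb[full, 3L], , drop = FALSE]
    area2[full] <- row_norm(row_cross(N2 - N1, N3 - N1))
  }
  if (any(!full)) area2[!full] <- if (any(full)) mean(area2[full]) else 0
  mag <- material$nu * sigma / (2 * material$sigma_res) * area2
  F[idx, ] <- -normals[idx, , drop = FALSE] * mag
  F
}
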