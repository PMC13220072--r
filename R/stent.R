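#' Balloon-expandable stent specification
#'
#' Device geometry and material parameters plus all derived mechanical
#' quantities, in the mm-N-MPa unit system:
#'
#' * second moment of area `I = pi * D_stn^4 / 64` (mm^4),
#' * radial rigidity `k_stn = 3 * E_stn * I / L^3` (N/mm, cantilever beam),
#' * force per unit length `F_unit = P_nom * D_stn` (N/mm),
#' * radial force `F_rf = F_unit * L` (N),
#' * inflection position `delta = L / (2 * pi * t_strut * k_stn * r_stn)`
#'   (evaluated numerically in the mm-N system exactly as written),
#' * scaling factor `chi = T * delta` (dimensionless; must lie in `[0, 1)`
#'   or the equilibrium diameter `(1 - chi) * D_stn` is non-physical).
#'
#' The balloon pressure is given in atm and converted with
#' 1 atm = 0.101325 MPa. `T` is the expansion-threshold fraction; its default
#' (0.01) keeps `chi <= 0.1` for coronary-scale devices. The strut thickness
#' default (0.08 mm) is a typical cobalt-chromium value; both are logged in
#' the run report because the equilibrium diameter depends on them.
#'
#' @param length_mm stent length L (mm)
#' @param diameter_mm target fully expanded diameter D_stn (mm)
#' @param crimped_radius_mm crimped stent radius r_stn (mm)
#' @param youngs_modulus_gpa stent Young's modulus (GPa)
#' @param poisson stent Poisson ratio (dimensionless)
#' @param pressure_atm nominal balloon pressure (atm)
#' @param strut_thickness_mm strut thickness t (mm); also the default contact
#'   threshold (a round strut's diameter equals its thickness)
#' @param threshold_T expansion-threshold fraction T (dimensionless)
#' @return object of class `stent_spec` with the inputs and the derived
#'   `I`, `k_stn`, `F_unit`, `F_rf`, `delta`, `chi`, `P_nom` (MPa),
#'   `E_stn` (MPa), `d_equilibrium` (mm)
#' @examples
#' sp <- stent_spec(34, 2.15, 0.5, 233, 0.35, 9)
#' sp$k_stn    # ~18.65 N/mm
#' sp$F_rf     # ~66.66 N
#' @export
stent_spec <- function(length_mm, diameter_mm, crimped_radius_mm,
                       youngs_modulus_gpa, poisson = 0.35, pressure_atm = 9,
                       strut_thickness_mm = 0.08, threshold_T = 0.01) {
  for (nm in c("length_mm", "diameter_mm", "crimped_radius_mm",
               "youngs_modulus_gpa", "pressure_atm", "strut_thickness_mm")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stopf("stent_spec: %s must be a positive number", nm)
  }
  if (threshold_T < 0) stopf("stent_spec: threshold_T must be >= 0")
  E_stn <- youngs_modulus_gpa * 1000          # GPa -> MPa
  P_nom <- pressure_atm * 0.101325            # atm -> MPa
  I <- pi * diameter_mm^4 / 64
  k_stn <- 3 * E_stn * I / length_mm^3
  F_unit <- P_nom * diameter_mm
  F_rf <- F_unit * length_mm
  delta <- length_mm / (2 * pi * strut_thickness_mm * k_stn * crimped_radius_mm)
  chi <- threshold_T * delta
  if (chi >= 1)
    stopf("stent_spec: chi = T * delta = %.3f >= 1 (non-physical equilibrium); lower threshold_T", chi)
  structure(list(L = length_mm, D_stn = diameter_mm, r_stn = crimped_radius_mm,
                 E_stn = E_stn, nu = poisson, P_nom = P_nom,
                 t_strut = strut_thickness_mm, threshold_T = threshold_T,
                 I = I, k_stn = k_stn, F_unit = F_unit, F_rf = F_rf,
                 delta = delta, chi = chi,
                 d_equilibrium = (1 - chi) * diameter_mm),
            class = "stent_spec")
}

#' @export
print.stent_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<stent_spec> L = %.2f mm, D = %.2f mm, r_crimped = %.2f mm\n",
    "  E = %.0f MPa, nu = %.2f, P_nom = %.6f MPa, t_strut = %.3f mm, T = %.4f\n",
    "  derived: k_stn = %.4f N/mm, F_unit = %.4f N/mm, F_rf = %.3f N\n",
    "           delta = %.4f, chi = %.5f, equilibrium diameter = %.4f mm\n"),
    x$L, x$D_stn, x$r_stn, x$E_stn, x$nu, x$P_nom, x$t_strut, x$threshold_T,
    x$k_stn, x$F_unit, x$F_rf, x$delta, x$chi, x$d_equilibrium))
  invisible(x)
}

#' Stent radial rigidity (beam formula)
#' @param spec a [stent_spec]
#' @return k_stn = 3 E I / L^3 in N/mm
#' @export
radial_rigidity <- function(spec) spec$k_stn

#' Stent radial force from nominal pressure
#' @param spec a [stent_spec]
#' @return list with `F_unit` = P_nom * D_stn (N/mm) and `F_rf` = F_unit * L (N)
#' @export
radial_force <- function(spec) list(F_unit = spec$F_unit, F_rf = spec$F_rf)

#' Normalized inflection position and scaling factor
#' @param spec a [stent_spec]
#' @return list with `delta` = L / (2 pi t k_stn r_stn) and `chi` = T * delta
#' @export
inflection_chi <- function(spec) list(delta = spec$delta, chi = spec$chi)

#' Internal (expansion) driving force of the stent
#'
#' Linear radial force-displacement law: at each free stent vertex,
#' `F_int = k_stn / (F_rf * D_stn) * ((1 - chi) * D_stn - dP) * n`,
#' where `dP` is the local lumen diameter of the vertex (twice its radial
#' distance to the centerline) and `n` the outward unit normal. The force is
#' outward while the vertex is under-expanded, zero at the equilibrium
#' diameter `(1 - chi) * D_stn` and inward beyond it. Constrained vertices
#' receive exactly zero.
#'
#' @param local_diameter numeric vector, per-vertex local diameter |dP| (mm)
#' @param normals n x 3 outward unit normals
#' @param spec a [stent_spec]
#' @param constrained logical vector (zero force where TRUE)
#' @return n x 3 matrix of force vectors (N)
#' @export
internal_force <- function(local_diameter, normals, spec, constrained = NULL) {
  if (anyNA(local_diameter)) stopf("internal_force: undefined local diameter (NA)")
  mag <- spec$k_stn / (spec$F_rf * spec$D_stn) *
    ((1 - spec$chi) * spec$D_stn - local_diameter)
  F <- rbind3(normals) * mag
  if (!is.null(constrained)) F[constrained, ] <- 0
  F
}

#' Generate the crimped stent simplex mesh by inward centerline projection
#'
#' Every free artery simplex vertex whose axial station lies in the stented
#' segment `[s0, s0 + L]` spawns a stent vertex at radial distance `r_stn`
#' from the centerline, along that vertex's own radial direction. Simplex
#' connectivity is copied from the artery mesh (restricted to the segment),
#' which yields a one-to-one stent-artery vertex pairing. Stent vertices
#' whose copied neighborhood was clipped at the segment ends keep degree < 3;
#' they remain free and fall back to their radial direction as the normal
#' during dynamics (the device expands along its whole length).
#'
#' A warning is issued when `r_stn` meets or exceeds the local lumen radius
#' anywhere (pre-loaded contact: the crimped device already touches a
#' narrowed wall at initiation).
#'
#' @param artery a `simplexmesh` of the luminal surface
#' @param cl a [centerline]
#' @param spec a [stent_spec]
#' @param s0 arc-length start of the stented segment (mm); default centers
#'   the stent on the centerline
#' @return list with `stent` (a `simplexmesh`), `pairing` (integer vector:
#'   artery vertex index per stent vertex) and `s0`
#' @export
build_stent_mesh <- function(artery, cl, spec, s0 = NULL) {
  total <- max(cl$s)
  if (is.null(s0)) s0 <- (total - spec$L) / 2
  if (s0 < -1e-9 || s0 + spec$L > total + 1e-9)
    stopf("stent segment [%.2f, %.2f] exceeds centerline arc length %.2f mm",
          s0, s0 + spec$L, total)
  rd <- radial_decomp(artery$vertices, cl)
  sel <- which(rd$s >= s0 & rd$s <= s0 + spec$L & !artery$constrained)
  if (length(sel) < 4L) stopf("stented segment contains too few artery vertices (%d)", length(sel))
  if (any(rd$r[sel] <= spec$r_stn))
    warnf("crimped stent radius %.2f mm meets/exceeds the lumen radius at %d vertices: pre-loaded contact",
          spec$r_stn, sum(rd$r[sel] <= spec$r_stn))
  near <- cl$points[rd$idx[sel], , drop = FALSE]
  verts <- near + rd$dir[sel, , drop = FALSE] * spec$r_stn
  # remap copied connectivity into the selected subset
  remap <- rep(NA_integer_, nrow(artery$vertices))
  remap[sel] <- seq_along(sel)
  nb <- artery$neighbors[sel, , drop = FALSE]
  nb[] <- remap[nb]                          # NA where neighbor left the segment
  # polygonal faces wholly inside the segment survive (needed for metrics/export)
  faces <- lapply(artery$faces, function(cyc) {
    mapped <- remap[cyc]
    if (anyNA(mapped)) NULL else mapped
  })
  faces <- faces[!vapply(faces, is.null, logical(1))]
  stent <- structure(list(vertices = verts,
                          neighbors = nb,
                          constrained = rep(FALSE, length(sel)),
                          source_face = artery$source_face[sel],
                          faces = faces),
                     class = "simplexmesh")
  list(stent = stent, pairing = sel, s0 = s0)
}
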