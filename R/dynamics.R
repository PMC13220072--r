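#' Dynamics configuration for damped explicit vertex integration
#'
#' Vertex positions evolve by the damped centered-difference rule
#' `P(t+1) = P(t) + (1 - gamma) * (P(t) - P(t-1)) + alpha * F_int + beta * F_ext`.
#' The lumped vertex mass and time step are absorbed into the force weights
#' `alpha` and `beta` (mm per unit force). Convergence is displacement-based:
#' the run stops once the maximum per-vertex displacement stays below
#' `tol_disp` for `window` consecutive steps.
#'
#' Defaults: `gamma = 0.65` (classical simplex-mesh practice),
#' `alpha = beta = 0.01` mm per unit force, `max_steps = 5000`,
#' `tol_disp = 1e-5` mm, `window = 10`.
#'
#' @param gamma damping coefficient, in (0, 1]
#' @param alpha,beta force weight coefficients (mm per unit force), > 0
#' @param max_steps maximum number of steps
#' @param tol_disp convergence displacement threshold (mm)
#' @param window number of consecutive quiet steps required
#' @return object of class `dynamics_config`
#' @export
dynamics_config <- function(gamma = 0.65, alpha = 0.01, beta = 0.01,
                            max_steps = 5000L, tol_disp = 1e-5, window = 10L) {
  if (gamma <= 0 || gamma > 1) stopf("dynamics_config: gamma must lie in (0, 1]")
  if (alpha <= 0 || beta <= 0) stopf("dynamics_config: alpha and beta must be > 0")
  if (tol_disp <= 0) stopf("dynamics_config: tol_disp must be > 0")
  structure(list(gamma = gamma, alpha = alpha, beta = beta,
                 max_steps = as.integer(max_steps), tol_disp = tol_disp,
                 window = as.integer(window)),
            class = "dynamics_config")
}

#' One damped centered-difference step
#'
#' Advances free vertices by
#' `P(t+1) = P(t) + (1 - gamma) * (P(t) - P(t-1)) + alpha * F_int + beta * F_ext`;
#' constrained vertices do not move.
#'
#' @param state list with `P_curr`, `P_prev` (n x 3 mm), `constrained`
#'   (logical), `step` (integer)
#' @param F_int,F_ext n x 3 force matrices evaluated at the current positions
#' @param config a [dynamics_config]
#' @return updated state (with `max_disp` of the step attached)
#' @export
sdm_step <- function(state, F_int, F_ext, config) {
  P_new <- state$P_curr +
    (1 - config$gamma) * (state$P_curr - state$P_prev) +
    config$alpha * F_int + config$beta * F_ext
  P_new[state$constrained, ] <- state$P_curr[state$constrained, , drop = FALSE]
  if (!all(is.finite(P_new))) {
    bad <- which(!is.finite(rowSums(P_new)))[1L]
    stopf("divergence at step %d: non-finite position at vertex %d", state$step + 1L, bad)
  }
  disp <- row_norm(P_new - state$P_curr)
  list(P_curr = P_new, P_prev = state$P_curr, constrained = state$constrained,
       step = state$step + 1L, max_disp = max(disp))
}

# outward normals of a (possibly clipped) stent simplex mesh: wedge-formula
# normals flipped to point away from the axis; radial fallback at clipped vertices
stent_normals <- function(sm, pos, radial_dir) {
  n <- nrow(pos)
  normals <- radial_dir
  nb <- sm$neighbors
  full <- rowSums(!is.na(nb)) == 3L
  if (any(full)) {
    nr <- vertex_normal(pos[nb[full, 1L], , drop = FALSE],
                        pos[nb[full, 2L], , drop = FALSE],
                        pos[nb[full, 3L], , drop = FALSE])
    nr <- rbind3(nr)
    flip <- row_dot(nr, radial_dir[full, , drop = FALSE]) < 0
    nr[flip, ] <- -nr[flip, , drop = FALSE]
    normals[full, ] <- nr
  }
  normals
}

#' Run a stent deployment simulation
#'
#' Iterates force evaluation and the damped centered-difference update until
#' displacement convergence or `max_steps`. The internal expansion force acts
#' from step one; the wall-resistance force is activated per vertex on
#' contact. After contact, the paired artery vertex is kinematically slaved
#' to its stent vertex: it is pushed outward along its own radial direction
#' so the wall never lags behind the strut (it is never pulled inward).
#'
#' @param artery artery `simplexmesh` (constrained boundary vertices fixed)
#' @param stent_build result of [build_stent_mesh()]
#' @param cl a [centerline]
#' @param spec a [stent_spec]
#' @param material an [artery_material]; `NULL` simulates free expansion
#'   (no wall, no contact)
#' @param config a [dynamics_config]
#' @param d_strut contact threshold (mm); defaults to the strut thickness
#' @return list with `converged`, `steps`, `first_contact_step` (NA if no
#'   contact), `history` (data.frame: step, F_int_total, F_ext_total,
#'   n_contacts, max_disp), `stent` and `artery` (deformed meshes),
#'   `stent_diameter` (per-vertex final local diameter, mm)
#' @export
sdm_run <- function(artery, stent_build, cl, spec, material = NULL,
                    config = dynamics_config(), d_strut = spec$t_strut) {
  stent <- stent_build$stent
  pairing <- stent_build$pairing
  n_st <- nrow(stent$vertices)

  # artery vertices move only radially when slaved: cache their decomposition
  a_rd <- radial_decomp(artery$vertices, cl)
  a_near <- cl$points[a_rd$idx, , drop = FALSE]
  a_r0 <- a_rd$r
  a_r <- a_rd$r
  a_dir <- a_rd$dir

  state <- list(P_curr = stent$vertices, P_prev = stent$vertices,
                constrained = stent$constrained, step = 0L)
  contacts <- NULL
  hist_n <- config$max_steps
  H <- matrix(NA_real_, hist_n, 5L,
              dimnames = list(NULL, c("step", "F_int_total", "F_ext_total",
                                      "n_contacts", "max_disp")))
  quiet <- 0L
  converged <- FALSE
  steps <- 0L

  for (tstep in seq_len(config$max_steps)) {
    rd <- radial_decomp(state$P_curr, cl)
    normals <- stent_normals(stent, state$P_curr, rd$dir)
    F_int <- internal_force(2 * rd$r, normals, spec, state$constrained)

    if (!is.null(material)) {
      artery_pos <- a_near + a_dir * a_r
      contacts <- detect_contact(state$P_curr, artery_pos, pairing, d_strut,
                                 prev = contacts, step = tstep - 1L)
      lambda_cur <- a_r[pairing] / a_r0[pairing]
      F_ext <- external_force(stent, state$P_curr, normals, lambda_cur,
                              contacts, material, warn = FALSE)
      n_contacts <- sum(contacts$flag)
    } else {
      F_ext <- matrix(0, n_st, 3L)
      n_contacts <- 0L
    }

    state <- sdm_step(state, F_int, F_ext, config)

    if (!is.null(material) && any(contacts$flag)) {
      # slave contacted wall vertices outward to the strut radius
      idx <- which(contacts$flag)
      s_r <- radial_decomp(state$P_curr[idx, , drop = FALSE], cl)$r
      ai <- pairing[idx]
      a_r[ai] <- pmax(a_r[ai], s_r)
    }

    H[tstep, ] <- c(tstep, sum(row_norm(F_int)), sum(row_norm(F_ext)),
                    n_contacts, state$max_disp)
    steps <- tstep
    quiet <- if (state$max_disp < config$tol_disp) quiet + 1L else 0L
    if (quiet >= config$window) { converged <- TRUE; break }
  }

  stent$vertices <- state$P_curr
  artery_out <- artery
  moved <- which(a_r != a_r0)
  artery_out$vertices[moved, ] <- a_near[moved, , drop = FALSE] +
    a_dir[moved, , drop = FALSE] * a_r[moved]

  first_contact <- if (!is.null(contacts) && any(!is.na(contacts$first_step)))
    min(contacts$first_step, na.rm = TRUE) else NA_integer_

  list(converged = converged, steps = steps,
       first_contact_step = first_contact,
       history = as.data.frame(H[seq_len(steps), , drop = FALSE]),
       stent = stent, artery = artery_out,
       stent_diameter = 2 * radial_decomp(state$P_curr, cl)$r,
       contacts = contacts)
}
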