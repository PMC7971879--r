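## Subcellular-element mechanics: force wrappers around the compiled
## kernels, overdamped noisy position updates, division by element
## splitting, and the cleavage schedule.

## Stage-scaled Morse parameters: equilibrium distances follow the element
## spacing, which shrinks with the cell radius as the embryo cleaves.
force_field <- function(params, n_cells) {
  sp <- element_spacing(params, n_cells)
  ## Morse range parameters are given in inverse element spacings so the
  ## core width shrinks with the cells as the embryo cleaves
  list(re_intra = params$re_intra_factor * sp,
       cut_intra = params$cutoff_factor * params$re_intra_factor * sp,
       re_inter = params$re_inter_factor * sp,
       cut_inter = params$cutoff_factor * params$re_inter_factor * sp,
       a_intra = params$a_intra / sp,
       a_inter = params$a_inter / sp)
}

ADHESION_TYPES <- c("DP", "Nanog+", "Gata6+", "DN", "TE", "unspecified")

## Per-cell adhesion type: TE lineage wins, otherwise the Nanog/Gata6 fate.
adhesion_type_of <- function(state, fates = NULL) {
  if (is.null(fates)) fates <- classify_fate(state$genes, state$params)
  ifelse(state$lineage == "TE", "TE",
         ifelse(state$lineage == "unspecified" &
                  n_cells(state) < 32, "unspecified", fates))
}

## Expand an adhesion_matrix (or NULL = uniform) to the full type set.
build_alpha <- function(adhesion, params) {
  al <- matrix(params$alpha_baseline, length(ADHESION_TYPES),
               length(ADHESION_TYPES),
               dimnames = list(ADHESION_TYPES, ADHESION_TYPES))
  if (!is.null(adhesion)) {
    tt <- adhesion$cell_types
    unknown <- setdiff(tt, ADHESION_TYPES)
    if (length(unknown))
      stop("adhesion matrix has unknown cell type(s): ",
           paste(unknown, collapse = ", "))
    al[tt, tt] <- adhesion$AS
  }
  al
}

#' Intracellular element forces
#'
#' Morse pair forces between same-cell elements (negative gradient of the
#' summed pair potential, pairs within the cutoff). Coincident elements are
#' regularized by a minimum pair distance.
#'
#' @param state an `embryo_state`.
#' @param params parameter set (defaults to the state's own).
#' @return E x 3 matrix of forces.
#' @export
intra_forces <- function(state, params = state$params) {
  ff <- force_field(params, n_cells(state))
  dummy <- matrix(1, 1, 1)
  cpp_pair_forces(state$pos, state$element_cell - 1L,
                  rep(0L, n_cells(state)), dummy,
                  params$de_intra, ff$a_intra, ff$re_intra, ff$cut_intra,
                  params$de_inter, ff$a_inter, ff$re_inter, ff$cut_inter,
                  params$min_pair_dist, TRUE, FALSE)
}

#' Intercellular element forces with selective adhesion
#'
#' Morse pair forces between elements of different cells. Only the
#' attractive term is scaled by the adhesion score of the (unordered) pair
#' of cell types; the repulsive core is adhesion-independent, so low
#' adhesion cannot cause interpenetration.
#'
#' @param state an `embryo_state`.
#' @param params parameter set.
#' @param adhesion an `adhesion_matrix`, or `NULL` for the uniform
#'   baseline.
#' @param fates optional precomputed fate labels (from [classify_fate()]).
#' @return E x 3 matrix of forces.
#' @export
inter_forces <- function(state, params = state$params, adhesion = NULL,
                         fates = NULL) {
  ff <- force_field(params, n_cells(state))
  al <- build_alpha(adhesion, params)
  ty <- match(adhesion_type_of(state, fates), ADHESION_TYPES) - 1L
  cpp_pair_forces(state$pos, state$element_cell - 1L, ty, al,
                  params$de_intra, ff$a_intra, ff$re_intra, ff$cut_intra,
                  params$de_inter, ff$a_inter, ff$re_inter, ff$cut_inter,
                  params$min_pair_dist, FALSE, TRUE)
}

## Cavity radius at the state's current time: zero before the cavity onset
## (recorded when the embryo reaches 32 cells), then a linear ramp to the
## configured maximum over three cleavage intervals.
cavity_radius_at <- function(state, params = state$params) {
  t0 <- state$cavity_t0
  if (is.na(t0) || state$time <= t0) return(0)
  min(params$cavity_max_radius,
      params$cavity_max_radius * (state$time - t0) /
        (3 * params$stage_duration))
}

#' External forces: zona pellucida confinement and cavity expansion
#'
#' Elements beyond the zona radius feel a linear restoring force toward
#' the origin; after cavity onset, elements inside the growing cavity
#' sphere (anchored off-center at the lower pole) are pushed radially out
#' of it, which sweeps the ICM against the opposite pole of the TE shell.
#'
#' @param state an `embryo_state`.
#' @param params parameter set.
#' @param cavity_r cavity radius; defaults to the state's ramped value.
#' @return E x 3 matrix of forces.
#' @export
external_forces <- function(state, params = state$params,
                            cavity_r = cavity_radius_at(state, params)) {
  cz <- params$cavity_center_z
  cpp_external_forces(state$pos, params$zona_radius, params$zona_stiffness,
                      0, 0, cz, cavity_r, params$cavity_stiffness)
}

#' Total force on every element
#' @inheritParams inter_forces
#' @param cavity_r cavity radius (defaults to the ramped schedule).
#' @return E x 3 matrix.
#' @export
total_forces <- function(state, params = state$params, adhesion = NULL,
                         fates = NULL,
                         cavity_r = cavity_radius_at(state, params)) {
  intra_forces(state, params) +
    inter_forces(state, params, adhesion, fates) +
    external_forces(state, params, cavity_r)
}

#' Total potential energy of a configuration
#'
#' Pair potentials (intra + adhesion-scaled inter) plus the external
#' harmonic wells, consistent with the force routines; used by the
#' energy-bookkeeping tests of zero-noise relaxation.
#'
#' @inheritParams inter_forces
#' @param cavity_r cavity radius.
#' @return scalar energy.
#' @export
potential_energy <- function(state, params = state$params, adhesion = NULL,
                             fates = NULL, cavity_r = 0) {
  ff <- force_field(params, n_cells(state))
  al <- build_alpha(adhesion, params)
  ty <- match(adhesion_type_of(state, fates), ADHESION_TYPES) - 1L
  cpp_potential_energy(state$pos, state$element_cell - 1L, ty, al,
                       params$de_intra, ff$a_intra, ff$re_intra,
                       ff$cut_intra, params$de_inter, ff$a_inter,
                       ff$re_inter, ff$cut_inter, params$min_pair_dist,
                       params$zona_radius, params$zona_stiffness,
                       0, 0, params$cavity_center_z, cavity_r,
                       params$cavity_stiffness)
}

#' Overdamped noisy position update
#'
#' `r <- r + (F / mobility) dt + sigma_move * noise_scale * sqrt(dt) * eta`
#' per coordinate, with standard normal `eta`. `noise_scale` multiplies
#' the baseline movement-noise amplitude (0.1 and 5 reproduce the
#' low/high random-movement experiments).
#'
#' @param state an `embryo_state`.
#' @param forces E x 3 force matrix.
#' @param dt timestep (> 0).
#' @param params parameter set.
#' @param noise_scale multiplier on `sigma_move`.
#' @return the state with updated positions and time unchanged.
#' @export
step_positions <- function(state, forces, dt, params = state$params,
                           noise_scale = params$move_noise_scale) {
  if (dt <= 0) stop("step_positions: dt must be > 0")
  bad <- which(!is.finite(rowSums(forces)))
  if (length(bad))
    stop("numerical instability: non-finite force on element ", bad[1],
         " (cell ", state$element_cell[bad[1]], ")")
  disp <- forces / params$mobility * dt
  ## cap the deterministic displacement per step (steep Morse cores after
  ## division replenishment would otherwise fling elements apart)
  cap <- params$max_disp_factor * element_spacing(params, n_cells(state))
  dn <- sqrt(rowSums(disp^2))
  over <- dn > cap
  if (any(over)) disp[over, ] <- disp[over, ] * (cap / dn[over])
  upd <- state$pos + disp
  amp <- params$sigma_move * noise_scale
  if (amp > 0)
    upd <- upd + amp * sqrt(dt) *
      matrix(stats::rnorm(length(upd)), nrow(upd), 3)
  state$pos <- upd
  state
}

#' Divide one cell by splitting its elements
#'
#' Partitions the mother's elements by a random plane through its
#' centroid (median-split along the plane normal, so both daughters are
#' nonempty), replenishes each daughter back to `elements_per_cell` by
#' duplicating its own elements with a small jitter, and copies the
#' mother's gene state, lineage and birth bookkeeping to both daughters.
#' Daughters' division times are left unscheduled (`Inf`); the driver
#' assigns them per the cleavage schedule once the round completes.
#'
#' @param state an `embryo_state`.
#' @param cell_id the mother cell.
#' @return the state with one extra cell.
#' @export
divide_cell <- function(state, cell_id) {
  ids <- elements_of(state, cell_id)
  if (length(ids) < 2)
    stop("cannot divide cell ", cell_id, ": fewer than 2 elements")
  p <- state$params
  cen <- colMeans(state$pos[ids, , drop = FALSE])
  nrm <- stats::rnorm(3)
  nrm <- nrm / sqrt(sum(nrm^2))
  proj <- as.numeric(state$pos[ids, , drop = FALSE] %*% nrm -
                       sum(cen * nrm))
  ord <- order(proj)
  half <- length(ids) %/% 2
  keep <- ids[ord[seq_len(half)]]            # daughter B (new id)
  new_id <- n_cells(state) + 1L
  state$element_cell[keep] <- new_id
  state$genes <- rbind(state$genes, state$genes[cell_id, , drop = FALSE])
  state$lineage <- c(state$lineage, state$lineage[cell_id])
  state$birth_time[cell_id] <- state$time
  state$birth_time <- c(state$birth_time, state$time)
  state$division_due[cell_id] <- Inf
  state$division_due <- c(state$division_due, Inf)
  ## replenish both daughters to the target element count
  jit <- p$daughter_jitter * cell_radius(p, n_cells(state))
  for (cid in c(cell_id, new_id)) {
    own <- which(state$element_cell == cid)
    deficit <- p$elements_per_cell - length(own)
    if (deficit > 0) {
      src <- own[sample.int(length(own), deficit, replace = TRUE)]
      newpos <- state$pos[src, , drop = FALSE] +
        matrix(stats::rnorm(deficit * 3, sd = jit), deficit, 3)
      state$pos <- rbind(state$pos, newpos)
      state$element_cell <- c(state$element_cell, rep(cid, deficit))
    }
  }
  state
}

#' Cells due to divide
#'
#' Returns the ids of cells whose scheduled division time has passed.
#' Synchronous rounds (all cells share one due time) run up to the 32-cell
#' stage; the 32-to-64 and 64-to-128 rounds draw per-cell due times
#' uniformly in the configured window; no divisions occur at or past 128
#' cells.
#'
#' @param state an `embryo_state`.
#' @param params parameter set.
#' @return integer vector of cell ids (possibly empty).
#' @export
division_scheduler <- function(state, params = state$params) {
  if (n_cells(state) >= 128) return(integer(0))
  which(state$division_due <= state$time + 1e-12)
}

#' Assign division times after a completed round
#'
#' Under 32 cells, every cell gets the same due time one cleavage interval
#' ahead (synchronous rounds). At 32 and 64 cells, each cell draws an
#' independent uniform due time in the configured window. At 128 cells,
#' no further divisions.
#'
#' @param state an `embryo_state`.
#' @param params parameter set.
#' @return the state with `division_due` filled in.
#' @export
schedule_divisions <- function(state, params = state$params) {
  n <- n_cells(state)
  state$division_due <- if (n < 32) {
    rep(state$time + params$stage_duration, n)
  } else if (n < 128) {
    unsched <- !is.finite(state$division_due)
    due <- state$division_due
    due[unsched] <- state$time + stats::runif(sum(unsched),
                                              params$div_window_start,
                                              params$div_window_end)
    due
  } else {
    rep(Inf, n)
  }
  state
}

#' Per-cell contact fraction
#'
#' Fraction of a cell's elements that have at least one element of a
#' different cell within a short contact range (a multiple of the element
#' spacing). Interior cells approach 1; cells with free surface score
#' lower. Drives the Oct4/Cdx2 toggle bias.
#'
#' @param state an `embryo_state`.
#' @param params parameter set.
#' @return numeric vector in `[0, 1]`, one entry per cell.
#' @export
contact_fractions <- function(state, params = state$params) {
  rcut <- params$contact_elem_factor * element_spacing(params, n_cells(state))
  cpp_contact_fraction(state$pos, state$element_cell - 1L, n_cells(state),
                       rcut)
}
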