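## Gene-regulatory dynamics: per-cell stochastic Nanog/Gata6/Fgfr2/Fgf4/Erk
## system, neighbor-perceived Fgf4, the Fgf modulation schedule, and the
## pre-blastocyst Oct4/Cdx2 contact toggle.

GENE_NAMES <- c("Nan", "Gat", "Fr", "Fs", "Erk", "Oct4", "Cdx2")

#' Deterministic drift of the Nanog/Gata6/Fgfr2/Fgf4/Erk system
#'
#' Evaluates the drift (deterministic time-derivative) of the five-species
#' regulatory system in each cell:
#' \itemize{
#'   \item Nanog: basal synthesis, Erk-mediated inhibition (gated by the
#'     Fgf control parameter `eps_t`), cooperative self-amplification
#'     inhibited by Gata6, linear degradation;
#'   \item Gata6: basal synthesis, Erk-mediated promotion (gated by
#'     `eps_t`), self-amplification inhibited by Nanog, degradation;
#'   \item Fgfr2: synthesis repressed by Nanog and promoted by Gata6;
#'   \item Fgf4: synthesis activated by Nanog;
#'   \item Erk: activation proportional to Fgfr2 and to a saturating
#'     function of perceived Fgf4, with a saturating (1 - Erk) ceiling and
#'     Michaelis-Menten deactivation, so Erk stays in [0, 1] without noise.
#' }
#'
#' @param g numeric matrix (cells x species) with columns `Nan`, `Gat`,
#'   `Fr`, `Fs`, `Erk` (extra columns are ignored), or a named vector for a
#'   single cell. All concentrations must be nonnegative.
#' @param Fp perceived Fgf4 per cell (recycled scalar or length-n vector).
#' @param eps_t Fgf modulation parameter (scalar in `[0, 1]` typically).
#' @param params a `blastosem_params` list.
#' @return matrix (cells x 5) of drifts with columns named as the species.
#' @export
grn_derivatives <- function(g, Fp, eps_t, params) {
  p <- params
  if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
  Nan <- g[, "Nan"]; Gat <- g[, "Gat"]; Fr <- g[, "Fr"]
  Fs <- g[, "Fs"]; Erk <- g[, "Erk"]
  if (any(c(Nan, Gat, Fr, Fs, Erk) < 0))
    stop("grn_derivatives: negative concentration input")
  eE <- eps_t * Erk
  dNan <- p$vsn0 +
    p$vsn1 * p$Kin1^p$u / (p$Kin1^p$u + eE^p$u) +
    p$vsn2 * (Nan^p$v / (p$Kan^p$v + Nan^p$v)) *
      (p$Kin2^p$w / (p$Kin2^p$w + Gat^p$w)) -
    p$kN * Nan
  dGat <- p$vsg0 +
    p$vsg1 * eE^p$r / (p$Kag1^p$r + eE^p$r) +
    p$vsg2 * (Gat^p$s / (p$Kag2^p$s + Gat^p$s)) *
      (p$Kig^p$q / (p$Kig^p$q + Nan^p$q)) -
    p$kG * Gat
  dFr <- p$vsfr1 * p$Kifr^p$x / (p$Kifr^p$x + Nan^p$x) +
    p$vsfr2 * Gat^p$y / (p$Kafr^p$y + Gat^p$y) -
    p$kFr * Fr
  dFs <- p$vsf * Nan^p$z / (p$Kaf^p$z + Nan^p$z) - p$kFs * Fs
  dErk <- p$va * Fr * (Fp / (p$Kd + Fp)) *
    ((1 - Erk) / (p$Ka + 1 - Erk)) -
    p$kErk * Erk / (p$Ki + Erk)
  cbind(Nan = dNan, Gat = dGat, Fr = dFr, Fs = dFs, Erk = dErk)
}

#' Perceived Fgf4 from neighboring cells
#'
#' For each cell i, averages the (noisy) secreted Fgf4 of its neighbors:
#' `Fp_i = sum_{j in N(i)} (1 + gamma_j) Fs_j / N_j`, with `N_j` the number
#' of neighbors of the *emitting* cell j and `gamma_j ~ N(0, sigma_gamma^2)`
#' a per-cell perception noise; `(1 + gamma_j)` is clamped at 0 so the flux
#' stays nonnegative. Cells without neighbors perceive 0.
#'
#' @param state an `embryo_state`.
#' @param params a `blastosem_params` list.
#' @param sigma_gamma overrides the perception-noise sd (default from
#'   `params`; use 0 for the deterministic signal).
#' @param subset optional cell indices; when given, only these cells emit
#'   and perceive (used to confine signaling to the ICM after the TE/ICM
#'   decision). Other cells receive 0.
#' @return numeric vector of perceived Fgf4, one entry per cell.
#' @export
perceived_fgf4 <- function(state, params, sigma_gamma = params$sigma_gamma,
                           subset = NULL) {
  n <- n_cells(state)
  nb <- neighbor_list(state, params)
  if (!is.null(subset)) {
    ## signaling restricted to a subpopulation (the ICM after the TE/ICM
    ## decision): non-members neither emit nor perceive
    nb <- lapply(seq_len(n), function(i)
      if (i %in% subset) intersect(nb[[i]], subset) else integer(0))
  }
  n_nb <- lengths(nb)
  Fs <- state$genes[, "Fs"]
  gam <- if (sigma_gamma > 0) stats::rnorm(n, 0, sigma_gamma) else numeric(n)
  flux <- pmax(1 + gam, 0) * Fs / pmax(n_nb, 1)
  unname(vapply(nb, function(js) if (length(js)) sum(flux[js]) else 0,
                numeric(1)))
}

#' Fgf modulation parameter for a given stage
#'
#' Piecewise-constant schedule for the control parameter gating the effect
#' of Fgf/Erk signaling on Nanog and Gata6: `epsilon_on` while
#' `on_stage <= stage < off_stage`, `epsilon_off` otherwise. Stages are
#' cell-count stages (1, 2, ..., 128); `off_stage = Inf` encodes signaling
#' that never attenuates.
#'
#' @param stage integer cell-count stage.
#' @param schedule list with `on_stage`, `off_stage`, `epsilon_on`,
#'   `epsilon_off` (an `fgf_schedule`).
#' @return scalar epsilon_t.
#' @export
epsilon_t <- function(stage, schedule) {
  if (stage >= schedule$on_stage &&
      (!is.finite(schedule$off_stage) || stage < schedule$off_stage))
    schedule$epsilon_on
  else
    schedule$epsilon_off
}

#' Construct an Fgf signaling schedule
#'
#' @param on_stage cell-count stage at which Fgf regulation activates.
#' @param off_stage stage at which it attenuates (`Inf` = never).
#' @param epsilon_on,epsilon_off values of the control parameter in the
#'   active / attenuated regime.
#' @return an `fgf_schedule` list.
#' @export
fgf_schedule <- function(on_stage = 1, off_stage = 128,
                         epsilon_on = 1, epsilon_off = 0) {
  if (is.finite(off_stage) && on_stage >= off_stage)
    stop("fgf_schedule: on_stage must be < off_stage")
  if (epsilon_off > epsilon_on)
    stop("fgf_schedule: epsilon_off must be <= epsilon_on")
  structure(list(on_stage = on_stage, off_stage = off_stage,
                 epsilon_on = epsilon_on, epsilon_off = epsilon_off),
            class = "fgf_schedule")
}

#' Euler-Maruyama update of the gene states
#'
#' Advances all cells' (Nan, Gat, Fr, Fs, Erk) by one step of the
#' stochastic system: `X <- X + drift dt + sigma_X X sqrt(dt) eta` with
#' independent standard normal `eta` per species and cell (multiplicative
#' noise), then clamps at 0. With all noise amplitudes zero this reduces to
#' one forward-Euler step of [grn_derivatives()].
#'
#' @param genes cells x species matrix (columns `Nan`..`Erk`; further
#'   columns pass through unchanged).
#' @param Fp perceived Fgf4 per cell.
#' @param eps_t Fgf modulation parameter.
#' @param dt timestep (> 0).
#' @param params a `blastosem_params` list; the per-species amplitudes are
#'   jointly scaled by `params$gene_noise_scale`.
#' @return updated gene matrix.
#' @export
step_genes <- function(genes, Fp, eps_t, dt, params) {
  if (dt <= 0) stop("step_genes: dt must be > 0")
  d <- grn_derivatives(genes, Fp, eps_t, params)
  sig <- params$gene_noise_scale *
    c(params$sigmaN, params$sigmaG, params$sigmaFr, params$sigmaFs,
      params$sigmaErk)
  n <- nrow(d)
  upd <- genes[, GENE_NAMES[1:5], drop = FALSE] + d * dt
  if (any(sig > 0)) {
    eta <- matrix(stats::rnorm(n * 5), n, 5)
    upd <- upd + sweep(eta, 2, sig, `*`) *
      genes[, GENE_NAMES[1:5], drop = FALSE] * sqrt(dt)
  }
  genes[, GENE_NAMES[1:5]] <- pmax(upd, 0)
  genes
}

#' Oct4/Cdx2 contact-modulated toggle (TE/ICM specification)
#'
#' Mutual antagonism with self-activation for the first lineage decision:
#' each factor has a basal synthesis biased by cell contact (interior
#' exposure favors Oct4, exterior exposure favors Cdx2), a cooperative
#' self-activation term repressed by the antagonist, and linear decay. The
#' pair is bistable; at the 32-cell stage cells are classified TE when
#' Cdx2 > Oct4 and ICM otherwise.
#'
#' @param g cells x species matrix containing `Oct4` and `Cdx2` columns (a
#'   full gene matrix works; other columns pass through).
#' @param contact_fraction per-cell fraction in `[0, 1]` of elements
#'   contacting other cells (1 = fully interior).
#' @param dt timestep.
#' @param params a `blastosem_params` list.
#' @param noise logical; include multiplicative noise (amplitude
#'   `oc_sigma`).
#' @return updated matrix.
#' @export
te_icm_step <- function(g, contact_fraction, dt, params, noise = TRUE) {
  p <- params
  if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
  stopifnot(all(contact_fraction >= 0 & contact_fraction <= 1))
  O <- g[, "Oct4"]; C <- g[, "Cdx2"]
  ## smooth contact bias centered at oc_contact_mid
  bias <- 1 / (1 + exp(-(contact_fraction - p$oc_contact_mid) / 0.08))
  hillO <- O^p$oc_n / (p$oc_K^p$oc_n + O^p$oc_n)
  hillC <- C^p$oc_n / (p$oc_K^p$oc_n + C^p$oc_n)
  repO <- p$oc_Kx^p$oc_n / (p$oc_Kx^p$oc_n + C^p$oc_n)
  repC <- p$oc_Kx^p$oc_n / (p$oc_Kx^p$oc_n + O^p$oc_n)
  dO <- p$oc_basal + p$oc_contact_gain * bias + p$oc_self * hillO * repO -
    p$oc_k * O
  dC <- p$oc_basal + p$oc_contact_gain * (1 - bias) +
    p$oc_self * hillC * repC - p$oc_k * C
  O2 <- O + dO * dt
  C2 <- C + dC * dt
  if (noise && p$oc_sigma > 0) {
    n <- length(O)
    O2 <- O2 + p$oc_sigma * O * sqrt(dt) * stats::rnorm(n)
    C2 <- C2 + p$oc_sigma * C * sqrt(dt) * stats::rnorm(n)
  }
  g[, "Oct4"] <- pmax(O2, 0)
  g[, "Cdx2"] <- pmax(C2, 0)
  g
}
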