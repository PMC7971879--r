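#' Default model parameters
#'
#' Builds the full parameter set for the multiscale blastocyst model: rate,
#' Hill and noise constants of the Nanog/Gata6/Fgfr2/Fgf4/Erk regulatory
#' system, the Oct4/Cdx2 contact toggle, the Fgf-signaling schedule, and all
#' mechanics constants of the subcellular-element model (Morse potentials,
#' zona pellucida confinement, blastocoel cavity, division schedule).
#'
#' All quantities are non-dimensional. The unit of length is the zona
#' pellucida radius; element interaction ranges and the cell-cell contact
#' cutoff are expressed as multiples of the current cell radius, which
#' shrinks by 2^(1/3) at each cleavage round because cleavage conserves
#' total embryo volume.
#'
#' @param ... named overrides for any default value, e.g.
#'   `default_parameters(elements_per_cell = 8, sigma_move = 0.02)`.
#' @return A named list of class `blastosem_params`.
#' @export
default_parameters <- function(...) {
  p <- list(
    ## --- gene regulatory network: synthesis rates -------------------------
    vsn0 = 0.05, vsn1 = 0.8, vsn2 = 2.2,
    vsg0 = 0.05, vsg1 = 1.05, vsg2 = 2.4,
    vsfr1 = 0.084, vsfr2 = 0.084,
    vsf = 1.0, va = 1.75,
    ## degradation rates
    kN = 1, kG = 1, kFr = 0.12, kFs = 1, kErk = 0.5,
    ## Hill / Michaelis constants
    Kin1 = 0.28, Kin2 = 1.5, Kan = 1.3,
    Kag1 = 0.28, Kag2 = 1.3, Kig = 1.6,
    Kifr = 2.5, Kafr = 0.8, Kaf = 1.5,
    Kd = 1.2, Ka = 0.5, Ki = 0.5,
    ## Hill exponents
    u = 2, v = 4, w = 4, r = 2, s = 4, q = 4, x = 2, y = 2, z = 4,
    ## multiplicative noise amplitudes (gene expression) and the
    ## perception-noise sd of the neighbor-averaged Fgf4 signal
    sigmaN = 0.07, sigmaG = 0.07, sigmaFr = 0.05, sigmaFs = 0.05,
    sigmaErk = 0.05, sigma_gamma = 0.1,
    gene_noise_scale = 1,
    ## --- Fgf signaling schedule (stages are cell counts) ------------------
    fgf_on_stage = 1, fgf_off_stage = 128,
    epsilon_on = 1, epsilon_off = 0,
    ## --- Oct4/Cdx2 contact toggle (active before the 32-cell stage) ------
    oc_basal = 0.1, oc_self = 1.6, oc_K = 0.6, oc_Kx = 0.5,
    oc_n = 4, oc_k = 1, oc_contact_gain = 0.6, oc_contact_mid = 0.58,
    oc_sigma = 0.05, oc_burnin = 2,
    ## initial zygote gene state (co-expressing, uncommitted)
    init_Nan = 1.2, init_Gat = 1.2, init_Fr = 0.1, init_Fs = 0.5,
    init_Erk = 0.3, init_Oct4 = 1.0, init_Cdx2 = 1.0,
    ## fate classification thresholds (mid-gap of the bimodal endpoint
    ## marginals of the default parameterization; see vignette)
    theta_N = 1.8, theta_G = 0.8,
    ## --- geometry and mechanics -------------------------------------------
    zona_radius = 1.0,           # unit of length
    embryo_radius = 0.95,        # radius of the 1-cell zygote
    elements_per_cell = 20,
    r_contact_factor = 2.6,      # contact cutoff, x current cell radius
    ## Morse potentials; distances in units of current element spacing
    de_intra = 1.0, a_intra = 2.5, re_intra_factor = 1.0,
    de_inter = 0.3, a_inter = 2.5, re_inter_factor = 1.2,
    cutoff_factor = 2.5,         # potential cutoff, x equilibrium distance
    alpha_baseline = 1.0,        # uniform adhesion before SA onset
    mobility = 1.0,              # overdamped drag
    sigma_move = 0.035,          # movement-noise amplitude (baseline)
    move_noise_scale = 1,
    min_pair_dist = 1e-6,        # coincident-element regularization
    max_disp_factor = 0.25,      # per-step displacement cap, x spacing
    zona_stiffness = 100,
    cavity_stiffness = 12,
    cavity_onset_stage = 32,
    cavity_center_z = -0.45,     # cavity anchored at the lower pole
    cavity_max_radius = 0.5,
    ## --- division schedule -------------------------------------------------
    stage_duration = 4,          # synchronous cleavage interval (1C..32C)
    div_window_start = 3,        # async windows (32->64, 64->128), offsets
    div_window_end = 7,          # from stage completion time
    sort_window = 5,            # time simulated past 128 cells
    daughter_jitter = 0.05,      # replenished-element jitter, x cell radius
    ## --- integration --------------------------------------------------------
    dt_mech = 0.02,
    dt_gene = 0.02,
    ## --- selective adhesion ------------------------------------------------
    sa_start_stage = 64,
    as_boost = 2.0,              # favored-pair score in H2..H5
    as_te_te = 2.0, as_te_epi = 2.0, as_te_pe = 1.0, as_te_dp = 1.5,
    ## --- pattern metrics ---------------------------------------------------
    contact_elem_factor = 1.6,   # element contact range, x element spacing
    adjacency_factor = 1.5,      # outcome-classifier adjacency, x cell radius
    pe_coverage_threshold = 0.8,
    n_random = 200               # label randomizations for the loss score
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "blastosem_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks the sign and range constraints that the model equations assume:
#' rates, Hill constants and stiffnesses nonnegative, Hill exponents >= 1,
#' positive contact cutoff and timesteps, and a consistent Fgf schedule.
#'
#' @param p a `blastosem_params` list.
#' @return `p`, invisibly; stops with a configuration error otherwise.
#' @export
validate_parameters <- function(p) {
  nonneg <- c("vsn0", "vsn1", "vsn2", "vsg0", "vsg1", "vsg2", "vsfr1",
              "vsfr2", "vsf", "va", "kN", "kG", "kFr", "kFs", "kErk",
              "Kin1", "Kin2", "Kan", "Kag1", "Kag2", "Kig", "Kifr", "Kafr",
              "Kaf", "Kd", "Ka", "Ki", "sigmaN", "sigmaG", "sigmaFr",
              "sigmaFs", "sigmaErk", "sigma_gamma", "zona_stiffness",
              "cavity_stiffness", "sigma_move", "de_intra", "de_inter",
              "epsilon_on", "epsilon_off")
  for (nm in nonneg)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("parameter ", nm, " must be finite and >= 0")
  for (nm in c("u", "v", "w", "r", "s", "q", "x", "y", "z"))
    if (p[[nm]] < 1) stop("Hill exponent ", nm, " must be >= 1")
  for (nm in c("r_contact_factor", "dt_mech", "dt_gene", "stage_duration",
               "mobility", "zona_radius", "embryo_radius"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter ", nm, " must be > 0")
  if (p$elements_per_cell < 2)
    stop("elements_per_cell must be >= 2")
  if (p$div_window_start >= p$div_window_end)
    stop("division window must have window_start < window_end")
  if (p$epsilon_off > p$epsilon_on)
    stop("epsilon_off must be <= epsilon_on")
  if (is.finite(p$fgf_off_stage) && p$fgf_on_stage >= p$fgf_off_stage)
    stop("fgf_on_stage must be < fgf_off_stage")
  invisible(p)
}

#' Read / write parameter configuration as YAML
#'
#' The YAML file mirrors the parameter names exactly; absent keys keep their
#' defaults. `Inf` (an Fgf schedule that never attenuates) is written as the
#' string `.inf` per YAML convention.
#'
#' @param path file path.
#' @param p a `blastosem_params` list (for writing).
#' @return `read_parameters` returns a validated `blastosem_params` list.
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_parameters, vals)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(p, path) {
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

## Radius of one cell when n cells share the (volume-conserving) embryo:
## r_n = embryo_radius * n^(-1/3).
cell_radius <- function(p, n_cells) p$embryo_radius * n_cells^(-1 / 3)

## Contact cutoff between cell centroids at the current stage.
contact_radius <- function(p, n_cells) p$r_contact_factor * cell_radius(p, n_cells)

## Element equilibrium spacing: elements_per_cell spheres packed in a cell.
element_spacing <- function(p, n_cells) {
  2 * cell_radius(p, n_cells) * p$elements_per_cell^(-1 / 3)
}
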