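## Simulation orchestration: the macro-step loop coupling gene dynamics,
## mechanics, fate-dependent adhesion, the division schedule and the
## TE/ICM decision, plus the scenario grid runner.

#' Define a simulation scenario
#'
#' A scenario bundles the experimental condition: the adhesion hypothesis
#' and its onset stage, the Fgf signaling schedule, the movement- and
#' gene-noise scalings, and the initial condition.
#'
#' @param adhesion `"H1"` .. `"H7"`, an `adhesion_matrix`, or `NULL` for
#'   uniform adhesion.
#' @param sa_start_stage selective-adhesion onset stage (32, 64 or 128).
#' @param fgf an `fgf_schedule` (default: on from stage 1, attenuated at
#'   the 128-cell stage).
#' @param movement_noise_scale multiplier on the movement-noise amplitude
#'   (0.1, 1, 5 in the noise experiments).
#' @param gene_noise_scale joint multiplier on the gene-expression noise
#'   amplitudes (0.1, 1, 2).
#' @param init `"spontaneous"` (zygote, gene states develop on their
#'   own), `"synthetic-32C"` or `"synthetic-64C"` (expression-like gene
#'   states imposed when the embryo reaches that stage).
#' @param init_composition optional fate composition for the synthetic
#'   initial states.
#' @param n_replicates,base_seed replicate bookkeeping for [run_grid()].
#' @param name optional label.
#' @return a `scenario` list.
#' @export
scenario <- function(adhesion = "H6", sa_start_stage = 64,
                     fgf = fgf_schedule(), movement_noise_scale = 1,
                     gene_noise_scale = 1,
                     init = c("spontaneous", "synthetic-32C",
                              "synthetic-64C"),
                     init_composition = NULL,
                     n_replicates = 10, base_seed = 1,
                     name = NULL) {
  init <- match.arg(init)
  stopifnot(sa_start_stage %in% c(32, 64, 128),
            n_replicates >= 1)
  if (is.null(name))
    name <- paste0(if (is.character(adhesion)) adhesion else "custom",
                   "_sa", sa_start_stage,
                   "_fgf", fgf$on_stage, "-",
                   if (is.finite(fgf$off_stage)) fgf$off_stage else "on")
  structure(list(adhesion = adhesion, sa_start_stage = sa_start_stage,
                 fgf = fgf, movement_noise_scale = movement_noise_scale,
                 gene_noise_scale = gene_noise_scale, init = init,
                 init_composition = init_composition,
                 n_replicates = n_replicates, base_seed = base_seed,
                 name = name),
            class = "scenario")
}

resolve_adhesion <- function(scn, params, seed) {
  if (is.null(scn$adhesion)) return(NULL)
  if (inherits(scn$adhesion, "adhesion_matrix")) {
    m <- scn$adhesion
    m$active_from_stage <- scn$sa_start_stage
    return(m)
  }
  hypothesis_matrix(scn$adhesion, params,
                    active_from_stage = scn$sa_start_stage)
}

#' Run one full simulation
#'
#' Advances the embryo from the zygote (or from an imposed 32C/64C
#' expression state) to the late 128-cell stage. Each macro step:
#' neighbor query, perceived Fgf4, stochastic gene update (plus the
#' Oct4/Cdx2 toggle before the 32-cell stage), fate classification,
#' adhesion lookup via the selective-adhesion schedule, forces, noisy
#' overdamped position update, then division bookkeeping. At the first
#' arrival at 32 cells the TE/ICM decision is frozen (Cdx2 > Oct4 at
#' that moment) and the cavity starts growing. The run ends
#' `sort_window` time units after the 128th cell appears.
#'
#' @param scn a [scenario()].
#' @param seed integer seed; the run is deterministic given
#'   (scenario, seed, params).
#' @param params parameter set.
#' @param track `"none"`, `"summary"` (per-unit-time population summary)
#'   or `"genes"` (long-format per-cell gene time series).
#' @param track_every time between tracked records.
#' @param out_dir if non-NULL, the endpoint state is written there.
#' @return list: endpoint `state`, `report` (a [pattern_report()]),
#'   `summary` / `genes` tracks (if requested), `t128` (time the 128th
#'   cell appeared).
#' @export
run_simulation <- function(scn, seed = scn$base_seed,
                           params = default_parameters(),
                           track = c("none", "summary", "genes"),
                           track_every = 1, out_dir = NULL) {
  track <- match.arg(track)
  stopifnot(inherits(scn, "scenario"))
  params$move_noise_scale <- scn$movement_noise_scale
  params$gene_noise_scale <- scn$gene_noise_scale
  adh <- resolve_adhesion(scn, params, seed)
  state <- new_embryo(params, seed)
  dt <- params$dt_mech
  gene_every <- max(1L, as.integer(round(params$dt_gene / dt)))
  dt_gene <- dt * gene_every
  t128 <- NA_real_
  t32 <- NA_real_
  lineage_frozen <- FALSE
  init_done <- scn$init == "spontaneous"
  init_stage <- if (scn$init == "synthetic-32C") 32
                else if (scn$init == "synthetic-64C") 64 else NA
  rows_sum <- list(); rows_gene <- list(); next_track <- 0
  step <- 0L
  repeat {
    n <- n_cells(state)
    stage <- embryo_stage(state)
    eps <- epsilon_t(stage, scn$fgf)
    fates <- classify_fate(state$genes, params)
    active_adh <- sa_schedule(stage, adh, params)
    ## gene dynamics (operator splitting: once per gene_every macro steps)
    if (step %% gene_every == 0L) {
      if (lineage_frozen) {
        ## the Epi/PE program and Fgf4 exchange are ICM-internal once the
        ## TE/ICM decision is made (Cdx2 represses it in the TE)
        icm <- which(state$lineage != "TE")
        Fp <- perceived_fgf4(state, params, subset = icm)
        upd <- step_genes(state$genes[icm, , drop = FALSE], Fp[icm], eps,
                          dt_gene, params)
        state$genes[icm, ] <- upd
      } else {
        Fp <- perceived_fgf4(state, params)
        state$genes <- step_genes(state$genes, Fp, eps, dt_gene, params)
        if (n >= 2) {
          cf <- contact_fractions(state, params)
          state$genes <- te_icm_step(state$genes, cf, dt_gene, params)
        }
      }
    }
    ## mechanics
    F <- total_forces(state, params, active_adh, fates)
    state <- step_positions(state, F, dt, params)
    state$time <- state$time + dt
    step <- step + 1L
    ## divisions (complete the round, then reschedule)
    due <- division_scheduler(state, params)
    if (length(due)) {
      for (id in due) state <- divide_cell(state, id)
      state <- schedule_divisions(state, params)
      n <- n_cells(state)
      if (is.na(t32) && n >= 32) t32 <- state$time
      if (!init_done && !is.na(init_stage) && init_stage == 64 && n >= 64) {
        state$genes <- impose_synth_states(state, "64C", scn, params, seed)
        init_done <- TRUE
      }
      if (is.na(t128) && n >= 128) t128 <- state$time
    }
    ## freeze the TE/ICM decision after a short burn-in at the 32C stage
    if (!lineage_frozen && !is.na(t32) &&
        state$time >= t32 + params$oc_burnin) {
      te <- state$genes[, "Cdx2"] > state$genes[, "Oct4"]
      state$lineage <- ifelse(te, "TE", "ICM")
      state$cavity_t0 <- state$time
      lineage_frozen <- TRUE
      if (!init_done && init_stage == 32) {
        state$genes <- impose_synth_states(state, "32C", scn, params, seed)
        init_done <- TRUE
      }
    }
    ## tracking
    if (track != "none" && state$time >= next_track - 1e-9) {
      next_track <- next_track + track_every
      if (track == "summary") {
        fr <- population_ratios(classify_fate(state$genes, params))
        rows_sum[[length(rows_sum) + 1L]] <-
          data.frame(time = state$time, n_cells = n_cells(state),
                     t(fr))
      } else {
        g <- state$genes[, 1:5, drop = FALSE]
        rows_gene[[length(rows_gene) + 1L]] <-
          data.frame(time = state$time,
                     cell_id = rep(seq_len(nrow(g)), 5),
                     species = rep(colnames(g), each = nrow(g)),
                     value = as.vector(g))
      }
    }
    if (!is.na(t128) && state$time >= t128 + params$sort_window) break
    if (state$time > 60 * params$stage_duration)
      stop("simulation exceeded the maximum duration without reaching ",
           "128 cells")
  }
  state$rng_state <- .Random.seed
  report <- pattern_report(state, params)
  if (!is.null(out_dir)) write_state(state, out_dir)
  out <- list(state = state, report = report, t128 = t128, seed = seed,
              scenario = scn)
  if (track == "summary") out$summary <- do.call(rbind, rows_sum)
  if (track == "genes") out$genes <- do.call(rbind, rows_gene)
  out
}

## Replace gene states with synthetic expression-derived states, keeping
## TE cells' Oct4/Cdx2 and preserving column layout.
impose_synth_states <- function(state, stage_label, scn, params, seed) {
  g <- synth_initial_states(stage_label, n_cells(state),
                            composition = scn$init_composition,
                            seed = seed + 7L, params = params)
  keep <- state$genes[, c("Oct4", "Cdx2"), drop = FALSE]
  g[, "Oct4"] <- keep[, "Oct4"]
  g[, "Cdx2"] <- keep[, "Cdx2"]
  g
}

#' Run a grid of scenarios
#'
#' Executes `n_replicates` runs per scenario (seeds
#' `base_seed + 0:(n-1)`), collecting loss score, outcome, population
#' ratios and runtime per run. Individual failures are recorded and do
#' not stop the grid.
#'
#' @param scenarios list of [scenario()] objects.
#' @param params parameter set.
#' @return data frame, one row per (scenario, replicate).
#' @export
run_grid <- function(scenarios, params = default_parameters()) {
  rows <- list()
  for (scn in scenarios) {
    for (k in seq_len(scn$n_replicates)) {
      seed <- scn$base_seed + k - 1
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(run_simulation(scn, seed, params),
                      error = function(e) e)
      dt <- proc.time()[["elapsed"]] - t0
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <-
          data.frame(scenario = scn$name, seed = seed, status = "failed",
                     loss = NA_real_, outcome = NA_character_,
                     nanog_pos = NA_real_, gata6_pos = NA_real_,
                     dp = NA_real_, dn = NA_real_, runtime = dt,
                     message = conditionMessage(res))
      } else {
        r <- res$report
        rows[[length(rows) + 1L]] <-
          data.frame(scenario = scn$name, seed = seed, status = "ok",
                     loss = r$loss_score, outcome = r$outcome,
                     nanog_pos = r$ratios[["Nanog+"]],
                     gata6_pos = r$ratios[["Gata6+"]],
                     dp = r$ratios[["DP"]], dn = r$ratios[["DN"]],
                     runtime = dt, message = "")
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a grid table per scenario
#'
#' @param grid data frame from [run_grid()].
#' @return data frame with success/partial rates and mean loss/ratios.
#' @export
summarize_grid <- function(grid) {
  ok <- grid[grid$status == "ok", , drop = FALSE]
  agg <- lapply(split(ok, ok$scenario), function(d) {
    data.frame(scenario = d$scenario[1], n = nrow(d),
               success_rate = mean(d$outcome == "success"),
               partial_rate = mean(d$outcome == "partial"),
               mean_loss = mean(d$loss),
               mean_gata6 = mean(d$gata6_pos),
               mean_nanog = mean(d$nanog_pos),
               mean_dp = mean(d$dp))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
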