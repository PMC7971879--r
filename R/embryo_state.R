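## Core data model: the simulated embryo as element positions + per-cell
## gene states and bookkeeping, with lossless text serialization.

#' Create a 1-cell embryo (zygote)
#'
#' Places a single cell at the origin, its elements sampled uniformly in a
#' ball of the stage-1 cell radius (then centered exactly), gene state at
#' the configured initial values, and the first synchronous division
#' scheduled one cleavage interval ahead. Deterministic given `seed`.
#'
#' @param params a `blastosem_params` list.
#' @param seed integer RNG seed.
#' @return an `embryo_state`: list with element positions `pos` (E x 3),
#'   element ownership `element_cell`, per-cell `genes` matrix, `lineage`,
#'   `birth_time`, `division_due`, simulation `time`, `cavity_t0`, the
#'   parameter set and an RNG reproducibility token.
#' @export
new_embryo <- function(params, seed = 1L) {
  validate_parameters(params)
  set.seed(seed)
  m <- params$elements_per_cell
  rc <- cell_radius(params, 1)
  dir <- matrix(stats::rnorm(m * 3), m, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  pos <- dir * rc * 0.8 * stats::runif(m)^(1 / 3)
  pos <- sweep(pos, 2, colMeans(pos))  # centroid exactly at the origin
  genes <- matrix(c(params$init_Nan, params$init_Gat, params$init_Fr,
                    params$init_Fs, params$init_Erk, params$init_Oct4,
                    params$init_Cdx2), nrow = 1,
                  dimnames = list(NULL, GENE_NAMES))
  state <- structure(list(
    time = 0,
    pos = pos,
    element_cell = rep(1L, m),
    genes = genes,
    lineage = "unspecified",
    birth_time = 0,
    division_due = params$stage_duration,
    cavity_t0 = NA_real_,
    params = params,
    seed = as.integer(seed),
    rng_state = .Random.seed
  ), class = "embryo_state")
  state
}

#' @export
print.embryo_state <- function(x, ...) {
  cat(sprintf("<embryo_state> t=%.2f  %d cells (stage %d), %d elements\n",
              x$time, n_cells(x), embryo_stage(x), nrow(x$pos)))
  invisible(x)
}

#' Number of cells / cell-count stage
#'
#' The stage is the cell count rounded down to the schedule's stage
#' boundaries (1, 2, 4, ..., 128): during the asynchronous 32-to-64 and
#' 64-to-128 rounds an embryo with e.g. 90 cells is at stage 64.
#'
#' @param state an `embryo_state`.
#' @return integer.
#' @export
n_cells <- function(state) nrow(state$genes)

#' @rdname n_cells
#' @export
embryo_stage <- function(state) {
  n <- n_cells(state)
  as.integer(2^floor(log2(n)))
}

#' Cell centroids
#'
#' Mean position of each cell's elements; the per-cell location used by
#' neighbor queries, the contact cutoff and the pattern metrics.
#'
#' @param state an `embryo_state`.
#' @return n x 3 matrix.
#' @export
cell_centroids <- function(state) {
  cpp_cell_centroids(state$pos, state$element_cell - 1L, n_cells(state))
}

#' Element ids of one cell
#' @param state an `embryo_state`.
#' @param cell_id integer cell id.
#' @return integer vector of element row indices.
#' @export
elements_of <- function(state, cell_id) {
  if (cell_id < 1 || cell_id > n_cells(state))
    stop("unknown cell id: ", cell_id)
  which(state$element_cell == cell_id)
}

#' Neighboring cells within the contact radius
#'
#' Cells j != i whose centroid lies within `r_contact` of cell i's
#' centroid. The relation is symmetric and irreflexive.
#'
#' @param state an `embryo_state`.
#' @param cell_id integer cell id.
#' @param r_contact cutoff; defaults to the stage-scaled contact radius
#'   `r_contact_factor * cell_radius`.
#' @return integer vector of neighbor cell ids.
#' @export
neighbors <- function(state, cell_id, r_contact = NULL) {
  n <- n_cells(state)
  if (cell_id < 1 || cell_id > n) stop("unknown cell id: ", cell_id)
  if (is.null(r_contact)) r_contact <- contact_radius(state$params, n)
  cen <- cell_centroids(state)
  d <- sqrt(colSums((t(cen) - cen[cell_id, ])^2))
  setdiff(which(d < r_contact), cell_id)
}

## All cells' neighbor lists at once (centroid cutoff).
neighbor_list <- function(state, params = state$params,
                          r_contact = NULL) {
  n <- n_cells(state)
  if (is.null(r_contact)) r_contact <- contact_radius(params, n)
  cen <- cell_centroids(state)
  d <- as.matrix(stats::dist(cen))
  diag(d) <- Inf
  apply(d < r_contact, 1, which, simplify = FALSE)
}

#' Write / read an embryo state as inspectable text files
#'
#' `write_state` creates (or overwrites) a directory holding
#' `header.json` (time, seed, RNG token, full parameter set),
#' `cells.csv` (one row per cell: id, centroid, gene state, lineage and
#' fate labels, division bookkeeping) and `elements.xyz` (extended-XYZ:
#' element id, owner cell, coordinates). Numbers are written with 17
#' significant digits so the round trip is lossless.
#'
#' @param state an `embryo_state`.
#' @param path directory path.
#' @return `read_state` returns the reconstructed `embryo_state`.
#' @export
write_state <- function(state, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(time = state$time, seed = state$seed,
                 cavity_t0 = state$cavity_t0,
                 rng_state = state$rng_state,
                 params = unclass(state$params))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  cen <- cell_centroids(state)
  fate <- classify_fate(state$genes, state$params)
  df <- data.frame(cell_id = seq_len(n_cells(state)),
                   x = cen[, 1], y = cen[, 2], z = cen[, 3],
                   state$genes,
                   lineage = state$lineage, fate = fate,
                   birth_time = state$birth_time,
                   division_due = state$division_due,
                   time = state$time)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, file.path(path, "cells.csv"), row.names = FALSE,
                   quote = FALSE)
  con <- file(file.path(path, "elements.xyz"), "w")
  on.exit(close(con))
  writeLines(as.character(nrow(state$pos)), con)
  writeLines(sprintf("t=%.17g", state$time), con)
  writeLines(sprintf("%d %d %.17g %.17g %.17g",
                     seq_len(nrow(state$pos)), state$element_cell,
                     state$pos[, 1], state$pos[, 2], state$pos[, 3]), con)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  hfile <- file.path(path, "header.json")
  cfile <- file.path(path, "cells.csv")
  efile <- file.path(path, "elements.xyz")
  for (f in c(hfile, cfile, efile))
    if (!file.exists(f)) stop("state directory is missing ", basename(f))
  header <- jsonlite::read_json(hfile, simplifyVector = TRUE)
  params <- do.call(default_parameters, header$params)
  cells <- tryCatch(
    utils::read.csv(cfile, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in cells.csv: ",
                             conditionMessage(e)))
  need <- c("cell_id", GENE_NAMES, "lineage", "birth_time", "division_due")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cells.csv is missing column(s): ", paste(miss, collapse = ", "))
  lines <- readLines(efile)
  if (length(lines) < 3) stop("parse error in elements.xyz: truncated file")
  ne <- suppressWarnings(as.integer(lines[1]))
  if (is.na(ne)) stop("parse error in elements.xyz line 1: not a count")
  if (length(lines) < 2 + ne)
    stop("parse error in elements.xyz: expected ", ne, " element records, ",
         "found ", length(lines) - 2)
  rec <- utils::read.table(text = lines[3:(2 + ne)], col.names =
    c("element", "cell", "x", "y", "z"))
  if (any(!is.finite(as.matrix(rec[, 3:5]))))
    stop("parse error in elements.xyz: non-finite coordinates")
  genes <- as.matrix(cells[, GENE_NAMES])
  dimnames(genes) <- list(NULL, GENE_NAMES)
  if (any(rec$cell < 1 | rec$cell > nrow(genes)))
    stop("elements.xyz references unknown cell ids")
  structure(list(
    time = header$time,
    pos = unname(as.matrix(rec[, c("x", "y", "z")])),
    element_cell = as.integer(rec$cell),
    genes = genes,
    lineage = cells$lineage,
    birth_time = cells$birth_time,
    division_due = cells$division_due,
    cavity_t0 = if (is.null(header$cavity_t0)) NA_real_
                else as.numeric(header$cavity_t0),
    params = params,
    seed = as.integer(header$seed),
    rng_state = as.integer(header$rng_state)
  ), class = "embryo_state")
}
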