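## Expression-matrix I/O and transforms, synthetic single-cell expression
## generators emulating the statistical structure of the real inputs
## (bimodal adhesion-gene expression; stage-stratified Nanog/Gata6
## states), and import of expression as simulation initial conditions.

#' Expression matrix container
#'
#' @param values cells x genes nonnegative numeric matrix with dimnames.
#' @param stage optional stage label per cell.
#' @param fate optional fate label per cell.
#' @return an `expression_matrix` list.
#' @export
expression_matrix <- function(values, stage = NULL, fate = NULL) {
  stopifnot(is.matrix(values))
  if (any(values < 0)) stop("expression values must be nonnegative")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("expression matrix needs gene names")
  chk <- function(v, nm) {
    if (!is.null(v) && length(v) != nrow(values))
      stop("validation error: ", nm, " has length ", length(v),
           " but the matrix has ", nrow(values), " cells")
    v
  }
  structure(list(values = values, cell_ids = rownames(values),
                 gene_ids = colnames(values),
                 stage = chk(stage, "stage"), fate = chk(fate, "fate")),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Load an expression matrix
#'
#' CSV format: cells as rows, a `cell_id` column plus one column per
#' gene (optional `stage` / `fate` columns are split into metadata).
#' MatrixMarket format: triplet file plus sidecar metadata CSV
#' (`cell_id`, optional `stage`, `fate`; one row per matrix row) and a
#' gene-id file (one name per line, one per matrix column).
#'
#' @param path matrix file.
#' @param format `"csv"` or `"mtx"`.
#' @param meta_path sidecar metadata CSV (required for mtx).
#' @param genes_path gene-name file (required for mtx).
#' @return an `expression_matrix`.
#' @export
load_expression <- function(path, format = c("csv", "mtx"),
                            meta_path = NULL, genes_path = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"cell_id" %in% names(df)) stop("CSV needs a cell_id column")
    stage <- df$stage; fate <- df$fate
    genecols <- setdiff(names(df), c("cell_id", "stage", "fate"))
    m <- as.matrix(df[, genecols, drop = FALSE])
    if (!is.numeric(m)) stop("validation error: non-numeric gene columns")
    rownames(m) <- df$cell_id
    expression_matrix(m, stage = stage, fate = fate)
  } else {
    if (is.null(meta_path) || is.null(genes_path))
      stop("mtx format needs meta_path and genes_path sidecars")
    m <- as.matrix(Matrix::readMM(path))
    meta <- utils::read.csv(meta_path)
    genes <- readLines(genes_path)
    if (nrow(meta) != nrow(m))
      stop("validation error: sidecar has ", nrow(meta),
           " rows but matrix has ", nrow(m), " cells")
    if (length(genes) != ncol(m))
      stop("validation error: ", length(genes), " gene names for ",
           ncol(m), " columns")
    rownames(m) <- meta$cell_id
    colnames(m) <- genes
    expression_matrix(m, stage = meta$stage, fate = meta$fate)
  }
}

#' Write an expression matrix
#' @param expr an `expression_matrix`.
#' @param path output file (csv) or matrix file (mtx).
#' @param format `"csv"` or `"mtx"`.
#' @param meta_path,genes_path sidecar paths for mtx output.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("csv", "mtx"),
                             meta_path = NULL, genes_path = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(cell_id = expr$cell_ids, expr$values,
                     check.names = FALSE)
    if (!is.null(expr$stage)) df$stage <- expr$stage
    if (!is.null(expr$fate)) df$fate <- expr$fate
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    if (is.null(meta_path) || is.null(genes_path))
      stop("mtx format needs meta_path and genes_path")
    Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), path)
    meta <- data.frame(cell_id = expr$cell_ids)
    if (!is.null(expr$stage)) meta$stage <- expr$stage
    if (!is.null(expr$fate)) meta$fate <- expr$fate
    utils::write.csv(meta, meta_path, row.names = FALSE)
    writeLines(expr$gene_ids, genes_path)
  }
  invisible(path)
}

#' log1p transform and per-gene z-score
#'
#' @param expr an `expression_matrix` or plain matrix.
#' @param genes gene names to transform.
#' @param zscore also standardize each gene across cells.
#' @return matrix of transformed columns.
#' @export
log1p_zscore <- function(expr, genes, zscore = TRUE) {
  m <- if (inherits(expr, "expression_matrix")) expr$values else expr
  miss <- setdiff(genes, colnames(m))
  if (length(miss)) stop("gene(s) not found: ", paste(miss, collapse = ", "))
  out <- log1p(m[, genes, drop = FALSE])
  if (zscore) out <- scale(out)[, , drop = FALSE]
  out
}

#' Mean expression per fate
#' @param expr an `expression_matrix` with fate labels.
#' @param genes gene names.
#' @return fates x genes matrix of arithmetic means of raw levels.
#' @export
mean_expression_by_fate <- function(expr, genes) {
  if (is.null(expr$fate)) stop("expression matrix has no fate labels")
  sub <- expr$values[, genes, drop = FALSE]
  out <- apply(sub, 2, function(v) tapply(v, expr$fate, mean))
  as.matrix(out)
}

#' Synthetic adhesion-gene expression (EphA4 / EphrinB2)
#'
#' Generates a cells x 2 expression matrix whose combined
#' log1p-sum z-score is a two-component Gaussian mixture: each cell is
#' high- or low-adhesive with a fate-dependent probability (default
#' ordering Nanog+ ~ DP > Gata6+, i.e. fewer Gata6+ cells in the
#' high-adhesion mode), and gene levels are lognormal within each mode.
#'
#' @param n_cells number of cells.
#' @param fractions_high_by_fate named fractions for `Nanog+`, `Gata6+`,
#'   `DP`.
#' @param fate_composition named fractions of fates among the cells.
#' @param mixture_params list with lognormal meanlog (`mu_high`,
#'   `mu_low`) and sdlog (`sd_high`, `sd_low`) per mode.
#' @param seed RNG seed.
#' @param params parameter set (unused defaults hook).
#' @return an `expression_matrix` with genes `EphA4`, `EphrinB2`, fate
#'   labels, stage label `"E4.5"`.
#' @export
synth_adhesion_expression <- function(
    n_cells = 500,
    fractions_high_by_fate = c("Nanog+" = 0.8, "Gata6+" = 0.35, "DP" = 0.75),
    fate_composition = c("Nanog+" = 0.4, "Gata6+" = 0.45, "DP" = 0.15),
    mixture_params = list(mu_high = log(30), sd_high = 0.35,
                          mu_low = log(3), sd_low = 0.45),
    seed = 1L, params = NULL) {
  stopifnot(all(fractions_high_by_fate >= 0 & fractions_high_by_fate <= 1))
  stopifnot(abs(sum(fate_composition) - 1) < 1e-9)
  set.seed(seed)
  fates <- sample(names(fate_composition), n_cells, replace = TRUE,
                  prob = fate_composition)
  p_hi <- fractions_high_by_fate[fates]
  hi <- stats::runif(n_cells) < p_hi
  mu <- ifelse(hi, mixture_params$mu_high, mixture_params$mu_low)
  sd <- ifelse(hi, mixture_params$sd_high, mixture_params$sd_low)
  vals <- cbind(EphA4 = stats::rlnorm(n_cells, mu, sd),
                EphrinB2 = stats::rlnorm(n_cells, mu, sd))
  rownames(vals) <- paste0("cell", seq_len(n_cells))
  out <- expression_matrix(vals, stage = rep("E4.5", n_cells), fate = fates)
  out$mode <- ifelse(hi, "high", "low")
  out
}

## Erk quasi-steady state given Fgfr2 level and a nominal perceived Fgf4.
erk_qss <- function(Fr, Fp, p) {
  vapply(Fr, function(fr) {
    act <- p$va * fr * Fp / (p$Kd + Fp)
    f <- function(E) act * (1 - E) / (p$Ka + 1 - E) -
      p$kErk * E / (p$Ki + E)
    if (f(0) <= 0) return(0)
    if (f(1) >= 0) return(1)
    stats::uniroot(f, c(0, 1), tol = 1e-9)$root
  }, numeric(1))
}

#' Synthetic stage-stratified initial gene states
#'
#' Draws per-cell (Nanog, Gata6) from fate-conditional lognormal
#' clusters in the model's non-dimensional units (DP: both high;
#' Nanog+: Nanog high / Gata6 low; Gata6+: converse), sets Fgfr2 and
#' Fgf4 at their quasi-steady values given (Nanog, Gata6) with
#' multiplicative scatter, and initializes Erk at quasi-steady state
#' given the cell's Fgfr2 and a nominal perceived Fgf4. Emulates using
#' measured single-cell expression as the initial condition at the 32-
#' or 64-cell stage.
#'
#' @param stage `"32C"` or `"64C"` (label only; both use the same
#'   clusters).
#' @param n_cells number of cells.
#' @param composition named fractions for `DP`, `Nanog+`, `Gata6+`
#'   (must sum to 1). The 32C default is DP-dominated, the 64C default
#'   an even salt-and-pepper mix with a DP remainder.
#' @param nominal_Fp perceived Fgf4 used for the Erk quasi-steady state.
#' @param seed RNG seed.
#' @param params parameter set.
#' @return cells x 7 gene matrix (columns as in `embryo_state$genes`).
#' @export
synth_initial_states <- function(stage = c("32C", "64C"), n_cells,
                                 composition = NULL, nominal_Fp = 0.5,
                                 seed = 1L,
                                 params = default_parameters()) {
  stage <- match.arg(stage)
  if (is.null(composition))
    composition <- if (stage == "32C")
      c("DP" = 0.8, "Nanog+" = 0.15, "Gata6+" = 0.05)
    else c("DP" = 0.3, "Nanog+" = 0.35, "Gata6+" = 0.35)
  if (abs(sum(composition) - 1) > 1e-9)
    stop("validation error: composition fractions must sum to 1")
  set.seed(seed)
  p <- params
  fates <- sample(names(composition), n_cells, replace = TRUE,
                  prob = composition)
  draw <- function(f) {
    switch(f,
      "DP"     = c(stats::rlnorm(1, log(2.3), 0.10),
                   stats::rlnorm(1, log(1.1), 0.15)),
      "Nanog+" = c(stats::rlnorm(1, log(2.9), 0.08),
                   stats::rlnorm(1, log(0.20), 0.30)),
      "Gata6+" = c(stats::rlnorm(1, log(0.15), 0.30),
                   stats::rlnorm(1, log(2.6), 0.10)))
  }
  ng <- t(vapply(fates, draw, numeric(2)))
  Nan <- ng[, 1]; Gat <- ng[, 2]
  Fr <- (p$vsfr1 * p$Kifr^p$x / (p$Kifr^p$x + Nan^p$x) +
           p$vsfr2 * Gat^p$y / (p$Kafr^p$y + Gat^p$y)) / p$kFr *
    stats::rlnorm(n_cells, 0, 0.1)
  Fs <- p$vsf * Nan^p$z / (p$Kaf^p$z + Nan^p$z) / p$kFs *
    stats::rlnorm(n_cells, 0, 0.1)
  Erk <- erk_qss(Fr, nominal_Fp, p)
  g <- cbind(Nan = Nan, Gat = Gat, Fr = Fr, Fs = Fs, Erk = Erk,
             Oct4 = rep(p$init_Oct4, n_cells),
             Cdx2 = rep(p$init_Cdx2, n_cells))
  rownames(g) <- NULL
  g
}

#' Map a measured expression matrix to model gene states
#'
#' Affine rescale of per-gene z-scores into `[0, c_max]` model units for
#' Nanog, Gata6, Fgf4, Fgfr2 (gene columns matched case-insensitively),
#' with Erk initialized at quasi-steady state.
#'
#' @param expr an `expression_matrix` containing the four genes.
#' @param c_max upper end of the non-dimensional concentration range.
#' @param nominal_Fp perceived Fgf4 for the Erk quasi-steady state.
#' @param params parameter set.
#' @return cells x 7 gene matrix.
#' @export
expression_to_genestates <- function(expr, c_max = 3, nominal_Fp = 0.5,
                                     params = default_parameters()) {
  m <- expr$values
  find <- function(g) {
    i <- match(tolower(g), tolower(colnames(m)))
    if (is.na(i)) stop("gene not found in matrix: ", g)
    i
  }
  idx <- vapply(c("Nanog", "Gata6", "Fgfr2", "Fgf4"), find, integer(1))
  z <- scale(log1p(m[, idx, drop = FALSE]))
  resc <- apply(z, 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(c_max / 2, length(v))
    else (v - rng[1]) / diff(rng) * c_max
  })
  Erk <- erk_qss(resc[, 3], nominal_Fp, params)
  cbind(Nan = resc[, 1], Gat = resc[, 2], Fr = resc[, 3], Fs = resc[, 4],
        Erk = Erk, Oct4 = rep(params$init_Oct4, nrow(m)),
        Cdx2 = rep(params$init_Cdx2, nrow(m)))
}
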