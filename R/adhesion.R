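## Adhesion models: data-informed adhesion scores from ligand-receptor
## expression, Gaussian-mixture binarization of the combined expression
## score, the phenomenological hypotheses H1-H7, and the selective-
## adhesion activation schedule.

#' Construct an adhesion matrix
#'
#' @param AS symmetric numeric matrix of adhesion scores with cell-type
#'   dimnames.
#' @param active_from_stage cell-count stage at which the selective values
#'   replace the uniform baseline (see [sa_schedule()]).
#' @return an `adhesion_matrix` list with `cell_types`, `AS`,
#'   `active_from_stage`.
#' @export
adhesion_matrix <- function(AS, active_from_stage = 64) {
  stopifnot(is.matrix(AS), nrow(AS) == ncol(AS))
  if (is.null(rownames(AS)))
    stop("adhesion matrix needs cell-type dimnames")
  if (!isTRUE(all.equal(AS, t(AS))))
    stop("adhesion matrix must be symmetric")
  if (any(!is.finite(AS)) || any(AS <= 0))
    stop("adhesion scores must be finite and > 0")
  structure(list(cell_types = rownames(AS), AS = AS,
                 active_from_stage = active_from_stage),
            class = "adhesion_matrix")
}

#' @export
print.adhesion_matrix <- function(x, ...) {
  cat("<adhesion_matrix> active from stage", x$active_from_stage, "\n")
  print(round(x$AS, 3))
  invisible(x)
}

## TE rows are not measurable from the ICM-restricted expression data;
## they come from the configured TE-adhesion assumption (TE adheres more
## strongly to Epi-fated than to PE-fated cells).
te_rows <- function(AS, params) {
  tt <- c(rownames(AS), "TE")
  out <- matrix(params$alpha_baseline, length(tt), length(tt),
                dimnames = list(tt, tt))
  out[rownames(AS), colnames(AS)] <- AS
  out["TE", "TE"] <- params$as_te_te
  for (ct in rownames(AS)) {
    v <- switch(ct, "Nanog+" = params$as_te_epi, "Gata6+" = params$as_te_pe,
                "DP" = params$as_te_dp, params$alpha_baseline)
    out["TE", ct] <- v
    out[ct, "TE"] <- v
  }
  out
}

#' Adhesion scores from ligand-receptor expression
#'
#' Mean-expression based scoring of cell-type pairs:
#' `AS0(i, j) = (([L]_i [R]_j + [L]_j [R]_i) / 2) ^ n_force`, normalized
#' by the DP-DP score (`AS(i, j) = AS0(i, j) / AS0(DP, DP)`), so
#' `AS(DP, DP) = 1` exactly. `n_force = +1` for adhesion-strengthening
#' pairs (e.g. EphA4/EphrinB2), `-1` for adhesion-weakening pairs (e.g.
#' EphB2/EphrinB2).
#'
#' @param expr_by_type data frame or matrix with one row per cell type
#'   (rownames = types, must include `"DP"`) and columns `ligand`,
#'   `receptor` holding mean expression levels (>= 0).
#' @param n_force `+1` or `-1`.
#' @param params parameter set (for the TE rows appended to the matrix).
#' @param active_from_stage selective-adhesion onset stage.
#' @return an `adhesion_matrix` including TE rows.
#' @export
adhesion_score <- function(expr_by_type, n_force = 1,
                           params = default_parameters(),
                           active_from_stage = params$sa_start_stage) {
  if (!n_force %in% c(1, -1)) stop("n_force must be +1 or -1")
  types <- rownames(expr_by_type)
  if (is.null(types) || !"DP" %in% types)
    stop("expr_by_type needs rownames including the DP anchor type")
  L <- expr_by_type[, 1]
  R <- expr_by_type[, 2]
  if (any(L < 0) || any(R < 0)) stop("mean expression must be >= 0")
  AS0 <- (outer(L, R) + t(outer(L, R))) / 2
  if (AS0["DP", "DP"] <= 0)
    stop("normalization error: AS0(DP, DP) is zero")
  AS0 <- AS0^n_force
  AS <- AS0 / AS0["DP", "DP"]
  dimnames(AS) <- list(types, types)
  adhesion_matrix(te_rows(AS, params), active_from_stage)
}

#' Combined ligand-receptor expression score
#'
#' Per cell, `log(L + 1) + log(R + 1)`, z-scored across cells. This is
#' the score whose distribution over ICM cells is bimodal for
#' EphA4/EphrinB2 and is binarized by [gmm_binarize()].
#'
#' @param expr an `expression_matrix` (see [load_expression()]) or plain
#'   cells x genes matrix.
#' @param ligand,receptor gene names.
#' @return numeric vector (mean 0, sd 1) with one entry per cell.
#' @export
combined_lr_zscore <- function(expr, ligand, receptor) {
  m <- if (inherits(expr, "expression_matrix")) expr$values else expr
  for (g in c(ligand, receptor))
    if (!g %in% colnames(m)) stop("gene not found in matrix: ", g)
  s <- log1p(m[, ligand]) + log1p(m[, receptor])
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0)
    stop("degenerate input: combined expression score has zero variance")
  as.numeric((s - mean(s)) / sdv)
}

#' Binarize scores by a two-component Gaussian mixture
#'
#' Fits a univariate two-component Gaussian mixture by EM (via
#' \pkg{mclust}, unequal variances), labels each cell by the component
#' with the higher posterior, calls the component with the larger mean
#' "high", and reports the fraction of high cells per fate when fates are
#' supplied.
#'
#' @param scores numeric vector (>= 20 cells).
#' @param fates optional fate label per cell.
#' @return list: `labels` (`"high"`/`"low"`), `means`, `sds`, `weights`
#'   (mixture proportions, high first), `fraction_high` (overall),
#'   `fraction_high_by_fate` (if fates given).
#' @export
gmm_binarize <- function(scores, fates = NULL) {
  if (length(scores) < 20)
    stop("need at least 20 cells to fit the mixture")
  if (stats::sd(scores) == 0)
    stop("fit error: scores are constant")
  fit <- tryCatch(
    Mclust(scores, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    stop("fit error: EM for the 2-component Gaussian mixture failed ",
         "(n = ", length(scores), ", sd = ", signif(stats::sd(scores), 3),
         ")")
  mu <- as.numeric(fit$parameters$mean)
  sd2 <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sd2) == 1) sd2 <- rep(sd2, 2)
  pro <- as.numeric(fit$parameters$pro)
  hi <- which.max(mu)
  labels <- ifelse(fit$classification == hi, "high", "low")
  ord <- c(hi, setdiff(1:2, hi))
  out <- list(labels = labels,
              means = mu[ord], sds = sd2[ord], weights = pro[ord],
              fraction_high = mean(labels == "high"))
  if (!is.null(fates)) {
    out$fraction_high_by_fate <-
      tapply(labels == "high", fates, mean)
  }
  out
}

#' Phenomenological and data-driven adhesion hypotheses
#'
#' The seven selective-adhesion models compared in the simulations
#' (baseline score 1, favored pairs boosted to `as_boost`):
#' \describe{
#'   \item{H1}{no selective adhesion (uniform).}
#'   \item{H2}{symmetric: equal same-type boosts for Nanog+, Gata6+, DP.}
#'   \item{H3}{Nanog+ self-adhesion boosted; DP adheres equally (and
#'     moderately) to Nanog+ and Gata6+.}
#'   \item{H4}{DP adheres more to Nanog+ than to Gata6+.}
#'   \item{H5}{DP adheres more to both Nanog+ and Gata6+, with
#'     Nanog+\eqn{-}Nanog+ adhesion stronger than Gata6+\eqn{-}Gata6+ and
#'     Nanog+\eqn{-}Gata6+.}
#'   \item{H6}{EphA4/EphrinB2-driven scores (adhesion-strengthening,
#'     `n_force = +1`) computed by [adhesion_score()] from a supplied or
#'     synthetic expression table.}
#'   \item{H7}{EphB2/EphrinB2-driven scores (`n_force = -1`).}
#' }
#'
#' @param name `"H1"` .. `"H7"`.
#' @param params parameter set.
#' @param expr_by_type mean ligand/receptor levels per type for H6/H7;
#'   defaults to the mean levels of the synthetic adhesion-gene fixture.
#' @param active_from_stage selective-adhesion onset stage.
#' @param seed seed for the default synthetic fixture.
#' @return an `adhesion_matrix`.
#' @export
hypothesis_matrix <- function(name, params = default_parameters(),
                              expr_by_type = NULL,
                              active_from_stage = params$sa_start_stage,
                              seed = 42L) {
  b <- params$alpha_baseline
  hi <- params$as_boost
  mid <- (b + hi) / 2
  tt <- c("DP", "Nanog+", "Gata6+")
  m <- matrix(b, 3, 3, dimnames = list(tt, tt))
  make <- function(m) adhesion_matrix(te_rows(m, params), active_from_stage)
  switch(name,
    H1 = make(m),
    H2 = { diag(m) <- hi; make(m) },
    H3 = {
      m["Nanog+", "Nanog+"] <- hi
      m["DP", "Nanog+"] <- m["Nanog+", "DP"] <- mid
      m["DP", "Gata6+"] <- m["Gata6+", "DP"] <- mid
      make(m)
    },
    H4 = {
      m["Nanog+", "Nanog+"] <- hi
      m["DP", "Nanog+"] <- m["Nanog+", "DP"] <- hi
      make(m)
    },
    H5 = {
      m["Nanog+", "Nanog+"] <- hi
      m["DP", "DP"] <- hi
      m["DP", "Nanog+"] <- m["Nanog+", "DP"] <- hi
      m["DP", "Gata6+"] <- m["Gata6+", "DP"] <- mid
      make(m)
    },
    H6 = ,
    H7 = {
      if (is.null(expr_by_type)) {
        em <- synth_adhesion_expression(n_cells = 600, seed = seed,
                                        params = params)
        expr_by_type <- mean_expression_by_fate(em, c("EphA4", "EphrinB2"))
      }
      adhesion_score(expr_by_type, n_force = if (name == "H6") 1 else -1,
                     params = params, active_from_stage = active_from_stage)
    },
    stop("unknown adhesion hypothesis: ", name)
  )
}

#' Selective-adhesion schedule
#'
#' Returns the adhesion matrix in force at a given stage: the uniform
#' baseline before `active_from_stage`, the selective matrix from that
#' stage on.
#'
#' @param stage integer cell-count stage.
#' @param matrix an `adhesion_matrix`.
#' @param params parameter set (for the baseline).
#' @return an `adhesion_matrix` or `NULL` (uniform baseline).
#' @export
sa_schedule <- function(stage, matrix, params = default_parameters()) {
  if (is.null(matrix) || stage < matrix$active_from_stage) NULL else matrix
}

#' Write / read an adhesion matrix as labeled CSV
#' @param x an `adhesion_matrix`.
#' @param path file path.
#' @return `read_adhesion_matrix` returns the `adhesion_matrix`.
#' @export
write_adhesion_matrix <- function(x, path) {
  df <- data.frame(cell_type = rownames(x$AS), x$AS, check.names = FALSE)
  attr(df, "active_from_stage") <- x$active_from_stage
  utils::write.csv(cbind(df, active_from_stage = x$active_from_stage),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adhesion_matrix
#' @export
read_adhesion_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  afs <- df$active_from_stage[1]
  types <- df$cell_type
  AS <- as.matrix(df[, types, drop = FALSE])
  rownames(AS) <- types
  adhesion_matrix(AS, afs)
}
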