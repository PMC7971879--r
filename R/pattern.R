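## Pattern evaluation: Nanog/Gata6 fate classification, the ICM-pole ideal
## pattern, the normalized bipartite-matching loss score, the
## success/partial/failure outcome classifier and population ratios.

#' Classify Nanog/Gata6 fates
#'
#' Threshold classification of the four ICM expression states:
#' Nanog+ (`Nan >= theta_N`, `Gat < theta_G`), Gata6+ (converse),
#' DP (both high), DN (both low).
#'
#' @param genes gene matrix with `Nan` and `Gat` columns (or a named
#'   vector for one cell).
#' @param params parameter set holding `theta_N`, `theta_G`.
#' @return character vector of fates.
#' @export
classify_fate <- function(genes, params) {
  if (is.null(dim(genes)))
    genes <- matrix(genes, nrow = 1, dimnames = list(NULL, names(genes)))
  if (params$theta_N <= 0 || params$theta_G <= 0)
    stop("classification thresholds must be > 0")
  hN <- genes[, "Nan"] >= params$theta_N
  hG <- genes[, "Gat"] >= params$theta_G
  unname(ifelse(hN & hG, "DP",
                ifelse(hN, "Nanog+", ifelse(hG, "Gata6+", "DN"))))
}

#' ICM pole
#'
#' Reference point on the TE shell toward which the epiblast should
#' aggregate: `r * xbar / ||xbar||`, with `xbar` the mean ICM position
#' (embryo centered at the origin) and `r` the mean distance from TE
#' cells to the embryo center.
#'
#' @param icm_positions n x 3 matrix of ICM cell positions.
#' @param r mean TE distance from the center.
#' @return length-3 numeric vector with `||pole|| = r`.
#' @export
icm_pole <- function(icm_positions, r) {
  xbar <- colMeans(icm_positions)
  nx <- sqrt(sum(xbar^2))
  if (nx < 1e-12)
    stop("degenerate geometry: mean ICM position is at the origin")
  r * xbar / nx
}

#' Ideal Epi/PE assignment
#'
#' The `n_epi` ICM cells closest to the pole are labeled Epi, the rest
#' PE; distance ties are broken by ascending cell index.
#'
#' @param icm_positions n x 3 matrix.
#' @param pole length-3 vector.
#' @param n_epi number of Epi labels to assign (`0 <= n_epi <= n`).
#' @return character vector of `"Epi"` / `"PE"`.
#' @export
ideal_assignment <- function(icm_positions, pole, n_epi) {
  n <- nrow(icm_positions)
  stopifnot(n_epi >= 0, n_epi <= n)
  d <- sqrt(colSums((t(icm_positions) - pole)^2))
  ord <- order(d, seq_len(n))
  lab <- rep("PE", n)
  lab[ord[seq_len(n_epi)]] <- "Epi"
  lab
}

#' Minimum-cost perfect matching (Hungarian algorithm)
#'
#' Jonker-Volgenant style shortest augmenting path solver for a square
#' cost matrix; returns the column assigned to each row and the total
#' cost. Used by the loss score; validated in the test suite against a
#' brute-force permutation oracle.
#'
#' @param cost square numeric matrix.
#' @return list with `assignment` (column per row) and `cost`.
#' @export
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(list(assignment = integer(0), cost = 0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  ## potentials and matching, 1-based with a virtual 0 column
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1                  # virtual free column (index offset by 1)
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j] + 1] <- u[p[j] + 1] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assignment[p[j]] <- j - 1
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

## Matching cost between misplaced-Epi and misplaced-PE cells for a given
## model labeling against the ideal labeling.
mismatch_cost <- function(positions, model_labels, ideal_labels) {
  J1 <- which(model_labels == "Epi" & ideal_labels == "PE")
  J2 <- which(model_labels == "PE" & ideal_labels == "Epi")
  if (length(J1) != length(J2))
    stop("label sets are inconsistent: |J1| != |J2|")
  if (length(J1) == 0) return(0)
  cost <- outer(J1, J2, function(a, b)
    sqrt(rowSums((positions[a, , drop = FALSE] -
                    positions[b, , drop = FALSE])^2)))
  dim(cost) <- c(length(J1), length(J2))
  hungarian_assignment(cost)$cost
}

#' Embryo pattern loss score
#'
#' Quantifies how far a simulated Epi/PE labeling is from the ideal
#' pole-proximal pattern. Misplaced Epi cells (model Epi, ideal PE) are
#' matched one-to-one with misplaced PE cells (model PE, ideal Epi) by
#' minimum-cost bipartite matching under Euclidean distance; the cost is
#' normalized by the mean matching cost of `n_random` uniformly random
#' labelings with the same Epi count. An ideal pattern scores 0; random
#' labelings score 1 in expectation.
#'
#' @param icm_positions n x 3 matrix of ICM cell positions (embryo
#'   centered at the origin).
#' @param model_labels `"Epi"`/`"PE"` per cell.
#' @param r mean TE distance used for the pole (default: mean ICM radius
#'   is a poor substitute, so pass the TE value when available; defaults
#'   to `1` in zona units).
#' @param n_random Monte-Carlo sample size for the normalizer.
#' @param pole optionally a precomputed pole.
#' @return scalar loss (>= 0).
#' @export
loss_score <- function(icm_positions, model_labels, r = 1,
                       n_random = 200, pole = NULL) {
  stopifnot(all(model_labels %in% c("Epi", "PE")))
  n <- nrow(icm_positions)
  n_epi <- sum(model_labels == "Epi")
  if (is.null(pole)) pole <- icm_pole(icm_positions, r)
  ideal <- ideal_assignment(icm_positions, pole, n_epi)
  d_mdl <- mismatch_cost(icm_positions, model_labels, ideal)
  if (d_mdl == 0) return(0)
  d_rand <- vapply(seq_len(n_random), function(k) {
    lab <- rep("PE", n)
    lab[sample.int(n, n_epi)] <- "Epi"
    mismatch_cost(icm_positions, lab, ideal)
  }, numeric(1))
  dbar <- mean(d_rand)
  if (dbar <= 0)
    stop("degenerate normalization: random labelings have zero cost")
  d_mdl / dbar
}

#' Population ratios among ICM cells
#'
#' Fractions of Nanog+ / Gata6+ / DP / DN among the given fates.
#'
#' @param fates character vector of fates (ICM cells only).
#' @return named numeric vector summing to 1.
#' @export
population_ratios <- function(fates) {
  if (length(fates) == 0) stop("no ICM cells to tabulate")
  tab <- table(factor(fates, levels = c("Nanog+", "Gata6+", "DP", "DN")))
  out <- as.numeric(tab) / length(fates)
  names(out) <- names(tab)
  out
}

#' Outcome classification of an endpoint pattern
#'
#' Builds the Epi adjacency graph (centroid distance below the adjacency
#' radius), counts connected Epi components, and checks TE attachment
#' (some Epi cell adjacent to a TE cell) and PE coverage (fraction of Epi
#' cells shielded on their cavity-facing side by an adjacent PE -- or
#' deeper Epi -- cell). Success: one attached, covered Epi aggregate;
#' partial success: several aggregates, all attached and covered;
#' failure: anything else (salt-and-pepper, detached or uncovered
#' clusters).
#'
#' @param state an `embryo_state` at the endpoint.
#' @param params parameter set (adjacency radius and coverage threshold).
#' @param cavity_center cavity center (default from parameters).
#' @return list (`pattern_outcome`): `outcome`, `n_epi_aggregates`,
#'   `attached`, `coverage`.
#' @export
classify_outcome <- function(state, params = state$params,
                             cavity_center = c(0, 0, params$cavity_center_z)) {
  fates <- classify_fate(state$genes, params)
  icm <- which(state$lineage != "TE")
  te <- which(state$lineage == "TE")
  if (length(icm) == 0) stop("no ICM cells to classify")
  cen <- cell_centroids(state)
  epi_lab <- ifelse(fates[icm] %in% c("Nanog+", "DP"), "Epi", "PE")
  epi <- icm[epi_lab == "Epi"]
  pe <- icm[epi_lab == "PE"]
  radius <- params$adjacency_factor * cell_radius(params, n_cells(state))
  if (length(epi) == 0)
    return(structure(list(outcome = "failure", n_epi_aggregates = 0L,
                          attached = FALSE, coverage = 0),
                     class = "pattern_outcome"))
  d <- as.matrix(stats::dist(cen))
  adj <- d < radius
  ## connected components of the Epi graph (BFS)
  comp <- rep(0L, length(epi)); k <- 0L
  for (s in seq_along(epi)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- k
      nb <- which(adj[epi[v], epi] & comp == 0L)
      queue <- c(queue, nb)
    }
  }
  n_agg <- k
  attached_comp <- vapply(seq_len(k), function(ci) {
    members <- epi[comp == ci]
    length(te) > 0 && any(adj[members, te, drop = FALSE])
  }, logical(1))
  ## PE coverage: each Epi cell should be shielded toward the cavity by an
  ## adjacent PE cell (or by a deeper Epi cell of its aggregate).
  covered <- vapply(epi, function(i) {
    dir <- cavity_center - cen[i, ]
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-9) return(TRUE)
    dir <- dir / nd
    shields <- c(pe, setdiff(epi, i))
    if (length(shields) == 0) return(FALSE)
    near <- shields[adj[i, shields]]
    if (length(near) == 0) return(FALSE)
    proj <- as.numeric((cen[near, , drop = FALSE] -
                          matrix(cen[i, ], length(near), 3,
                                 byrow = TRUE)) %*% dir)
    any(proj > 0)
  }, logical(1))
  coverage <- mean(covered)
  ok_cover <- coverage >= params$pe_coverage_threshold
  outcome <- if (n_agg == 1 && attached_comp[1] && ok_cover) "success"
  else if (n_agg > 1 && all(attached_comp) && ok_cover) "partial"
  else "failure"
  structure(list(outcome = outcome, n_epi_aggregates = n_agg,
                 attached = all(attached_comp), coverage = coverage),
            class = "pattern_outcome")
}

#' Full pattern report for an endpoint state
#'
#' Computes the ICM pole, the normalized loss score of the simulated
#' Epi/PE labeling (Epi = Nanog-high: Nanog+ or DP), the outcome class
#' and the population ratios.
#'
#' @param state an `embryo_state` at the endpoint.
#' @param params parameter set.
#' @param n_random randomizations for the loss normalizer.
#' @return a `pattern_report` list.
#' @export
pattern_report <- function(state, params = state$params,
                           n_random = params$n_random) {
  fates <- classify_fate(state$genes, params)
  icm <- which(state$lineage != "TE")
  te <- which(state$lineage == "TE")
  if (length(icm) == 0) stop("no ICM cells to evaluate")
  cen <- cell_centroids(state)
  cen <- sweep(cen, 2, colMeans(cen))   # center the embryo
  r_te <- if (length(te)) mean(sqrt(rowSums(cen[te, , drop = FALSE]^2)))
          else params$embryo_radius
  labels <- ifelse(fates[icm] %in% c("Nanog+", "DP"), "Epi", "PE")
  pole <- icm_pole(cen[icm, , drop = FALSE], r_te)
  loss <- loss_score(cen[icm, , drop = FALSE], labels, r = r_te,
                     n_random = n_random, pole = pole)
  oc <- classify_outcome(state, params)
  structure(list(loss_score = loss,
                 outcome = oc$outcome,
                 n_epi_aggregates = oc$n_epi_aggregates,
                 ratios = population_ratios(fates[icm]),
                 icm_pole = pole,
                 n_icm = length(icm), n_te = length(te)),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(sprintf("<pattern_report> loss=%.3f outcome=%s aggregates=%d\n",
              x$loss_score, x$outcome, x$n_epi_aggregates))
  cat("  ICM ratios:",
      paste(sprintf("%s=%.2f", names(x$ratios), x$ratios), collapse = " "),
      sprintf(" (n_icm=%d, n_te=%d)\n", x$n_icm, x$n_te))
  invisible(x)
}

#' Fraction of Nanog-high cells highly expressing Gata6
#'
#' Among cells whose Nanog exceeds the Nanog-high threshold, the fraction
#' whose Gata6 also exceeds the Gata6-high threshold (equivalently
#' `DP / (DP + Nanog+)`). Under persistent Fgf signaling this fraction
#' stays elevated because aggregated Nanog-high cells keep perceiving
#' Fgf4 and re-express Gata6; attenuation at the 128-cell stage drives it
#' toward zero.
#'
#' @param genes gene matrix (ICM cells).
#' @param params parameter set.
#' @return scalar fraction in `[0, 1]` (`NaN` if no Nanog-high cells).
#' @export
nanog_high_gata6_fraction <- function(genes, params) {
  hN <- genes[, "Nan"] >= params$theta_N
  if (!any(hN)) return(NaN)
  mean(genes[hN, "Gat"] >= params$theta_G)
}
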