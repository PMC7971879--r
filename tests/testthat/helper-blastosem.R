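## Shared fixtures and independent oracles for the test suite.

## Small, fast parameter set used by most mechanics/driver tests.
test_params <- function(...) {
  default_parameters(elements_per_cell = 6, ...)
}

## Hand-built two-cell state at controlled centroid separation: each cell
## is a small isotropic element cloud. No simulation involved.
two_cell_state <- function(params = test_params(), sep = 0.4, seed = 7) {
  set.seed(seed)
  m <- params$elements_per_cell
  mk <- function(center, spread) {
    sweep(matrix(stats::rnorm(m * 3, sd = spread), m, 3), 2, center, `+`)
  }
  rc <- cell_radius(params, 2)
  pos <- rbind(mk(c(-sep / 2, 0, 0), 0.25 * rc),
               mk(c(+sep / 2, 0, 0), 0.25 * rc))
  st <- new_embryo(params, seed)
  st$pos <- pos
  st$element_cell <- rep(1:2, each = m)
  st$genes <- st$genes[c(1, 1), , drop = FALSE]
  st$lineage <- rep("ICM", 2)
  st$birth_time <- c(0, 0)
  st$division_due <- c(Inf, Inf)
  st
}

## Random packed multicell state (no dynamics): n cells on jittered grid.
random_state <- function(n, params = test_params(), seed = 11,
                         lineage = NULL) {
  set.seed(seed)
  m <- params$elements_per_cell
  rc <- cell_radius(params, n)
  dirs <- matrix(stats::rnorm(n * 3), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  centers <- dirs * (params$embryo_radius - rc) * stats::runif(n)^(1 / 3)
  pos <- do.call(rbind, lapply(seq_len(n), function(i) {
    sweep(matrix(stats::rnorm(m * 3, sd = 0.3 * rc), m, 3), 2,
          centers[i, ], `+`)
  }))
  st <- new_embryo(params, seed)
  st$pos <- pos
  st$element_cell <- rep(seq_len(n), each = m)
  st$genes <- st$genes[rep(1, n), , drop = FALSE]
  st$lineage <- if (is.null(lineage)) rep("ICM", n) else lineage
  st$birth_time <- rep(0, n)
  st$division_due <- rep(Inf, n)
  st
}

## Brute-force all-pairs neighbor oracle on centroids.
brute_neighbors <- function(state, cell_id, r_contact) {
  cen <- cell_centroids(state)
  out <- integer(0)
  for (j in seq_len(nrow(cen))) {
    if (j == cell_id) next
    if (sqrt(sum((cen[j, ] - cen[cell_id, ])^2)) < r_contact)
      out <- c(out, j)
  }
  out
}

## Independent transcription of the regulatory drift, written directly
## from the rate-law structure (kept deliberately separate from the
## package implementation).
oracle_drift <- function(g, Fp, eps, p) {
  N <- g[["Nan"]]; G <- g[["Gat"]]; Fr <- g[["Fr"]]; Fs <- g[["Fs"]]
  E <- g[["Erk"]]
  hill <- function(x, K, n) x^n / (K^n + x^n)
  inh <- function(x, K, n) K^n / (K^n + x^n)
  c(Nan = p$vsn0 + p$vsn1 * inh(eps * E, p$Kin1, p$u) +
      p$vsn2 * hill(N, p$Kan, p$v) * inh(G, p$Kin2, p$w) - p$kN * N,
    Gat = p$vsg0 + p$vsg1 * hill(eps * E, p$Kag1, p$r) +
      p$vsg2 * hill(G, p$Kag2, p$s) * inh(N, p$Kig, p$q) - p$kG * G,
    Fr = p$vsfr1 * inh(N, p$Kifr, p$x) + p$vsfr2 * hill(G, p$Kafr, p$y) -
      p$kFr * Fr,
    Fs = p$vsf * hill(N, p$Kaf, p$z) - p$kFs * Fs,
    Erk = p$va * Fr * (Fp / (p$Kd + Fp)) * ((1 - E) / (p$Ka + 1 - E)) -
      p$kErk * E / (p$Ki + E))
}

## Brute-force minimum matching cost over all permutations (|J1| <= 7).
brute_min_matching <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(0)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- Inf
  for (pp in perms(seq_len(n)))
    best <- min(best, sum(cost[cbind(seq_len(n), pp)]))
  best
}

## Central-difference gradient of a scalar function of the positions.
numerical_gradient <- function(f, pos, h = 1e-6) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos)))
    for (k in 1:3) {
      pp <- pos; pp[i, k] <- pp[i, k] + h
      pm <- pos; pm[i, k] <- pm[i, k] - h
      g[i, k] <- (f(pp) - f(pm)) / (2 * h)
    }
  g
}
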