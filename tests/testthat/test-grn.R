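p0 <- default_parameters()

test_that("drift at the zero state reduces to the basal synthesis rates", {
  g <- c(Nan = 0, Gat = 0, Fr = 0, Fs = 0, Erk = 0)
  d <- grn_derivatives(g, Fp = 0, eps_t = 1, p0)
  expect_equal(d[1, "Nan"], p0$vsn0 + p0$vsn1)
  expect_equal(d[1, "Gat"], p0$vsg0)
  expect_equal(d[1, "Fr"], p0$vsfr1)
  expect_equal(d[1, "Fs"], 0)
  expect_equal(d[1, "Erk"], 0)
})

test_that("Erk drift is nonpositive at the Erk = 1 boundary", {
  for (Fp in c(0, 0.5, 2)) {
    g <- c(Nan = 1, Gat = 1, Fr = 1, Fs = 0.5, Erk = 1)
    d <- grn_derivatives(g, Fp, 1, p0)
    expect_lte(d[1, "Erk"], 0)
  }
})

test_that("drift matches an independently transcribed evaluation", {
  set.seed(1)
  for (k in 1:25) {
    g <- stats::runif(5, 0, 3)
    names(g) <- c("Nan", "Gat", "Fr", "Fs", "Erk")
    Fp <- stats::runif(1, 0, 1.5)
    eps <- sample(c(0, 0.5, 1), 1)
    d <- grn_derivatives(g, Fp, eps, p0)
    o <- oracle_drift(as.list(g), Fp, eps, p0)
    expect_equal(unname(d[1, ]), unname(o), tolerance = 1e-12)
  }
  expect_error(grn_derivatives(c(Nan = -1, Gat = 0, Fr = 0, Fs = 0,
                                 Erk = 0), 0, 1, p0), "negative")
})

test_that("zero-noise stepping equals explicit Euler and is first order", {
  p <- default_parameters(sigmaN = 0, sigmaG = 0, sigmaFr = 0, sigmaFs = 0,
                          sigmaErk = 0)
  g <- matrix(c(1.2, 0.8, 0.5, 0.3, 0.2, 1, 1), 1, 7,
              dimnames = list(NULL, c("Nan", "Gat", "Fr", "Fs", "Erk",
                                      "Oct4", "Cdx2")))
  d <- grn_derivatives(g, 0.4, 1, p)
  stepped <- step_genes(g, 0.4, 1, 0.01, p)
  expect_equal(stepped[, 1:5], pmax(g[, 1:5] + d * 0.01, 0)[1, ],
               tolerance = 1e-14)
  expect_error(step_genes(g, 0.4, 1, -0.1, p), "dt")

  ## first-order convergence against a high-order adaptive oracle
  integrate_euler <- function(dt, Tend = 2) {
    x <- g
    for (i in seq_len(Tend / dt)) x <- step_genes(x, 0.4, 1, dt, p)
    x[1, 1:5]
  }
  oracle <- deSolve::ode(
    y = g[1, 1:5], times = c(0, 2),
    func = function(t, y, parms)
      list(grn_derivatives(matrix(y, 1, dimnames = list(NULL, names(y))),
                           0.4, 1, p)[1, ]),
    method = "lsoda", rtol = 1e-10, atol = 1e-12)
  ref <- oracle[2, -1]
  errs <- vapply(c(0.04, 0.02, 0.01),
                 function(dt) max(abs(integrate_euler(dt) - ref)),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  ## halving dt roughly halves the error
  expect_gt(errs[1] / errs[2], 1.5)
  expect_gt(errs[2] / errs[3], 1.5)
})

test_that("species stay nonnegative under the clamped noisy scheme", {
  p <- default_parameters(gene_noise_scale = 2)
  set.seed(99)
  g <- matrix(stats::runif(5 * 7, 0, 2), 5, 7,
              dimnames = list(NULL, c("Nan", "Gat", "Fr", "Fs", "Erk",
                                      "Oct4", "Cdx2")))
  for (i in 1:300) {
    g <- step_genes(g, stats::runif(5), 1, 0.02, p)
    expect_true(all(g >= 0))
  }
})

test_that("Erk stays in [0, 1] without noise", {
  p <- default_parameters(sigmaN = 0, sigmaG = 0, sigmaFr = 0, sigmaFs = 0,
                          sigmaErk = 0)
  g <- matrix(c(1, 1, 1.2, 0.5, 0.9, 1, 1), 1, 7,
              dimnames = list(NULL, c("Nan", "Gat", "Fr", "Fs", "Erk",
                                      "Oct4", "Cdx2")))
  for (i in 1:2000) {
    g <- step_genes(g, 1.5, 1, 0.02, p)
    expect_true(g[, "Erk"] >= 0 && g[, "Erk"] <= 1)
  }
})

test_that("epsilon schedule is piecewise constant in the stage", {
  s <- fgf_schedule(1, 128, epsilon_on = 1, epsilon_off = 0)
  expect_equal(epsilon_t(64, s), 1)
  expect_equal(epsilon_t(128, s), 0)
  late <- fgf_schedule(32, Inf)
  expect_equal(epsilon_t(16, late), late$epsilon_off)
  expect_equal(epsilon_t(32, late), late$epsilon_on)
  early_off <- fgf_schedule(1, 64)
  expect_equal(epsilon_t(100, early_off), early_off$epsilon_off)
  expect_error(fgf_schedule(64, 32), "on_stage")
})

test_that("perceived Fgf4 follows the neighbor-averaged secretion", {
  p <- test_params()
  st1 <- new_embryo(p, 1)
  expect_equal(perceived_fgf4(st1, p, sigma_gamma = 0), 0)
  ## two mutually neighboring cells: Fp_i = Fs_j / 1
  st2 <- two_cell_state(p, sep = 0.3 * contact_radius(p, 2))
  st2$genes[, "Fs"] <- c(0.8, 0.2)
  expect_equal(unname(perceived_fgf4(st2, p, sigma_gamma = 0)),
               c(0.2, 0.8))
  ## 8-cell cluster vs brute-force evaluation
  st8 <- random_state(8, p, seed = 21)
  st8$genes[, "Fs"] <- stats::runif(8)
  rc <- contact_radius(p, 8)
  Fp <- perceived_fgf4(st8, p, sigma_gamma = 0)
  for (i in 1:8) {
    expected <- 0
    for (j in brute_neighbors(st8, i, rc)) {
      Nj <- length(brute_neighbors(st8, j, rc))
      expected <- expected + st8$genes[j, "Fs"] / Nj
    }
    expect_equal(unname(Fp[i]), unname(expected), tolerance = 1e-12)
  }
})

test_that("signaling can be restricted to a subpopulation", {
  p <- test_params()
  st <- random_state(8, p, seed = 21)
  st$genes[, "Fs"] <- 1
  sub <- c(1L, 2L, 3L)
  Fp <- perceived_fgf4(st, p, sigma_gamma = 0, subset = sub)
  expect_true(all(Fp[setdiff(1:8, sub)] == 0))
})

test_that("Oct4/Cdx2 toggle resolves by contact exposure", {
  p <- default_parameters()
  g0 <- matrix(c(0, 0, 0, 0, 0, 1, 1), 1, 7,
               dimnames = list(NULL, c("Nan", "Gat", "Fr", "Fs", "Erk",
                                       "Oct4", "Cdx2")))
  run <- function(cf) {
    g <- g0
    for (i in 1:3000) g <- te_icm_step(g, cf, 0.02, p, noise = FALSE)
    g[1, c("Oct4", "Cdx2")]
  }
  interior <- run(1)
  exterior <- run(0)
  expect_gt(interior["Oct4"], interior["Cdx2"])
  expect_gt(exterior["Cdx2"], exterior["Oct4"])
  expect_error(te_icm_step(g0, 1.5, 0.02, p), "contact_fraction")
})

test_that("Fgf/Erk coupling drives the fate switch (bistability sweep)", {
  p <- default_parameters(sigmaN = 0, sigmaG = 0, sigmaFr = 0, sigmaFs = 0,
                          sigmaErk = 0)
  integrate <- function(eps, Fp, Tend = 300) {
    g <- matrix(c(p$init_Nan, p$init_Gat, p$init_Fr, p$init_Fs, p$init_Erk,
                  1, 1), 1, 7,
                dimnames = list(NULL, c("Nan", "Gat", "Fr", "Fs", "Erk",
                                        "Oct4", "Cdx2")))
    for (i in seq_len(Tend / 0.05)) g <- step_genes(g, Fp, eps, 0.05, p)
    classify_fate(g, p)
  }
  ## signaling off: Nanog-high is the only outcome ("only Nanog+ cells
  ## exist when Fgf signaling is off")
  expect_equal(integrate(0, 0), "Nanog+")
  expect_equal(integrate(0, 0.9), "Nanog+")
  ## signaling on with strong perceived Fgf4: Gata6-high
  expect_equal(integrate(1, 0.9), "Gata6+")
})

test_that("mutual inhibition alone cannot separate Nanog+ and Gata6+", {
  ## disable the Erk coupling and sweep basal rates: the deterministic
  ## flow from co-expressing initial states never splits a population --
  ## every basal-rate combination sends all such cells to one dominated
  ## outcome (Nanog+, Gata6+ or DP), so there is no controlled
  ## Nanog+/Gata6+ separation without Fgf signaling
  set.seed(5)
  for (basal in list(c(0.05, 0.05), c(0.3, 0.05), c(0.05, 0.3),
                     c(0.3, 0.3))) {
    p <- default_parameters(va = 0, vsn0 = basal[1], vsg0 = basal[2],
                            sigmaN = 0, sigmaG = 0, sigmaFr = 0,
                            sigmaFs = 0, sigmaErk = 0)
    n <- 10
    g <- matrix(rep(c(p$init_Nan, p$init_Gat, p$init_Fr, p$init_Fs,
                      p$init_Erk, 1, 1), each = n), n, 7,
                dimnames = list(NULL, c("Nan", "Gat", "Fr", "Fs", "Erk",
                                        "Oct4", "Cdx2")))
    for (i in 1:3000) g <- step_genes(g, 0.5, 1, 0.02, p)
    fates <- classify_fate(g, p)
    ## the deterministic flow sends the whole co-expressing population to
    ## a single dominated outcome; no Nanog+/Gata6+ separation arises
    expect_equal(length(unique(fates)), 1L)
    expect_false(all(c("Nanog+", "Gata6+") %in% fates))
  }
})
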