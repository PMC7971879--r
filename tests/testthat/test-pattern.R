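p <- default_parameters()

test_that("fate classification follows the two thresholds", {
  tN <- p$theta_N; tG <- p$theta_G
  g <- rbind(c(Nan = tN + 1, Gat = tG + 1),  # both high
             c(Nan = 0, Gat = 0),            # both low
             c(Nan = tN + 1, Gat = 0),
             c(Nan = 0, Gat = tG + 1),
             c(Nan = tN, Gat = tG))          # boundary: inclusive
  expect_equal(classify_fate(g, p),
               c("DP", "DN", "Nanog+", "Gata6+", "DP"))
})

test_that("threshold sweep matches an independent re-classification", {
  set.seed(12)
  g <- cbind(Nan = stats::runif(200, 0, 3), Gat = stats::runif(200, 0, 3))
  for (tN in c(0.5, 1.5, 2.5)) for (tG in c(0.4, 1, 2)) {
    q <- default_parameters(theta_N = tN, theta_G = tG)
    got <- population_ratios(classify_fate(g, q))
    hN <- g[, "Nan"] >= tN; hG <- g[, "Gat"] >= tG
    expect_equal(unname(got),
                 c(mean(hN & !hG), mean(hG & !hN), mean(hN & hG),
                   mean(!hN & !hG)))
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("population ratios: direct arithmetic and error contract", {
  expect_equal(unname(population_ratios(rep("Nanog+", 7))), c(1, 0, 0, 0))
  expect_equal(unname(population_ratios(c(rep("Nanog+", 2),
                                          rep("Gata6+", 3)))),
               c(0.4, 0.6, 0, 0))
  expect_error(population_ratios(character(0)), "no ICM")
})

test_that("the ICM pole sits at distance r along the mean ICM direction", {
  pos <- matrix(rep(c(0.3, 0, 0), 5), 5, 3, byrow = TRUE)
  expect_equal(icm_pole(pos, 1), c(1, 0, 0))
  set.seed(8)
  pos2 <- matrix(stats::rnorm(30, mean = 0.2), 10, 3)
  for (r in c(0.5, 1, 2))
    expect_equal(sqrt(sum(icm_pole(pos2, r)^2)), r, tolerance = 1e-12)
  sym <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_error(icm_pole(sym, 1), "degenerate")
})

test_that("ideal assignment labels the pole-closest cells Epi", {
  set.seed(3)
  pos <- matrix(stats::rnorm(30), 10, 3)
  pole <- c(2, 0, 0)
  expect_equal(ideal_assignment(pos, pole, 0), rep("PE", 10))
  expect_equal(ideal_assignment(pos, pole, 10), rep("Epi", 10))
  lab <- ideal_assignment(pos, pole, 4)
  d <- sqrt(colSums((t(pos) - pole)^2))
  expect_equal(which(lab == "Epi"), sort(order(d)[1:4]))
})

test_that("Hungarian matching equals the brute-force permutation minimum", {
  set.seed(42)
  for (trial in 1:1000) {
    n <- sample(1:6, 1)
    cost <- matrix(stats::runif(n * n, 0, 10), n, n)
    h <- hungarian_assignment(cost)
    expect_equal(h$cost, brute_min_matching(cost), tolerance = 1e-10)
    expect_equal(sort(h$assignment), 1:n)
  }
})

test_that("a pattern identical to the ideal assignment has zero loss", {
  set.seed(5)
  for (trial in 1:20) {
    pos <- matrix(stats::rnorm(60, mean = 0.3), 20, 3)
    pole <- icm_pole(pos, 1)
    n_epi <- sample(3:17, 1)
    ideal <- ideal_assignment(pos, pole, n_epi)
    expect_equal(loss_score(pos, ideal, r = 1, n_random = 10), 0)
  }
})

test_that("random labelings have expected loss 1 (within 2 SE)", {
  set.seed(9)
  pos <- matrix(stats::rnorm(60, mean = 0.25), 20, 3)
  n_epi <- 8
  pole <- icm_pole(pos, 1)
  losses <- replicate(300, {
    lab <- rep("PE", 20)
    lab[sample.int(20, n_epi)] <- "Epi"
    loss_score(pos, lab, r = 1, n_random = 200, pole = pole)
  })
  se <- stats::sd(losses) / sqrt(length(losses))
  expect_lt(abs(mean(losses) - 1), 2 * se + 0.02)
})

test_that("the loss score is invariant under rigid motions", {
  set.seed(14)
  pos <- matrix(stats::rnorm(45, mean = 0.3), 15, 3)
  lab <- sample(c("Epi", "PE"), 15, replace = TRUE, prob = c(0.4, 0.6))
  ## rotation about z by 40 degrees
  th <- 40 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  set.seed(100); l1 <- loss_score(pos, lab, r = 1, n_random = 300)
  set.seed(100); l2 <- loss_score(pos %*% t(R), lab, r = 1, n_random = 300)
  expect_equal(l1, l2, tolerance = 0.05)
})

test_that("outcome classification separates the three pattern classes", {
  q <- test_params(elements_per_cell = 3)
  build <- function(centers, lineage, fates) {
    n <- nrow(centers)
    st <- random_state(n, q, seed = 1, lineage = lineage)
    m <- q$elements_per_cell
    for (i in seq_len(n))
      st$pos[st$element_cell == i, ] <-
        sweep(matrix(stats::rnorm(m * 3, sd = 0.005), m, 3), 2,
              centers[i, ], `+`)
    ## encode requested fates through the gene state
    st$genes[, "Nan"] <- ifelse(fates == "Epi", q$theta_N + 1, 0)
    st$genes[, "Gat"] <- ifelse(fates == "Epi", 0, q$theta_G + 1)
    st
  }
  block <- function(x0, z, nx = 2, ny = 2, sp) {
    g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
    cbind(x0 + g$x * sp, g$y * sp, z)
  }
  ## distances in units of the nominal cell radius at this cell count
  n_tot <- 17
  rc <- blastosem:::cell_radius(q, n_tot)
  sp <- 1.2 * rc  # adjacent under the 1.5 rc adjacency radius
  cavity <- c(0, 0, -20 * rc)
  ## success: TE sheet on top, one Epi block attached beneath it, PE
  ## layer covering the Epi toward the cavity
  te <- block(0, 1.2 * rc, 3, 3, sp)
  epi <- block(0, 0, 2, 2, sp)
  pe <- block(0, -1.2 * rc, 2, 2, sp)
  st <- build(rbind(te, epi, pe),
              c(rep("TE", 9), rep("ICM", 8)),
              c(rep("PE", 9), rep("Epi", 4), rep("PE", 4)))
  out <- classify_outcome(st, q, cavity_center = cavity)
  expect_equal(out$n_epi_aggregates, 1L)
  expect_equal(out$outcome, "success")

  ## partial: a second attached, covered Epi block far to the side;
  ## geometry rebuilt at this scene's cell count so the blocks stay
  ## adjacent under the stage-scaled adjacency radius
  rc2 <- blastosem:::cell_radius(q, 34)
  sp2 <- 1.2 * rc2
  te2 <- block(0, 1.2 * rc2, 3, 3, sp2)
  epi2 <- block(0, 0, 2, 2, sp2)
  pe2 <- block(0, -1.2 * rc2, 2, 2, sp2)
  shift <- 12 * rc2
  sh <- function(m) { m[, 1] <- m[, 1] + shift; m }
  st2 <- build(rbind(te2, epi2, pe2, sh(te2), sh(epi2), sh(pe2)),
               c(rep("TE", 9), rep("ICM", 8), rep("TE", 9), rep("ICM", 8)),
               c(rep("PE", 9), rep("Epi", 4), rep("PE", 4),
                 rep("PE", 9), rep("Epi", 4), rep("PE", 4)))
  out2 <- classify_outcome(st2, q, cavity_center = cavity)
  expect_equal(out2$n_epi_aggregates, 2L)
  expect_equal(out2$outcome, "partial")

  ## failure: alternating Epi/PE lattice detached from the TE
  gx <- expand.grid(x = 0:3, y = 0:3)
  lat <- cbind(gx$x * sp, gx$y * sp, -8 * rc)
  fates3 <- ifelse((gx$x + gx$y) %% 2 == 0, "Epi", "PE")
  st3 <- build(rbind(te, lat), c(rep("TE", 9), rep("ICM", 16)),
               c(rep("PE", 9), fates3))
  out3 <- classify_outcome(st3, q, cavity_center = cavity)
  expect_equal(out3$outcome, "failure")
  expect_gt(out3$n_epi_aggregates, 1L)
  ## error contract: no ICM
  st4 <- st; st4$lineage <- rep("TE", 17)
  expect_error(classify_outcome(st4, q), "no ICM")
})

test_that("nanog-high Gata6 co-expression fraction counts DP share", {
  g <- rbind(c(Nan = 2.5, Gat = 0.1), c(Nan = 2.2, Gat = 1.5),
             c(Nan = 0.2, Gat = 2.0), c(Nan = 2.0, Gat = 0.9))
  ## among the three Nanog-high cells, two exceed the Gata6 threshold
  expect_equal(nanog_high_gata6_fraction(g, p), 2 / 3)
  lowN <- rbind(c(Nan = 0.1, Gat = 2))
  expect_true(is.nan(nanog_high_gata6_fraction(lowN, p)))
})
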