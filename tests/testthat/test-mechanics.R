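p <- test_params()

test_that("two same-cell elements at the equilibrium distance feel no force", {
  st <- new_embryo(p, 1)
  ff <- blastosem:::force_field(p, 1)
  st$pos <- rbind(c(0, 0, 0), c(ff$re_intra, 0, 0))
  st$element_cell <- c(1L, 1L)
  F <- intra_forces(st, p)
  expect_lt(max(abs(F)), 1e-10)
})

test_that("internal forces obey action-reaction (momentum conservation)", {
  st <- random_state(6, p, seed = 2)
  fates <- rep("Gata6+", 6)
  Fi <- intra_forces(st, p)
  Fe <- inter_forces(st, p, hypothesis_matrix("H5", p), fates)
  expect_lt(max(abs(colSums(Fi))), 1e-10)
  expect_lt(max(abs(colSums(Fe))), 1e-10)
  expect_lt(max(abs(colSums(Fi + Fe))), 1e-10)
})

test_that("intra forces equal the numerical gradient of the potential", {
  set.seed(4)
  st <- new_embryo(p, 1)
  rc <- cell_radius(p, 1)
  st$pos <- matrix(stats::rnorm(10 * 3, sd = 0.3 * rc), 10, 3)
  st$element_cell <- rep(1L, 10)
  zf <- test_params(zona_stiffness = 0)  # pair terms only
  F <- intra_forces(st, zf)
  num <- numerical_gradient(function(pp) {
    s2 <- st; s2$pos <- pp
    potential_energy(s2, zf)
  }, st$pos)
  expect_equal(F, -num, tolerance = 1e-5)
})

test_that("inter forces match the gradient of the adhesion-scaled potential", {
  zf <- test_params(zona_stiffness = 0)
  st <- random_state(4, zf, seed = 6)
  st$lineage <- rep("ICM", 4)
  fates <- c("Nanog+", "Gata6+", "DP", "Nanog+")
  adh <- hypothesis_matrix("H5", zf)
  F <- intra_forces(st, zf) + inter_forces(st, zf, adh, fates)
  num <- numerical_gradient(function(pp) {
    s2 <- st; s2$pos <- pp
    potential_energy(s2, zf, adh, fates)
  }, st$pos)
  expect_equal(F, -num, tolerance = 1e-4)
})

test_that("adhesion scales only the attractive force component linearly", {
  st <- two_cell_state(p, sep = 1.1 * contact_radius(p, 2) / p$r_contact_factor)
  st$lineage <- rep("ICM", 2)
  fates <- c("Nanog+", "Nanog+")
  mk <- function(a) {
    AS <- matrix(a, 1, 1, dimnames = list("Nanog+", "Nanog+"))
    adhesion_matrix(blastosem:::te_rows(AS, p), active_from_stage = 1)
  }
  F1 <- inter_forces(st, p, mk(1), fates)
  F2 <- inter_forces(st, p, mk(2), fates)
  F0 <- inter_forces(st, p, mk(1e-9), fates)  # repulsion-only limit
  attr1 <- F1 - F0
  attr2 <- F2 - F0
  expect_equal(attr2, 2 * attr1, tolerance = 1e-6)
})

test_that("uniform adhesion equals the unscaled inter-force computation", {
  st <- random_state(5, p, seed = 8)
  fates <- c("Nanog+", "Gata6+", "DP", "DN", "Nanog+")
  h1 <- hypothesis_matrix("H1", p)
  expect_equal(inter_forces(st, p, NULL, fates),
               inter_forces(st, p, h1, fates))
})

test_that("external forces confine at the zona and expel from the cavity", {
  st <- new_embryo(p, 1)
  st$pos <- rbind(c(0.5, 0, 0),               # inside zona
                  c(1.4, 0, 0),               # outside zona
                  c(0, 0, p$cavity_center_z)) # at the cavity center
  st$element_cell <- rep(1L, 3)
  F0 <- external_forces(st, p, cavity_r = 0)
  expect_equal(F0[1, ], c(0, 0, 0))
  expect_lt(F0[2, 1], 0)  # restoring force points inward
  Fc <- external_forces(st, p, cavity_r = 0.3)
  expect_gt(sqrt(sum(Fc[3, ]^2)), 0)  # expelled from the cavity sphere
  ## sign check against the potential gradient
  st$pos <- matrix(c(0.05, 0, p$cavity_center_z + 0.1), 1, 3)
  st$element_cell <- 1L
  num <- numerical_gradient(function(pp) {
    s2 <- st; s2$pos <- pp
    potential_energy(s2, p, cavity_r = 0.3)
  }, st$pos)
  expect_equal(external_forces(st, p, cavity_r = 0.3), -num,
               tolerance = 1e-4)
})

test_that("zero-noise relaxation does not increase the potential energy", {
  q <- test_params(sigma_move = 0)
  st <- two_cell_state(q, sep = 0.5, seed = 3)
  st$lineage <- rep("ICM", 2)
  e_prev <- potential_energy(st, q)
  for (i in 1:200) {
    F <- intra_forces(st, q) + inter_forces(st, q) + external_forces(st, q)
    st <- step_positions(st, F, 0.005, q, noise_scale = 0)
    e <- potential_energy(st, q)
    expect_lte(e, e_prev + 1e-9)
    e_prev <- e
  }
})

test_that("position update contracts: no force, no noise, no movement", {
  st <- random_state(3, p, seed = 1)
  F <- matrix(0, nrow(st$pos), 3)
  st2 <- step_positions(st, F, 0.1, p, noise_scale = 0)
  expect_identical(st2$pos, st$pos)
  F[2, 1] <- NaN
  expect_error(step_positions(st, F, 0.1, p), "element 2")
})

test_that("division conserves elements and copies the gene state", {
  q <- test_params(elements_per_cell = 20)
  st <- new_embryo(q, 5)
  st$genes[1, "Nan"] <- 2.5
  before <- st$genes[1, ]
  set.seed(10)
  st2 <- divide_cell(st, 1)
  expect_equal(n_cells(st2), 2)
  ## partition: first 20 elements are the mother's, split between the two
  own <- st2$element_cell[1:20]
  expect_setequal(unique(own), c(1L, 2L))
  expect_equal(sum(own == 1L), 10)
  expect_equal(sum(own == 2L), 10)
  ## replenished back to the target count
  expect_equal(length(elements_of(st2, 1)), 20)
  expect_equal(length(elements_of(st2, 2)), 20)
  expect_equal(st2$genes[1, ], before)
  expect_equal(st2$genes[2, ], before)
  tiny <- st; tiny$pos <- tiny$pos[1, , drop = FALSE]
  tiny$element_cell <- 1L
  expect_error(divide_cell(tiny, 1), "fewer than 2")
})

test_that("daughter centroids straddle the mother centroid", {
  q <- test_params(elements_per_cell = 20)
  set.seed(77)
  devs <- replicate(100, {
    st <- new_embryo(q, sample.int(1e6, 1))
    mother <- colMeans(st$pos)
    st2 <- divide_cell(st, 1)
    cen <- cell_centroids(st2)
    mid <- colMeans(cen)
    sqrt(sum((mid - mother)^2))
  })
  expect_lt(mean(devs), 0.1 * cell_radius(q, 1))
})

test_that("the cleavage schedule is synchronous to 32 then windowed", {
  q <- test_params()
  st <- new_embryo(q, 1)
  expect_equal(st$division_due, q$stage_duration)
  ## no divisions due before the due time
  expect_length(division_scheduler(st, q), 0)
  st$time <- q$stage_duration
  expect_equal(division_scheduler(st, q), 1L)
  ## synchronous reassignment under 32 cells
  st8 <- random_state(8, q, seed = 4)
  st8$time <- 20
  st8$division_due <- rep(Inf, 8)
  st8 <- schedule_divisions(st8, q)
  expect_true(all(st8$division_due == 20 + q$stage_duration))
  st8$time <- 20 + q$stage_duration
  expect_equal(division_scheduler(st8, q), 1:8)
  ## windowed at 64: i.i.d. uniform in the configured window
  set.seed(2)
  st64 <- random_state(64, test_params(elements_per_cell = 3), seed = 4)
  st64$time <- 50
  st64$division_due <- rep(Inf, 64)
  st64 <- schedule_divisions(st64, q)
  d <- st64$division_due - 50
  expect_true(all(d >= q$div_window_start & d <= q$div_window_end))
  expect_gt(length(unique(d)), 32)  # not synchronous
  ks <- suppressWarnings(stats::ks.test(
    (d - q$div_window_start) / (q$div_window_end - q$div_window_start),
    "punif"))
  expect_gt(ks$p.value, 0.01)
  ## terminal stage: never due again
  st128 <- random_state(128, test_params(elements_per_cell = 3), seed = 4)
  st128$time <- 99
  st128 <- schedule_divisions(st128, q)
  expect_true(all(!is.finite(st128$division_due)))
  expect_length(division_scheduler(st128, q), 0)
})
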