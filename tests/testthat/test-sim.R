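test_that("initial population size follows the effective-cell formula", {
  pop <- init_population(170000, 0.89, diversity = 8e6, seed = 1)
  expect_equal(pop$n_clones, round(170000 * (1 - exp(-0.89))))
  expect_equal(pop$n_clones, 100189)
  # MOI -> infinity saturates at the seeded count
  expect_equal(init_population(500, 50, diversity = 10, seed = 1)$n_clones,
               500)
  expect_error(init_population(10, 1e-9, diversity = 10), "no effective")
})

test_that("integration counts are zero-truncated Poisson", {
  pop <- init_population(50000, 0.89, diversity = 8e6, seed = 2)
  k <- lengths(split(pop$clone_barcodes$barcode, pop$clone_barcodes$clone))
  expect_true(all(k >= 1))
  kbar_expected <- 0.89 / (1 - exp(-0.89))
  expect_equal(mean(k), kbar_expected, tolerance = 0.02)
  # vanishing MOI: everyone has exactly one integration
  tiny <- init_population(1e9, 1e-6, diversity = 100, seed = 3)
  expect_true(all(lengths(split(tiny$clone_barcodes$barcode,
                                tiny$clone_barcodes$clone)) == 1))
  # forced single-integration reference mode
  single <- init_population(50000, 0.89, diversity = 8e6, seed = 4,
                            integration_model = "single")
  expect_equal(length(single$clone_barcodes$barcode), single$n_clones)
})

test_that("unrelated-cell barcode collisions match the birthday count", {
  # N0 = 1e5 single-integration cells over D = 8e6 barcodes:
  # expected duplicated draws ~ choose(N0,2)/D ~ 625
  n_seeded <- round(1e5 / (1 - exp(-0.89)))
  pop <- init_population(n_seeded, 0.89, diversity = 8e6, seed = 5,
                         integration_model = "single")
  n0 <- pop$n_clones
  expected <- choose(n0, 2) / 8e6
  observed <- sum(duplicated(pop$clone_barcodes$barcode))
  expect_equal(observed, expected, tolerance = 3 * sqrt(expected) / expected)
})

test_that("division replaces each cell by its drawn progeny", {
  pop <- init_population(1000, 1, diversity = 1e4, seed = 6)
  p2 <- setNames(c(0, 0, 1, rep(0, 6)), 0:8)
  doubled <- divide_cells(pop, p2, seed = 7)
  expect_equal(length(doubled$clone), 2 * pop$n_clones)
  expect_true(all(doubled$class == 2L))
  p0 <- setNames(c(1, rep(0, 8)), 0:8)
  expect_length(divide_cells(pop, p0, seed = 8)$clone, 0)
  expect_error(divide_cells(pop, rep(0.2, 9)), "sum to 1")
})

test_that("empirical progeny-class frequencies match the distribution", {
  pop <- init_population(170000, 0.89, diversity = 8e6, seed = 9)
  pr <- default_progeny_prob()
  kids <- divide_cells(pop, pr, seed = 10)
  # class frequencies among progenitors: recover k draws from progeny
  k_per_clone <- tapply(kids$class, kids$clone, unique)
  freq <- tabulate(unlist(k_per_clone) + 1L, nbins = 9) /
    length(k_per_clone)
  cond <- pr[-1] / sum(pr[-1]) # class 0 leaves no progeny to observe
  for (k in 1:8) {
    se <- sqrt(cond[k] * (1 - cond[k]) / length(k_per_clone))
    expect_lt(abs(freq[k + 1] - cond[k]), 5 * se + 1e-3)
  }
})

test_that("plating is uniform and splits sisters 75% of the time", {
  pop <- init_population(40000, 1, diversity = 1e6, seed = 11)
  p2 <- setNames(c(0, 0, 1, rep(0, 6)), 0:8)
  kids <- plate_cells(divide_cells(pop, p2, seed = 12), seed = 13)
  expect_equal(unname(tabulate(kids$dish, 4) / length(kids$dish)),
               rep(0.25, 4), tolerance = 0.02)
  split_frac <- mean(tapply(kids$dish, kids$clone,
                            function(d) d[1] != d[2]))
  expect_equal(split_frac, 0.75, tolerance = 0.01)
  # plating an empty population is a no-op
  empty <- divide_cells(pop, setNames(c(1, rep(0, 8)), 0:8), seed = 1)
  expect_length(plate_cells(empty)$dish, 0)
})

test_that("loss removes a fixed count per dish without class bias", {
  pop <- init_population(10000, 1, diversity = 1e6, seed = 14)
  kids <- plate_cells(divide_cells(pop, seed = 15), seed = 16)
  expect_identical(cull_cells(kids, 0), kids)
  culled <- cull_cells(kids, 0.5, seed = 17)
  for (d in 1:4) {
    n_before <- sum(kids$dish == d)
    expect_equal(sum(culled$dish == d), n_before - round(0.5 * n_before))
  }
  # survivors are an unbiased sample of progeny classes
  p_before <- tabulate(kids$class, 8) / length(kids$class)
  p_after <- tabulate(culled$class, 8) / length(culled$class)
  expect_equal(p_after, p_before, tolerance = 0.05)
})

test_that("fixed Gaussian targets give each dish exactly mu barcodes", {
  # single-integration cells: quotas are exact (multi-integration cells
  # can overshoot a quota by at most their extra integrations)
  pop <- init_population(20000, 0.6, diversity = 1e6, seed = 18,
                         integration_model = "single")
  kids <- plate_cells(divide_cells(pop, seed = 19), seed = 20)
  rp <- reprogram_cells(kids, mu = 50, si = 0, heritability = 0,
                        seed = 21)
  ov <- attr(rp, "overlaps")
  expect_equal(unname(ov$ba), rep(50L, 4))
  expect_equal(unname(ov$per_dish), rep(50L, 4))
  # under the final-count quota, every dish reaches its target even with
  # inheritance on; overshoot can come only from sisters flagged after a
  # dish met its quota
  rp2 <- reprogram_cells(kids, mu = 50, si = 0, heritability = 0.5,
                         seed = 22, quota = "final")
  pd2 <- unname(attr(rp2, "overlaps")$per_dish)
  expect_true(all(pd2 >= 50L))
  expect_lt(mean(pd2 - 50L), 15)
  # under the stage-1 quota, sister flags can push counts beyond it
  rp3 <- reprogram_cells(kids, mu = 50, si = 0, heritability = 0.5,
                         seed = 22, quota = "stage1")
  expect_equal(unname(attr(rp3, "overlaps")$ba), rep(50L, 4))
  expect_true(all(attr(rp3, "overlaps")$per_dish >= 50L))
})

test_that("infeasible dish targets are clamped with a flag or rejected", {
  pop <- init_population(100, 0.6, diversity = 1e6, seed = 23)
  kids <- plate_cells(divide_cells(pop, seed = 24), seed = 25)
  rp <- reprogram_cells(kids, mu = 1e5, si = 0, heritability = 0,
                        seed = 26)
  expect_true(all(attr(rp, "overlaps")$clamped))
  expect_error(
    reprogram_cells(kids, mu = 1e5, si = 0, heritability = 0, seed = 26,
                    on_infeasible = "error"),
    "exceeds")
})

test_that("replicated runs are seed-deterministic and conserve cells", {
  p <- sim_params(5000, 0.6, diversity = 1e5, loss = 0.2,
                  heritability = 0.2, mu = 80, si = 10)
  s1 <- run_simulation(p, replicates = 5, seed = 27)
  s2 <- run_simulation(p, replicates = 5, seed = 27)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(attr(s1, "contribution"), attr(s2, "contribution"))
})

test_that("overlap counts partition shared barcodes by dish multiplicity", {
  p <- sim_params(5000, 0.6, diversity = 1e5, heritability = 0.4,
                  mu = 100, si = 10)
  s <- run_simulation(p, replicates = 10, seed = 28)
  expect_equal(s$shared, s$exactly2 + s$exactly3 + s$exactly4)
  expect_true(all(s$shared >= 0))
})

test_that("overlaps are counted at barcode level: one clone, k shared", {
  # a triple-integration clone whose two sisters reprogramme in two
  # dishes shows up as three shared barcodes, not one
  pop <- structure(list(
    clone = c(1L, 1L),
    class = c(2L, 2L),
    dish = c(1L, 2L),
    reprog = c(FALSE, FALSE),
    stage1 = c(FALSE, FALSE),
    n_clones = 1L,
    clone_barcodes = list(clone = c(1L, 1L, 1L), barcode = c(4L, 9L, 2L))
  ), class = "cell_population")
  rp <- reprogram_cells(pop, dish_targets = c(3L, 0L, 0L, 0L),
                        heritability = 1, seed = 1)
  ov <- attr(rp, "overlaps")
  expect_equal(ov$shared, 3L)
  expect_equal(unname(ov$exactly["2"]), 3L)
})

test_that("vanishing MOI reproduces the single-integration reference", {
  base <- list(n_seeded = 20000, moi = 1e-4, diversity = 5e4,
               loss = 0, heritability = 0.3, mu = 50, si = 0)
  # n_seeded scaled so both modes track the same effective population
  base$n_seeded <- round(2000 / (1 - exp(-base$moi)))
  p_tiny <- do.call(sim_params, c(base, integration_model = "ztpois"))
  p_single <- do.call(sim_params, c(base, integration_model = "single"))
  s_tiny <- run_simulation(p_tiny, replicates = 20, seed = 29)
  s_single <- run_simulation(p_single, replicates = 20, seed = 30)
  expect_equal(mean(s_tiny$shared), mean(s_single$shared),
               tolerance = 0.25)
})

test_that("the post-hoc correction divides by the mean integration count", {
  p_corr <- sim_params(20000, 1.2, diversity = 5e4, heritability = 0,
                       mu = 200, si = 0, integration_model = "ztpois",
                       correct_multi = TRUE)
  s_corr <- run_simulation(p_corr, replicates = 5, seed = 31)
  kbar <- 1.2 / (1 - exp(-1.2))
  expect_equal(s_corr$shared_corrected, s_corr$shared / kbar)
})

test_that("progeny-class-specific heritability routes overlap contributions", {
  # only class-4 clones inherit fate: their contribution share must rise
  h_map <- c("4" = 0.8, "default" = 0)
  p <- sim_params(10000, 0.6, diversity = 1e6, heritability = h_map,
                  mu = 60, si = 0)
  s <- run_simulation(p, replicates = 10, seed = 31)
  rep_share <- contribution_report(s)
  expect_equal(sum(rep_share$share), 1, tolerance = 1e-9)
  expect_gt(rep_share$share[rep_share$class == 4],
            rep_share$population_fraction[rep_share$class == 4])
})
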