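test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(roost_config(n_individuals = 10, community_sizes = c(3, 3)),
               "sum\\(community_sizes\\)")
  expect_error(roost_config(p_detect = 1.2), "p_detect")
  expect_error(roost_config(p_drift = -0.1), "p_drift")
  expect_error(roost_config(n_individuals = 9, community_sizes = c(3, 3, 3),
                            n_roosts = 2), "n_roosts")
  expect_error(roost_config(n_days = 0), "n_days")
})

test_that("generation is deterministic given the seed", {
  cfg <- roost_config(n_individuals = 30, community_sizes = c(10, 10, 10),
                      n_days = 60, n_roosts = 6, p_detect = 0.5,
                      p_drift = 0.1, p_fission = 0.2, seed = 1)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$partition$membership, b$partition$membership)
  c <- generate_population(cfg, seed = 2)
  expect_false(identical(a$data, c$data))
})

test_that("generated records respect the one-record-per-individual-day contract", {
  cfg <- roost_config(n_individuals = 20, community_sizes = c(10, 10),
                      n_days = 30, n_roosts = 5, seed = 3)
  pop <- generate_population(cfg)
  expect_false(any(duplicated(pop$data[c("individual_id", "day")])))
  expect_true(all(pop$data$day >= 1 & pop$data$day <= 30))
  expect_true(all(pop$data$individual_id %in% names(pop$partition$membership)))
})

test_that("zero-mixing limit gives within-community HWI 1 and between 0", {
  cfg <- roost_config(n_individuals = 12, community_sizes = c(4, 4, 4),
                      n_days = 15, n_roosts = 6, p_detect = 1, p_drift = 0,
                      p_fission = 0, disjoint_homes = TRUE, seed = 11)
  pop <- generate_population(cfg)
  # everyone detected every day
  expect_equal(nrow(pop$data), 12 * 15)
  w <- association_matrix(pop$data)
  memb <- pop$partition$membership[rownames(w)]
  same <- outer(memb, memb, "==")
  diag(same) <- NA
  expect_true(all(w[same & !is.na(same)] == 1))
  expect_true(all(w[!same & !is.na(same)] == 0))
  # community detection recovers the planted partition exactly
  fg <- fast_greedy_communities(w)
  expect_equal(dyad_similarity(fg, pop$partition), 1)
})

test_that("detection counts scale with p_detect and drift erodes modularity", {
  mean_det <- function(p_detect, seed) {
    cfg <- roost_config(n_individuals = 20, community_sizes = c(10, 10),
                        n_days = 50, n_roosts = 5, p_detect = p_detect,
                        seed = seed)
    nrow(generate_population(cfg)$data) / 20
  }
  for (p in c(0.3, 0.7)) {
    dets <- vapply(1:8, function(s) mean_det(p, s), numeric(1))
    se <- stats::sd(dets) / sqrt(length(dets))
    expect_lt(abs(mean(dets) - p * 50), 3 * max(se, 0.5))
  }

  planted_q <- function(p_drift, seed) {
    cfg <- roost_config(n_individuals = 24, community_sizes = c(8, 8, 8),
                        n_days = 40, n_roosts = 6, p_detect = 0.8,
                        p_fission = 0.2, p_drift = p_drift, seed = seed)
    generate_population(cfg)$partition$q
  }
  qs <- sapply(1:6, function(s) {
    c(low = planted_q(0.05, s), mid = planted_q(0.4, s), high = planted_q(0.9, s))
  })
  expect_gt(mean(qs["low", ]), mean(qs["mid", ]))
  expect_gt(mean(qs["mid", ]), mean(qs["high", ]))
})

test_that("calibration converges to reachable targets and reports unreachable ones", {
  cfg <- roost_config(n_individuals = 24, community_sizes = c(8, 8, 8),
                      n_days = 40, n_roosts = 6, p_detect = 0.6, seed = 1)
  # degenerate tolerance can never be met by a stochastic generator
  cal0 <- calibrate_generator(config = cfg, tolerance = 0,
                              n_seeds = 2, p_drift_grid = c(0.2),
                              p_fission_grid = c(0.2), seed = 1)
  expect_false(cal0$converged)
  expect_true(all(is.finite(cal0$residuals)))

  # complete-graph limit: high drift fills the network in and kills Q
  cal1 <- calibrate_generator(targets = c(density = 1, q = 0, clustering = 1),
                              config = cfg, tolerance = 0.15, n_seeds = 3,
                              p_drift_grid = c(0.2, 0.9),
                              p_fission_grid = 0, seed = 2)
  expect_gte(cal1$config$p_drift, 0.9)
  expect_lt(cal1$achieved[["q"]], 0.15)
  expect_gt(cal1$achieved[["density"]], 0.85)
})
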