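# A small structured population reused across tests in this file.
make_ref <- function(seed = 1, n_rand = 60, n_boot = 60) {
  cfg <- roost_config(n_individuals = 18, community_sizes = c(6, 6, 6),
                      n_days = 30, n_roosts = 6, p_detect = 0.8,
                      p_fission = 0.3, p_drift = 0.2, seed = seed)
  pop <- generate_population(cfg)
  build_observed(pop$data, min_days = 15, obs_cap = 15, n_rand = n_rand,
                 n_boot = n_boot, n_repeat = 2, seed = seed + 100)
}

test_that("build_observed filters, balances and characterizes the reference", {
  ref <- make_ref()
  counts <- table(ref$data$individual_id)
  expect_true(all(counts == 15))              # balanced to obs_cap
  expect_true(setequal(names(counts), ref$ids))
  expect_equal(ref$metrics$n_communities, ref$partition$n_communities)
  expect_true(ref$p_q >= 0 && ref$p_q <= 1)
  expect_true(ref$r_com_obs >= -1 && ref$r_com_obs <= 1)

  # an individual below the detection filter is excluded...
  d <- disjoint_for_filter <- data.frame(
    individual_id = c(rep("a", 5), rep("b", 5), rep("c", 4)),
    day = c(1:5, 1:5, 1:4), roost_id = "r1")
  ref2 <- build_observed(d, min_days = 5, obs_cap = 5, n_rand = 5,
                         n_boot = 5, n_repeat = 1, seed = 1)
  expect_setequal(ref2$ids, c("a", "b"))
  # ...and with exactly obs_cap detections truncation is the identity
  expect_equal(sort(ref2$data$day[ref2$data$individual_id == "a"]), 1:5)

  expect_error(build_observed(d, min_days = 6, obs_cap = 6), "min_days")
})

test_that("draw_sample enforces the regime and excludes the complete cell", {
  ref <- make_ref()
  expect_error(draw_sample(ref, length(ref$ids), ref$obs_cap), "excluded")
  expect_silent(smp <- draw_sample(ref, length(ref$ids), ref$obs_cap,
                                   allow_full = TRUE, seed = 1))
  expect_error(draw_sample(ref, 500, 5), "population")
  expect_error(draw_sample(ref, 5, 500), "obs_cap")

  s1 <- draw_sample(ref, 6, 1, seed = 3)
  expect_equal(nrow(s1), 6)                   # one record each
  expect_length(unique(s1$individual_id), 6)

  expect_identical(draw_sample(ref, 8, 5, seed = 9),
                   draw_sample(ref, 8, 5, seed = 9))
  # sampled records are a subset of the reference records
  s2 <- draw_sample(ref, 8, 5, seed = 9)
  key <- function(d) paste(d$individual_id, d$day, d$roost_id)
  expect_true(all(key(s2) %in% key(ref$data)))
})

test_that("dyad similarity matches enumeration and its brute-force oracle", {
  ref_all_one <- stats::setNames(rep(1, 3), c("a", "b", "c"))
  singletons <- stats::setNames(1:3, c("a", "b", "c"))
  expect_equal(dyad_similarity(singletons, ref_all_one), 0)  # 0 of 3 dyads
  expect_equal(dyad_similarity(ref_all_one, ref_all_one), 1)
  expect_error(dyad_similarity(ref_all_one["a"], ref_all_one), "at least 2")

  set.seed(13)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    ids <- letters[1:n]
    ms <- stats::setNames(sample.int(4, n, replace = TRUE), ids)
    mr <- stats::setNames(sample.int(4, n, replace = TRUE), ids)
    expect_equal(dyad_similarity(ms, mr), brute_dyad_similarity(ms, mr))
  }
})

test_that("evaluate_sample codes outcomes, deltas and the degenerate path", {
  ref <- make_ref()
  smp <- draw_sample(ref, 12, 10, seed = 21)
  row <- evaluate_sample(smp, ref, n_rand = 60, n_boot = 60, seed = 22)
  expect_equal(row$n_individuals, 12)
  expect_equal(row$n_obs, 10)
  expect_equal(row$evidence, as.integer(row$p_q < 0.05))
  expect_equal(row$acceptable_rcom,
               as.integer(row$r_com >= 0.5 & row$r_com <= ref$r_com_obs))
  expect_equal(row$delta_n_comm,
               abs(row$n_communities - ref$metrics$n_communities))
  expect_gte(row$similarity, 0)

  # forcing the complete cell through gives zero discrepancies
  full <- evaluate_sample(draw_sample(ref, length(ref$ids), ref$obs_cap,
                                      allow_full = TRUE, seed = 1),
                          ref, n_rand = 30, n_boot = 30, seed = 2)
  expect_equal(full$delta_n_comm, 0)
  expect_equal(full$delta_density, 0)
  expect_equal(full$similarity, 1)

  # an edgeless sample: q = 0, one community per individual, all codings 0
  lonely <- data.frame(individual_id = letters[1:5], day = 1:5,
                       roost_id = "r1")
  ref2 <- build_observed(rbind(lonely, transform(lonely, day = day + 5),
                               transform(lonely, roost_id = "r2", day = day + 10)),
                         min_days = 3, obs_cap = 3, n_rand = 10, n_boot = 10,
                         n_repeat = 1, seed = 3)
  edgeless <- data.frame(individual_id = letters[1:4], day = 1:4,
                         roost_id = "r1")
  row0 <- evaluate_sample(edgeless, ref2, n_rand = 10, n_boot = 10, seed = 4)
  expect_true(row0$degenerate)
  expect_equal(row0$q, 0)
  expect_equal(row0$n_communities, 4)
  expect_equal(row0$evidence, 0L)
  expect_equal(row0$r_com, 0)
})

test_that("run_experiment covers the grid and summarize_grid recounts it", {
  ref <- make_ref()
  res <- run_experiment(ref, individuals_grid = c(6, 18), obs_grid = c(5, 15),
                        n_reps = 3, n_rand = 30, n_boot = 30, seed = 5)
  # 2x2 grid minus the excluded (18, 15) cell, 3 replicates each
  expect_equal(nrow(res), 9)
  expect_false(any(res$n_individuals == 18 & res$n_obs == 15))
  # every sample matches its regime exactly
  expect_true(all(res$n_obs * res$n_individuals ==
                    res$n_individuals * res$n_obs))

  res2 <- run_experiment(ref, individuals_grid = c(6, 18), obs_grid = c(5, 15),
                         n_reps = 3, n_rand = 30, n_boot = 30, seed = 5)
  expect_identical(res, res2)

  sg <- summarize_grid(res, ref)
  expect_equal(nrow(sg), 3)
  expect_true(all(sg$n_reps == 3))
  for (i in seq_len(nrow(sg))) {
    sub <- res[res$n_individuals == sg$n_individuals[i] &
                 res$n_obs == sg$n_obs[i], ]
    expect_equal(sg$evidence[i], sum(sub$evidence))
    expect_equal(sg$acceptable_rcom[i], sum(sub$acceptable_rcom))
    expect_equal(sg$correct_n_comm[i],
                 sum(sub$n_communities == ref$metrics$n_communities))
    expect_equal(sg$within_one[i],
                 sum(abs(sub$n_communities - ref$metrics$n_communities) <= 1))
  }
})

test_that("checkpointed runs resume from flushed regimes", {
  ref <- make_ref()
  ck <- withr::local_tempdir()
  res <- run_experiment(ref, individuals_grid = 6, obs_grid = c(5, 10),
                        n_reps = 2, n_rand = 20, n_boot = 20, seed = 7,
                        checkpoint_dir = ck)
  expect_length(list.files(ck, pattern = "^regime_"), 2)
  res2 <- run_experiment(ref, individuals_grid = 6, obs_grid = c(5, 10),
                         n_reps = 2, n_rand = 20, n_boot = 20, seed = 7,
                         checkpoint_dir = ck)
  expect_equal(res, res2)
})
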