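disjoint_clique_data <- function(n_days = 10) {
  do.call(rbind, lapply(seq_len(n_days), function(d) {
    data.frame(individual_id = letters[1:9], day = d,
               roost_id = rep(c("r1", "r2", "r3"), each = 3))
  }))
}

test_that("bootstrap replicates are seeded and respect invariant structure", {
  df <- disjoint_clique_data()
  a <- bootstrap_partitions(df, n_boot = 30, seed = 5)
  b <- bootstrap_partitions(df, n_boot = 30, seed = 5)
  expect_identical(a, b)
  # permanent cliques: every replicate rediscovers the same 3 communities
  ref <- a[[1]]$membership
  for (p in a) {
    expect_equal(p$n_communities, 3)
    expect_equal(dyad_similarity(p, ref), 1)
  }

  # a single-day dataset can only resample that day: replicates identical
  one <- df[df$day == 1, ]
  parts <- bootstrap_partitions(one, n_boot = 10, seed = 2)
  for (p in parts) expect_identical(p$membership, parts[[1]]$membership)
})

test_that("comembership is the dyadic co-assignment proportion", {
  p1 <- stats::setNames(c(1, 1, 2), c("a", "b", "c"))
  p2 <- stats::setNames(c(1, 2, 2), c("a", "b", "c"))
  cm <- comembership(list(p1, p2))
  expect_equal(cm["a", "b"], 0.5)
  expect_equal(cm["b", "c"], 0.5)
  expect_equal(cm["a", "c"], 0)
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(attr(cm, "n_boot"), 2)

  # all-singleton partitions: off-diagonal all zero
  s <- stats::setNames(1:3, c("a", "b", "c"))
  s2 <- stats::setNames(c(9, 7, 5), c("a", "b", "c"))
  cms <- comembership(list(s, s2))
  expect_true(all(cms[upper.tri(cms)] == 0))
})

test_that("assortativity hits the closed-form limits", {
  # perfectly stable communities: co-membership 1 within, 0 between
  memb <- stats::setNames(rep(1:2, each = 3), letters[1:6])
  cm <- outer(memb, memb, "==") + 0
  attr(cm, "n_boot") <- 100L
  r <- community_assortativity(memb, cm)
  expect_equal(r$r_com, 1)
  expect_false(r$degenerate)

  # zero co-membership weight: degenerate, 0
  cm0 <- diag(6); dimnames(cm0) <- list(letters[1:6], letters[1:6])
  r0 <- community_assortativity(memb, cm0)
  expect_equal(r0$r_com, 0)
  expect_true(r0$degenerate)

  # single observed community: coefficient undefined, coded degenerate 0
  r1 <- community_assortativity(stats::setNames(rep(1, 6), letters[1:6]), cm)
  expect_true(r1$degenerate)

  # all co-membership weight inside one label class (the other individuals
  # never co-assigned with anyone): 0/0 again, coded degenerate 0
  memb2 <- stats::setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  cm2 <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  cm2[1:3, 1:3] <- 1; diag(cm2) <- 1
  r2 <- community_assortativity(memb2, cm2)
  expect_true(r2$degenerate)
  expect_equal(r2$r_com, 0)
})

test_that("random labels on a uniform comembership give near-zero assortativity", {
  set.seed(77)
  rs <- replicate(100, {
    n <- 20
    cm <- matrix(stats::runif(n * n, 0.4, 0.6), n, n)
    cm <- (cm + t(cm)) / 2; diag(cm) <- 1
    dimnames(cm) <- list(paste0("i", 1:n), paste0("i", 1:n))
    memb <- stats::setNames(sample.int(3, n, replace = TRUE), paste0("i", 1:n))
    if (length(unique(memb)) < 2) return(NA_real_)
    community_assortativity(memb, cm)$r_com
  })
  # a small negative finite-size bias (order 1/n) is expected
  expect_lt(max(abs(rs), na.rm = TRUE), 0.15)
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
})

test_that("the pipeline is exact in the fixed-structure limit and degenerate when edgeless", {
  rc <- rcom_pipeline(disjoint_clique_data(), n_boot = 50, seed = 3)
  expect_gte(rc$r_com, 0.99)

  # every individual alone every day: no edges anywhere
  lonely <- data.frame(individual_id = rep(letters[1:4], 3),
                       day = rep(1:3, each = 4),
                       roost_id = paste0("r", rep(1:4, 3)))
  rc0 <- rcom_pipeline(lonely, n_boot = 10, seed = 1)
  expect_true(rc0$degenerate)
  expect_equal(rc0$r_com, 0)
})

test_that("repeat-averaging equals the mean of single runs with derived seeds", {
  df <- disjoint_clique_data(6)
  both <- rcom_pipeline(df, n_boot = 20, n_repeat = 3, seed = 11)
  singles <- vapply(1:3, function(t) {
    parts <- bootstrap_partitions(df, n_boot = 20, seed = derive_seed(11, t))
    obs <- fast_greedy_communities(association_matrix(df))
    community_assortativity(obs, comembership(parts))$r_com
  }, numeric(1))
  expect_equal(both$per_repeat, singles)
  expect_equal(both$r_com, mean(singles))
})

test_that("rcom rises with observations per individual in structured data", {
  med_rcom <- function(n_days) {
    vals <- vapply(1:6, function(s) {
      cfg <- roost_config(n_individuals = 18, community_sizes = c(6, 6, 6),
                          n_days = n_days, n_roosts = 6, p_detect = 0.9,
                          p_fission = 0.3, p_drift = 0.25, seed = s)
      pop <- generate_population(cfg)
      rcom_pipeline(pop$data, n_boot = 60, seed = s + 500)$r_com
    }, numeric(1))
    stats::median(vals)
  }
  expect_gt(med_rcom(40), med_rcom(4))
})
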