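# The core experiment: build a balanced reference ("observed") network,
# then repeatedly subsample individuals and observations, recompute all
# global metrics, and code each sample against the reference.

# Filter to individuals with >= min_days detections and truncate each
# to exactly obs_cap randomly chosen records.
balance_data <- function(data, min_days, obs_cap, seed = NULL) {
  validate_roosting(data)
  if (obs_cap > min_days) {
    stop("obs_cap must not exceed min_days", call. = FALSE)
  }
  counts <- table(data$individual_id)
  keep <- names(counts)[counts >= min_days]
  if (length(keep) < 2L) {
    stop(sprintf(
      "fewer than 2 individuals with at least %d detections (filter min_days)",
      min_days), call. = FALSE)
  }
  rows <- split(seq_len(nrow(data)), data$individual_id)[keep]
  picked <- with_seed(seed, lapply(rows, function(r) {
    r[sample.int(length(r), obs_cap)]
  }))
  out <- data[sort(unlist(picked, use.names = FALSE)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the balanced reference ("observed") network
#'
#' Filters the detection stream to individuals observed on at least
#' `min_days` days, truncates each to exactly `obs_cap` randomly chosen
#' observations (a balanced dataset: equal effort per individual,
#' though not the same days), and characterizes the resulting
#' half-weight network: global metrics, fast-greedy partition,
#' Monte-Carlo p-value of modularity from `n_rand` day-constrained
#' permutations, and the community assortativity averaged over
#' `n_repeat` runs of `n_boot` bootstraps.
#'
#' @param data Roosting `data.frame`.
#' @param min_days Minimum detections for an individual to be retained.
#' @param obs_cap Observations kept per retained individual (the
#'   reference analysis uses 40 and 40).
#' @param n_rand Permutations for the modularity test (default 1000).
#' @param n_boot Bootstraps per Rcom repeat (default 1000).
#' @param n_repeat Rcom repeats averaged (default 10).
#' @param seed Optional integer seed.
#' @return A list of class `observed_reference`: `data` (balanced
#'   records), `ids`, `matrix`, `partition`, `metrics` (list with `q`,
#'   `n_communities`, `density`, `clustering`), `p_q`, `r_com_obs`, and
#'   the settings used.
#' @export
build_observed <- function(data, min_days = 40, obs_cap = 40,
                           n_rand = 1000, n_boot = 1000, n_repeat = 10,
                           seed = NULL) {
  bal <- balance_data(data, min_days = min_days, obs_cap = obs_cap,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  ids <- sort(unique(as.character(bal$individual_id)))
  w <- hwi_fast(bal, ids)
  gm <- global_metrics(w)
  null <- null_distribution(bal, n_rand = n_rand,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 2),
                            ids = ids)
  p_q <- monte_carlo_p(gm$q, null)
  rc <- rcom_pipeline(bal, n_boot = n_boot, n_repeat = n_repeat,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 3),
                      ids = ids)
  structure(list(
    data = bal, ids = ids, matrix = w,
    partition = gm$partition,
    metrics = gm[c("q", "n_communities", "density", "clustering")],
    null = null, p_q = p_q, r_com_obs = rc$r_com,
    min_days = min_days, obs_cap = obs_cap,
    n_rand = n_rand, n_boot = n_boot, n_repeat = n_repeat
  ), class = "observed_reference")
}

#' @export
print.observed_reference <- function(x, ...) {
  cat(sprintf("Observed reference network: %d individuals x %d obs each\n",
              length(x$ids), x$obs_cap))
  cat(sprintf("  Q = %.3f (p = %.4g, %d permutations), %d communities\n",
              x$metrics$q, x$p_q, x$n_rand, x$metrics$n_communities))
  cat(sprintf("  density = %.3f, clustering = %.3f, Rcom = %.3f (%d x %d bootstraps)\n",
              x$metrics$density, x$metrics$clustering, x$r_com_obs,
              x$n_repeat, x$n_boot))
  invisible(x)
}

#' Draw one subsampled dataset from the reference
#'
#' Samples `n_individuals` without replacement from the reference
#' population and, for each, `n_obs` of its `obs_cap` balanced records
#' without replacement.  The complete cell (all individuals, all
#' observations) is the reference itself and is refused unless
#' `allow_full = TRUE`.
#'
#' @param ref An [build_observed()] reference.
#' @param n_individuals,n_obs Sampling regime.
#' @param seed Optional integer seed.
#' @param allow_full Permit the complete-reference cell.
#' @return A roosting `data.frame`.
#' @export
draw_sample <- function(ref, n_individuals, n_obs, seed = NULL,
                        allow_full = FALSE) {
  stopifnot(inherits(ref, "observed_reference"))
  if (!is_count(n_individuals) || n_individuals > length(ref$ids)) {
    stop("n_individuals must be between 1 and the reference population size",
         call. = FALSE)
  }
  if (!is_count(n_obs) || n_obs > ref$obs_cap) {
    stop("n_obs must be between 1 and the reference obs_cap", call. = FALSE)
  }
  if (!allow_full && n_individuals == length(ref$ids) && n_obs == ref$obs_cap) {
    stop("the (all individuals, all observations) cell is the reference ",
         "network itself and is excluded from sampling", call. = FALSE)
  }
  with_seed(seed, {
    take <- sample(ref$ids, n_individuals)
    rows <- split(seq_len(nrow(ref$data)), ref$data$individual_id)[take]
    picked <- lapply(rows, function(r) r[sample.int(length(r), n_obs)])
    out <- ref$data[sort(unlist(picked, use.names = FALSE)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Dyadic similarity between a sample and the reference partition
#'
#' Over all unordered dyads of sampled individuals, the proportion
#' whose same-community / different-community status agrees between the
#' sample partition and the reference partition (the Rand index
#' restricted to the sampled ids).  1 means every dyad is assorted as
#' in the reference.
#'
#' @param sample_p Sample partition (class `netss_partition` or named
#'   membership vector) over the sampled ids.
#' @param ref_p Reference partition covering at least those ids.
#' @return Proportion in `[0, 1]`.
#' @export
dyad_similarity <- function(sample_p, ref_p) {
  ms <- if (inherits(sample_p, "netss_partition")) sample_p$membership else sample_p
  mr <- if (inherits(ref_p, "netss_partition")) ref_p$membership else ref_p
  ids <- names(ms)
  if (is.null(ids) || is.null(names(mr))) {
    stop("partitions must carry individual ids as names", call. = FALSE)
  }
  if (!all(ids %in% names(mr))) {
    stop("sampled ids missing from the reference partition", call. = FALSE)
  }
  if (length(ids) < 2L) {
    stop("dyadic similarity needs at least 2 sampled individuals",
         call. = FALSE)
  }
  mr <- mr[ids]
  ut <- upper.tri(matrix(0, length(ids), length(ids)))
  same_s <- outer(ms, ms, "==")[ut]
  same_r <- outer(mr, mr, "==")[ut]
  mean(same_s == same_r)
}

#' Evaluate one subsampled network against the reference
#'
#' Rebuilds the half-weight network from the sampled records (as if the
#' unsampled individuals never existed), computes all global metrics,
#' the Monte-Carlo p-value of modularity (`n_rand` day-constrained
#' permutations), the community assortativity (`n_boot` bootstraps),
#' the dyadic similarity to the reference partition, and the binary
#' codings: `evidence` (p < 0.05 on a non-degenerate network) and
#' `acceptable_rcom` (0.5 <= Rcom <= reference Rcom, both ends closed).
#' An edgeless sample is a defined outcome: `q = 0`, as many
#' communities as individuals, `evidence = 0`, `r_com = 0`.
#'
#' @param sample Roosting `data.frame` drawn with [draw_sample()].
#' @param ref The [build_observed()] reference.
#' @param n_rand Permutations for the modularity test.
#' @param n_boot Bootstraps for Rcom.
#' @param seed Optional integer seed.
#' @return One-row `data.frame` with the regime, metrics, codings and
#'   absolute discrepancies (`delta_*`) from the reference.
#' @export
evaluate_sample <- function(sample, ref, n_rand = 1000, n_boot = 1000,
                            seed = NULL) {
  stopifnot(inherits(ref, "observed_reference"))
  validate_roosting(sample)
  ids <- sort(unique(as.character(sample$individual_id)))
  n <- length(ids)
  n_obs <- nrow(sample) / n
  w <- hwi_fast(sample, ids)
  part <- fast_greedy_communities(w)
  degenerate <- part$degenerate

  if (degenerate) {
    q <- 0
    n_comm <- n
    density <- 0
    clustering <- if (n >= 3) 0 else NA_real_
    p_q <- NA_real_
    evidence <- 0L
    r_com <- 0
  } else {
    q <- part$q
    n_comm <- part$n_communities
    density <- graph_density(w)
    clustering <- if (n >= 3) global_clustering(w) else NA_real_
    null <- null_distribution(sample, n_rand = n_rand,
                              seed = if (is.null(seed)) NULL else derive_seed(seed, 1),
                              ids = ids)
    p_q <- monte_carlo_p(q, null)
    evidence <- as.integer(p_q < 0.05)
    rc <- rcom_pipeline(sample, n_boot = n_boot, n_repeat = 1,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, 2),
                        ids = ids)
    r_com <- rc$r_com
  }

  sim <- if (n >= 2) dyad_similarity(part, ref$partition) else NA_real_
  data.frame(
    n_individuals = n,
    n_obs = n_obs,
    q = q,
    n_communities = n_comm,
    density = density,
    clustering = clustering,
    p_q = p_q,
    evidence = evidence,
    r_com = r_com,
    acceptable_rcom = as.integer(r_com >= 0.5 & r_com <= ref$r_com_obs),
    similarity = sim,
    delta_n_comm = abs(n_comm - ref$metrics$n_communities),
    delta_density = abs(density - ref$metrics$density),
    delta_clustering = abs(clustering - ref$metrics$clustering),
    degenerate = degenerate
  )
}

#' Run the full individuals-by-observations subsampling experiment
#'
#' For every regime in the cross of `individuals_grid` and `obs_grid`
#' (minus the complete-reference cell) draws `n_reps` independent
#' samples and evaluates each against the reference.  Per-replicate
#' seeds are derived deterministically from the master seed, so the
#' experiment is reproducible and, with `checkpoint_dir`, resumable: a
#' regime whose checkpoint file already exists is loaded, not rerun.
#'
#' The default grids are the reference study design
#' (9 x 7 regimes - 1 excluded cell, 100 replicates: 6200 rows); scale
#' them down for desk-scale runs.
#'
#' @param ref The [build_observed()] reference.
#' @param individuals_grid,obs_grid Regime grids.
#' @param n_reps Replicates per regime (default 100).
#' @param n_rand,n_boot Permutations and bootstraps per sample.
#' @param seed Master seed (default 1).
#' @param checkpoint_dir Optional directory for per-regime CSV flushes.
#' @param progress Emit a message per regime.
#' @return `data.frame` with one row per (regime, replicate); columns
#'   as in [evaluate_sample()] plus `replicate`.
#' @export
run_experiment <- function(ref,
                           individuals_grid = c(5, 10, 15, 20, 25, 35, 50, 75, 99),
                           obs_grid = c(1, 5, 10, 15, 20, 30, 40),
                           n_reps = 100, n_rand = 1000, n_boot = 1000,
                           seed = 1, checkpoint_dir = NULL,
                           progress = FALSE) {
  stopifnot(inherits(ref, "observed_reference"))
  individuals_grid <- sort(unique(as.integer(individuals_grid)))
  obs_grid <- sort(unique(as.integer(obs_grid)))
  if (any(individuals_grid > length(ref$ids)) || any(obs_grid > ref$obs_cap)) {
    stop("grids exceed the reference population or obs_cap", call. = FALSE)
  }
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }

  out <- list()
  for (ni in individuals_grid) {
    for (no in obs_grid) {
      if (ni == length(ref$ids) && no == ref$obs_cap) next  # the reference itself
      ck <- if (!is.null(checkpoint_dir)) {
        file.path(checkpoint_dir, sprintf("regime_%03d_%03d.csv", ni, no))
      }
      if (!is.null(ck) && file.exists(ck)) {
        out[[length(out) + 1L]] <- utils::read.csv(ck)
        next
      }
      rows <- lapply(seq_len(n_reps), function(rep) {
        s <- derive_seed(seed, ni, no, rep)
        smp <- draw_sample(ref, ni, no, seed = s)
        cbind(replicate = rep,
              evaluate_sample(smp, ref, n_rand = n_rand, n_boot = n_boot,
                              seed = derive_seed(s, 1)))
      })
      regime <- do.call(rbind, rows)
      if (!is.null(ck)) utils::write.csv(regime, ck, row.names = FALSE)
      if (progress) {
        message(sprintf("regime %d individuals x %d obs: %d/%d with evidence, %d degenerate",
                        ni, no, sum(regime$evidence), n_reps,
                        sum(regime$degenerate)))
      }
      out[[length(out) + 1L]] <- regime
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-regime summary of the subsampling experiment
#'
#' For each (individuals, observations) regime: the number of
#' replicates with evidence for community structure (p < 0.05), with an
#' acceptable community assortativity, with exactly the reference
#' number of communities, and within one of it.
#'
#' @param results Results table from [run_experiment()].
#' @param ref The [build_observed()] reference, or the reference number
#'   of communities as an integer.
#' @return `data.frame` with one row per regime.
#' @export
summarize_grid <- function(results, ref) {
  if (nrow(results) == 0L) stop("empty results table", call. = FALSE)
  ref_k <- if (inherits(ref, "observed_reference")) {
    ref$metrics$n_communities
  } else {
    as.integer(ref)
  }
  agg <- stats::aggregate(
    cbind(evidence = results$evidence,
          acceptable_rcom = results$acceptable_rcom,
          correct_n_comm = as.integer(results$n_communities == ref_k),
          within_one = as.integer(abs(results$n_communities - ref_k) <= 1)),
    by = list(n_individuals = results$n_individuals,
              n_obs = results$n_obs),
    FUN = sum)
  reps <- stats::aggregate(list(n_reps = results$evidence),
                           by = list(n_individuals = results$n_individuals,
                                     n_obs = results$n_obs),
                           FUN = length)
  out <- merge(agg, reps, by = c("n_individuals", "n_obs"))
  out[order(out$n_individuals, out$n_obs), ]
}
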