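#' Configuration for the synthetic fission-fusion roosting generator
#'
#' Describes a closed population of individuals partitioned into social
#' communities that choose among a fixed set of roosts each day.  Each
#' day every community is assigned a "home" roost; with probability
#' `p_fission` the community splits across two roosts for that day
#' (members allocated by fair coin).  Each individual is detected with
#' probability `p_detect`; a detected individual uses its community's
#' roost(s) with probability `1 - p_drift` and otherwise drifts to a
#' uniformly random roost.  Drift and shared home roosts are what
#' create between-community associations, emulating the fission-fusion
#' mixing of a bat maternity colony.
#'
#' The defaults emulate a well-studied bat maternity colony: 99
#' individuals in 3
#' equal communities, 131 observation days, 11 roosts, with mixing
#' parameters chosen by [calibrate_generator()] so that the balanced
#' reference network (40 observations per individual) has graph density,
#' modularity and clustering coefficient near 0.675, 0.285 and 0.828.
#'
#' @param n_individuals Number of individuals in the closed population.
#' @param community_sizes Integer vector of community sizes; must sum to
#'   `n_individuals`.
#' @param n_days Number of observation days.
#' @param n_roosts Number of roosts; must be at least the number of
#'   communities.
#' @param p_detect Daily per-individual detection probability.
#' @param p_fission Daily per-community probability of splitting across
#'   two roosts.
#' @param p_drift Probability that a detected individual roosts at a
#'   uniformly random roost instead of its community's roost that day.
#' @param disjoint_homes If `TRUE`, the daily home roosts of the
#'   communities (and any fission roosts) are forced to be distinct,
#'   giving perfectly separated communities when `p_drift = 0`.
#' @param seed Optional integer seed stored with the configuration and
#'   used by default in [generate_population()].
#' @return A list of class `roost_config`.
#' @seealso [generate_population()], [calibrate_generator()]
#' @examples
#' cfg <- roost_config(n_individuals = 30, community_sizes = c(10, 10, 10),
#'                     n_days = 60, n_roosts = 6, seed = 1)
#' cfg
#' @export
roost_config <- function(n_individuals = 99,
                         community_sizes = c(33, 33, 33),
                         n_days = 131,
                         n_roosts = 11,
                         p_detect = 0.45,
                         p_fission = 0.7,
                         p_drift = 0.4,
                         disjoint_homes = FALSE,
                         seed = NULL) {
  config <- structure(
    list(n_individuals = as.integer(n_individuals),
         community_sizes = as.integer(community_sizes),
         n_communities = length(community_sizes),
         n_days = as.integer(n_days),
         n_roosts = as.integer(n_roosts),
         p_detect = p_detect,
         p_fission = p_fission,
         p_drift = p_drift,
         disjoint_homes = isTRUE(disjoint_homes),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "roost_config")
  validate_roost_config(config)
  config
}

validate_roost_config <- function(config) {
  bad <- function(msg) {
    stop("invalid generator config: ", msg, call. = FALSE)
  }
  if (!is_count(config$n_individuals)) {
    bad("n_individuals must be a positive integer")
  }
  if (length(config$community_sizes) < 1L ||
      any(!vapply(config$community_sizes, is_count, logical(1)))) {
    bad("community_sizes must all be positive integers")
  }
  if (sum(config$community_sizes) != config$n_individuals) {
    bad("sum(community_sizes) must equal n_individuals")
  }
  if (!is_count(config$n_days)) bad("n_days must be >= 1")
  if (!is_count(config$n_roosts)) bad("n_roosts must be >= 1")
  if (config$n_roosts < config$n_communities) {
    bad("n_roosts must be >= the number of communities")
  }
  for (p in c("p_detect", "p_fission", "p_drift")) {
    if (!is_prob(config[[p]])) bad(paste(p, "must be a probability in [0, 1]"))
  }
  if (!is.null(config$seed) && !is_count(config$seed, min = 0L)) {
    bad("seed must be a non-negative integer")
  }
  invisible(config)
}

#' @export
print.roost_config <- function(x, ...) {
  cat("Fission-fusion roosting generator config\n")
  cat(sprintf("  %d individuals in %d communities (%s)\n",
              x$n_individuals, x$n_communities,
              paste(x$community_sizes, collapse = ", ")))
  cat(sprintf("  %d days, %d roosts%s\n", x$n_days, x$n_roosts,
              if (x$disjoint_homes) " (disjoint daily home roosts)" else ""))
  cat(sprintf("  p_detect = %.3g, p_fission = %.3g, p_drift = %.3g\n",
              x$p_detect, x$p_fission, x$p_drift))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Generate synthetic roosting detection data with planted communities
#'
#' Simulates one season of daily roost detections under the
#' fission-fusion model described in [roost_config()] and returns the
#' long-format detection records together with the planted community
#' partition.  The output is deterministic for a given `(config, seed)`.
#'
#' @param config A [roost_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with elements:
#'   \describe{
#'     \item{data}{`data.frame` with columns `individual_id`, `day`
#'       (integer, `1:n_days`), `roost_id`; at most one row per
#'       individual-day.}
#'     \item{partition}{the planted partition (class `netss_partition`)
#'       with its modularity `q` on the half-weight network of the
#'       generated data.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cfg <- roost_config(n_individuals = 12, community_sizes = c(4, 4, 4),
#'                     n_days = 20, n_roosts = 4, seed = 7)
#' pop <- generate_population(cfg)
#' head(pop$data)
#' pop$partition
#' @export
generate_population <- function(config, seed = config$seed) {
  validate_roost_config(config)
  n <- config$n_individuals
  k <- config$n_communities
  ids <- sprintf("ind%03d", seq_len(n))
  community <- rep.int(seq_len(k), config$community_sizes)

  res <- with_seed(seed, {
    ind_l <- vector("list", config$n_days)
    roost_l <- vector("list", config$n_days)
    for (d in seq_len(config$n_days)) {
      if (config$disjoint_homes) {
        homes <- sample.int(config$n_roosts, k)
      } else {
        homes <- sample.int(config$n_roosts, k, replace = TRUE)
      }
      fission <- stats::runif(k) < config$p_fission
      second <- rep(NA_integer_, k)
      if (any(fission)) {
        free <- setdiff(seq_len(config$n_roosts), if (config$disjoint_homes) homes else integer())
        for (g in which(fission)) {
          if (config$disjoint_homes) {
            if (length(free) == 0L) next  # no spare roost: fission skipped today
            second[g] <- free[sample.int(length(free), 1L)]
            free <- setdiff(free, second[g])
          } else {
            others <- setdiff(seq_len(config$n_roosts), homes[g])
            if (length(others) == 0L) next
            second[g] <- others[sample.int(length(others), 1L)]
          }
        }
      }
      detected <- which(stats::runif(n) < config$p_detect)
      if (length(detected) == 0L) next
      comm_d <- community[detected]
      roost <- homes[comm_d]
      split_off <- !is.na(second[comm_d]) & stats::runif(length(detected)) < 0.5
      roost[split_off] <- second[comm_d[split_off]]
      drift <- stats::runif(length(detected)) < config$p_drift
      if (any(drift)) {
        roost[drift] <- sample.int(config$n_roosts, sum(drift), replace = TRUE)
      }
      ind_l[[d]] <- detected
      roost_l[[d]] <- roost
    }
    list(ind = ind_l, roost = roost_l)
  })

  days <- rep.int(seq_len(config$n_days), lengths(res$ind))
  data <- data.frame(
    individual_id = ids[unlist(res$ind, use.names = FALSE)],
    day = days,
    roost_id = sprintf("roost%02d", unlist(res$roost, use.names = FALSE)),
    stringsAsFactors = FALSE)

  labels <- stats::setNames(community, ids)
  w <- association_matrix(data, ids = ids)
  q <- network_modularity(w, labels)
  list(data = data,
       partition = new_partition(labels, q = q),
       config = config)
}

#' Calibrate the generator to target network metrics
#'
#' Grid search over `(p_drift, p_fission, p_detect)` for a configuration
#' whose generated networks match target graph density, modularity and
#' clustering coefficient.  Each candidate is scored by the mean metrics
#' of `n_seeds` independent simulations; when `min_days`/`obs_cap` are
#' supplied the metrics are computed on the balanced reference network
#' (individuals filtered to `>= min_days` detections and truncated to
#' `obs_cap` observations each), which is the network the downstream
#' subsampling experiment resamples.
#'
#' The search never silently succeeds: if no candidate brings every
#' metric within `tolerance` of its target, the best candidate found is
#' returned with `converged = FALSE` and the residuals reported.
#'
#' @param targets Named numeric vector with elements `density`, `q` and
#'   `clustering`, each in `[0, 1]`.
#' @param config Base [roost_config()]; structural fields (population,
#'   days, roosts) are kept fixed during the search.
#' @param tolerance Maximum absolute deviation allowed per metric.
#' @param n_seeds Number of simulations averaged per candidate.
#' @param p_drift_grid,p_fission_grid,p_detect_grid Candidate values.
#' @param min_days,obs_cap Optional balancing applied before measuring
#'   (see [build_observed()]); both or neither.
#' @param seed Integer seed controlling the evaluation simulations.
#' @return A list of class `generator_calibration`: `config` (the best
#'   configuration), `achieved`, `residuals`, `converged`, `tolerance`,
#'   and `evaluated` (a data frame of all candidates and their metrics).
#' @examples
#' \donttest{
#' cal <- calibrate_generator(
#'   targets = c(density = 0.675, q = 0.285, clustering = 0.828),
#'   config = roost_config(seed = 1), tolerance = 0.1, n_seeds = 3,
#'   min_days = 40, obs_cap = 40)
#' cal$achieved
#' }
#' @export
calibrate_generator <- function(targets = c(density = 0.675, q = 0.285,
                                            clustering = 0.828),
                                config = roost_config(),
                                tolerance = 0.1,
                                n_seeds = 5,
                                p_drift_grid = c(0, 0.2, 0.4, 0.6),
                                p_fission_grid = c(0, 0.35, 0.7),
                                p_detect_grid = config$p_detect,
                                min_days = NULL, obs_cap = NULL,
                                seed = 1) {
  stopifnot(all(c("density", "q", "clustering") %in% names(targets)))
  targets <- targets[c("density", "q", "clustering")]
  if (any(targets < 0 | targets > 1)) {
    stop("calibration targets must lie in [0, 1]", call. = FALSE)
  }
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  if (xor(is.null(min_days), is.null(obs_cap))) {
    stop("supply both of min_days and obs_cap, or neither", call. = FALSE)
  }

  grid <- expand.grid(p_drift = p_drift_grid, p_fission = p_fission_grid,
                      p_detect = p_detect_grid, KEEP.OUT.ATTRS = FALSE)
  eval_one <- function(i) {
    cfg <- config
    cfg$p_drift <- grid$p_drift[i]
    cfg$p_fission <- grid$p_fission[i]
    cfg$p_detect <- grid$p_detect[i]
    m <- matrix(NA_real_, n_seeds, 3)
    for (s in seq_len(n_seeds)) {
      sd_s <- derive_seed(seed, i, s)
      pop <- generate_population(cfg, seed = sd_s)
      dat <- pop$data
      if (!is.null(min_days)) {
        dat <- tryCatch(
          balance_data(dat, min_days = min_days, obs_cap = obs_cap,
                       seed = derive_seed(seed, i, s, 1)),
          error = function(e) NULL)
        if (is.null(dat)) next  # too few qualifying individuals
      }
      w <- association_matrix(dat)
      fg <- fast_greedy_communities(w)
      m[s, ] <- c(graph_density(w), fg$q, global_clustering(w))
    }
    colMeans(m, na.rm = TRUE)
  }

  achieved <- t(vapply(seq_len(nrow(grid)), eval_one, numeric(3)))
  colnames(achieved) <- c("density", "q", "clustering")
  resid <- sweep(achieved, 2, targets)
  score <- apply(abs(resid), 1, max)
  score[!is.finite(score)] <- Inf
  best <- which.min(score)

  cfg <- config
  cfg$p_drift <- grid$p_drift[best]
  cfg$p_fission <- grid$p_fission[best]
  cfg$p_detect <- grid$p_detect[best]
  structure(list(
    config = cfg,
    achieved = achieved[best, ],
    residuals = resid[best, ],
    converged = is.finite(score[best]) && tolerance > 0 &&
      all(abs(resid[best, ]) <= tolerance),
    tolerance = tolerance,
    targets = targets,
    evaluated = cbind(grid, achieved)
  ), class = "generator_calibration")
}

#' @export
print.generator_calibration <- function(x, ...) {
  cat(sprintf("Generator calibration (%s, tolerance %.3g)\n",
              if (x$converged) "converged" else "NOT converged", x$tolerance))
  cat(sprintf("  best: p_drift = %.3g, p_fission = %.3g, p_detect = %.3g\n",
              x$config$p_drift, x$config$p_fission, x$config$p_detect))
  cat(sprintf("  achieved density = %.3f (target %.3f), q = %.3f (%.3f), clustering = %.3f (%.3f)\n",
              x$achieved["density"], x$targets["density"],
              x$achieved["q"], x$targets["q"],
              x$achieved["clustering"], x$targets["clustering"]))
  invisible(x)
}
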