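# Day-constrained data-stream randomization and the Monte-Carlo test
# for community structure.
#
# The null model reshuffles which detected individuals occupied which
# roost within each day, holding the day's detected individuals and the
# multiset of roost-group sizes fixed. Each random network is an
# independent full reshuffle, sampling the constrained space uniformly
# without burn-in.

#' Randomly reassign individuals among a day's roosting groups
#'
#' Independently for every day, the detected individuals are reassigned
#' uniformly at random to that day's roost groups, preserving the exact
#' multiset of group sizes.  Individuals never move across days.
#'
#' @param groups A `daily_groups` object from [group_by_day()].
#' @param seed Optional integer seed.
#' @return A `daily_groups` object with the same days, roosts and group
#'   sizes.
#' @export
permute_days <- function(groups, seed = NULL) {
  stopifnot(inherits(groups, "daily_groups"))
  out <- with_seed(seed, lapply(groups, function(day) {
    ids <- unlist(day, use.names = FALSE)
    ids <- ids[sample.int(length(ids))]
    sizes <- lengths(day)
    stats::setNames(split(ids, rep.int(seq_along(day), sizes)), names(day))
  }))
  structure(out, class = "daily_groups")
}

#' Null distributions of global metrics under day-constrained shuffles
#'
#' Generates `n_rand` independent randomized datasets by reshuffling
#' roost membership within days, rebuilds the half-weight network for
#' each, and records the fast-greedy modularity together with graph
#' density and clustering coefficient.  Only the modularity
#' distribution feeds the community-structure test
#' ([monte_carlo_p()]); the other two are stored for inspection.
#'
#' @param data Roosting `data.frame`.
#' @param n_rand Number of random networks (the reference analysis uses
#'   1000).
#' @param seed Optional integer seed.
#' @param ids Individuals to retain (default: all present).
#' @return A list of class `null_distribution` with numeric vectors
#'   `q`, `density`, `clustering` and the count `n_rand`.
#' @export
null_distribution <- function(data, n_rand, seed = NULL, ids = NULL) {
  validate_roosting(data)
  if (!is_count(n_rand)) stop("n_rand must be >= 1", call. = FALSE)
  ids <- ids %||% sort(unique(as.character(data$individual_id)))
  n <- length(ids)
  di <- match(data$individual_id, ids)
  keep <- !is.na(di)
  df <- data[keep, , drop = FALSE]
  di <- di[keep]

  q <- dens <- clus <- numeric(n_rand)
  if (nrow(df) == 0L) {
    return(structure(list(q = q, density = dens, clustering = clus,
                          n_rand = as.integer(n_rand)),
                     class = "null_distribution"))
  }

  dayf <- factor(df$day)
  grp <- factor(paste(as.integer(dayf), df$roost_id, sep = "\1"))
  gi <- as.integer(grp)
  det <- tabulate(di, n)
  denom <- outer(det, det, "+") / 2
  # record positions grouped by day; shuffling individuals within these
  # blocks is exactly the constrained randomization
  bidx <- order(as.integer(dayf))
  day_key <- as.integer(dayf)[bidx]
  nrec <- length(di)

  with_seed(seed, for (r in seq_len(n_rand)) {
    perm <- order(day_key, stats::runif(nrec))
    dj <- di
    dj[bidx] <- di[bidx][perm]
    w <- assoc_from_assignment(gi, dj, n, nlevels(grp), denom)
    if (!any(w > 0)) {
      q[r] <- 0; dens[r] <- 0; clus[r] <- 0
    } else {
      g <- assoc_graph(w)
      fg <- igraph::cluster_fast_greedy(g)
      q[r] <- network_modularity(w, as.integer(igraph::membership(fg)))
      dens[r] <- sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
      tr <- igraph::transitivity(g, type = "global")
      clus[r] <- if (is.nan(tr)) 0 else tr
    }
  })
  structure(list(q = q, density = dens, clustering = clus,
                 n_rand = as.integer(n_rand)),
            class = "null_distribution")
}

#' Monte-Carlo p-value for community structure
#'
#' The proportion of random-network modularity values at or above the
#' observed modularity.  Ties count toward the numerator, which is the
#' conservative reading; `p < 0.05` is the conventional evidence
#' threshold for community structure.
#'
#' @param q_obs Observed modularity (fast-greedy optimum).
#' @param null A [null_distribution()] object.
#' @return The empirical p-value.
#' @export
monte_carlo_p <- function(q_obs, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (length(null$q) == 0L) stop("empty null distribution", call. = FALSE)
  mean(null$q >= q_obs)
}
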