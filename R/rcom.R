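# Bootstrap community assortativity (Rcom): how consistently the data
# assort individuals into the same communities when the sampling
# periods are resampled.
#
# The estimator follows the bootstrap/assortativity method of Shizuka &
# Farine (2016, Animal Behaviour 112:237-246): community detection is
# rerun on day-resampled datasets, the dyadic co-membership proportions
# across replicates form a weighted network, and Rcom is the discrete
# weighted assortativity of the observed community labels on that
# network. Because consistency is scored dyadically, bootstrap
# community labels never need to be matched across replicates.

#' Community partitions of day-resampled datasets
#'
#' Each bootstrap replicate resamples the observation days with
#' replacement (keeping the number of days), rebuilds the half-weight
#' network over all retained individuals, and reruns fast-greedy
#' community detection.  A replicate whose network has no positive
#' edges yields the all-singleton partition; it is recorded, not
#' skipped.
#'
#' @param data Roosting `data.frame`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @param ids Individuals to retain (default: all present).
#' @return List of `n_boot` partition objects (class `netss_partition`).
#' @export
bootstrap_partitions <- function(data, n_boot, seed = NULL, ids = NULL) {
  validate_roosting(data)
  if (!is_count(n_boot)) stop("n_boot must be >= 1", call. = FALSE)
  ids <- ids %||% sort(unique(as.character(data$individual_id)))
  n <- length(ids)
  di <- match(data$individual_id, ids)
  keep <- !is.na(di)
  df <- data[keep, , drop = FALSE]
  di <- di[keep]
  day_rows <- split(seq_along(di), factor(df$day))
  nd <- length(day_rows)
  roost <- as.character(df$roost_id)

  with_seed(seed, lapply(seq_len(n_boot), function(b) {
    s <- sample.int(nd, nd, replace = TRUE)
    picked <- day_rows[s]
    rec <- unlist(picked, use.names = FALSE)
    if (length(rec) == 0L) {
      return(new_partition(stats::setNames(seq_len(n), ids),
                           q = 0, degenerate = TRUE))
    }
    # a day drawn twice is a distinct sampling-period instance, so
    # groups are keyed by draw index, not by the original day label
    inst <- rep.int(seq_along(s), lengths(picked))
    grp <- factor(paste(inst, roost[rec], sep = "\1"))
    dj <- di[rec]
    det <- tabulate(dj, n)
    denom <- outer(det, det, "+") / 2
    w <- assoc_from_assignment(as.integer(grp), dj, n, nlevels(grp), denom)
    dimnames(w) <- list(ids, ids)
    fast_greedy_communities(w)
  }))
}

#' Dyadic co-membership proportions across partitions
#'
#' @param partitions List of partition objects over a common id set.
#' @return Symmetric matrix with entries in `[0, 1]`: the proportion of
#'   partitions assigning each dyad to the same community (diagonal 1).
#'   Carries the number of partitions as attribute `n_boot`.
#' @export
comembership <- function(partitions) {
  if (length(partitions) == 0L) stop("need at least one partition", call. = FALSE)
  membs <- lapply(partitions, function(p) {
    if (inherits(p, "netss_partition")) p$membership else p
  })
  ids <- names(membs[[1]])
  n <- length(membs[[1]])
  acc <- matrix(0, n, n)
  for (m in membs) {
    if (length(m) != n) stop("partitions cover different id sets", call. = FALSE)
    if (!is.null(ids) && !is.null(names(m))) m <- m[ids]
    acc <- acc + outer(m, m, "==")
  }
  p_same <- acc / length(membs)
  dimnames(p_same) <- list(ids, ids)
  attr(p_same, "n_boot") <- length(membs)
  p_same
}

#' Community assortativity coefficient from co-membership proportions
#'
#' Newman's discrete weighted assortativity of the observed community
#' labels, taking the bootstrap co-membership proportions as the edge
#' weights (diagonal excluded): with mixing matrix
#' `e_kl = sum of p_same over dyads with labels (k, l)` normalized to
#' sum 1, `r = (sum_k e_kk - sum_k a_k b_k) / (1 - sum_k a_k b_k)`.
#' Values near 1 mean dyads are almost always re-assorted into the same
#' observed communities; the conventional adequacy threshold is 0.5.
#'
#' Degenerate inputs -- zero total co-membership weight, or an observed
#' partition with a single community (where the coefficient is 0/0) --
#' return 0 with the degenerate flag set.
#'
#' @param obs Observed partition (class `netss_partition` or a
#'   membership vector).
#' @param cm Co-membership matrix from [comembership()].
#' @return A list of class `rcom_result` with `r_com` (clamped to
#'   `[-1, 1]`), `n_boot` and `degenerate`.
#' @export
community_assortativity <- function(obs, cm) {
  memb <- if (inherits(obs, "netss_partition")) obs$membership else obs
  if (length(memb) != nrow(cm)) {
    stop("observed partition and co-membership matrix cover different ids",
         call. = FALSE)
  }
  if (!is.null(names(memb)) && !is.null(rownames(cm))) {
    memb <- memb[rownames(cm)]
  }
  n_boot <- attr(cm, "n_boot") %||% NA_integer_
  w <- unclass(cm)
  diag(w) <- 0
  tot <- sum(w)
  labs <- unique(memb)
  if (tot == 0 || length(labs) < 2L) {
    return(structure(list(r_com = 0, n_boot = n_boot, degenerate = TRUE),
                     class = "rcom_result"))
  }
  M <- outer(memb, labs, "==") + 0  # n x K indicator
  e <- crossprod(M, w %*% M) / tot
  ab <- sum(rowSums(e) * colSums(e))
  if (abs(1 - ab) < 1e-12) {
    # all co-membership weight inside one label class: coefficient is 0/0
    return(structure(list(r_com = 0, n_boot = n_boot, degenerate = TRUE),
                     class = "rcom_result"))
  }
  r <- (sum(diag(e)) - ab) / (1 - ab)
  r <- min(1, max(-1, r))  # clamp numerical overshoot (<= 1e-9)
  structure(list(r_com = r, n_boot = n_boot, degenerate = FALSE),
            class = "rcom_result")
}

#' @export
print.rcom_result <- function(x, ...) {
  cat(sprintf("Rcom = %.4f (%s bootstraps%s)\n", x$r_com,
              ifelse(is.na(x$n_boot), "?", format(x$n_boot)),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Full Rcom pipeline with optional repeat-averaging
#'
#' Detects the observed communities on the half-weight network, runs
#' `n_boot` day-resampling bootstraps, and returns the community
#' assortativity.  With `n_repeat > 1` the whole bootstrap is repeated
#' with derived seeds and the mean coefficient returned, as is done for
#' the reference network (10 repeats of 1000 bootstraps).
#'
#' An edgeless observed network is the defined degenerate case:
#' `r_com = 0`.
#'
#' @param data Roosting `data.frame`.
#' @param n_boot Bootstraps per repeat (default 1000).
#' @param n_repeat Number of repeats to average (default 1).
#' @param seed Optional integer seed.
#' @param ids Individuals to retain (default: all present).
#' @return A list of class `rcom_result` with `r_com`, `n_boot`,
#'   `n_repeat`, `per_repeat` and `degenerate`.
#' @export
rcom_pipeline <- function(data, n_boot = 1000, n_repeat = 1, seed = NULL,
                          ids = NULL) {
  validate_roosting(data)
  ids <- ids %||% sort(unique(as.character(data$individual_id)))
  w <- hwi_fast(data, ids)
  obs <- fast_greedy_communities(w)
  if (obs$degenerate) {
    out <- list(r_com = 0, n_boot = as.integer(n_boot),
                n_repeat = as.integer(n_repeat),
                per_repeat = rep(0, n_repeat), degenerate = TRUE)
    return(structure(out, class = "rcom_result"))
  }
  per <- vapply(seq_len(n_repeat), function(t) {
    st <- if (is.null(seed)) NULL else derive_seed(seed, t)
    parts <- bootstrap_partitions(data, n_boot = n_boot, seed = st, ids = ids)
    community_assortativity(obs, comembership(parts))$r_com
  }, numeric(1))
  structure(list(r_com = mean(per), n_boot = as.integer(n_boot),
                 n_repeat = as.integer(n_repeat), per_repeat = per,
                 degenerate = FALSE),
            class = "rcom_result")
}
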