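# Independent brute-force oracles. Deliberately naive (day-by-day and
# pairwise enumeration) so they share no code path with the package's
# vectorized implementations.

brute_dyad_counts <- function(df, ids) {
  n <- length(ids)
  days <- sort(unique(df$day))
  x <- yab <- ya <- yb <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- ids[i]; b <- ids[j]
      for (d in days) {
        ra <- df$roost_id[df$individual_id == a & df$day == d]
        rb <- df$roost_id[df$individual_id == b & df$day == d]
        if (length(ra) && length(rb)) {
          if (ra == rb) x[i, j] <- x[i, j] + 1 else yab[i, j] <- yab[i, j] + 1
        } else if (length(ra)) {
          ya[i, j] <- ya[i, j] + 1
        } else if (length(rb)) {
          yb[i, j] <- yb[i, j] + 1
        }
      }
      x[j, i] <- x[i, j]; yab[j, i] <- yab[i, j]
      ya[j, i] <- yb[i, j]; yb[j, i] <- ya[i, j]
    }
  }
  list(x = x, y_ab = yab, y_a = ya, y_b = yb)
}

brute_index <- function(bc, type = c("hwi", "sri")) {
  type <- match.arg(type)
  n <- nrow(bc$x)
  w <- matrix(0, n, n, dimnames = dimnames(bc$x))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      den <- if (type == "hwi") {
        bc$x[i, j] + bc$y_ab[i, j] + 0.5 * (bc$y_a[i, j] + bc$y_b[i, j])
      } else {
        bc$x[i, j] + bc$y_ab[i, j] + bc$y_a[i, j] + bc$y_b[i, j]
      }
      w[i, j] <- if (den > 0) bc$x[i, j] / den else 0
    }
  }
  w
}

brute_modularity <- function(w, memb) {
  n <- nrow(w)
  tw <- sum(w)
  if (tw == 0) return(0)
  s <- rowSums(w)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) q <- q + w[i, j] - s[i] * s[j] / tw
    }
  }
  unname(q / tw)
}

brute_density <- function(w) {
  n <- nrow(w)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (w[i, j] > 0) e <- e + 1
  e / choose(n, 2)
}

brute_clustering <- function(w) {
  n <- nrow(w)
  a <- w > 0
  triangles <- 0
  triples <- 0
  for (trip in utils::combn(n, 3, simplify = FALSE)) {
    i <- trip[1]; j <- trip[2]; k <- trip[3]
    ne <- a[i, j] + a[i, k] + a[j, k]
    if (ne == 3) {
      triangles <- triangles + 1
      triples <- triples + 3
    } else if (ne == 2) {
      triples <- triples + 1
    }
  }
  if (triples == 0) 0 else 3 * triangles / triples
}

brute_dyad_similarity <- function(ms, mr) {
  ids <- names(ms)
  agree <- 0
  total <- 0
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      total <- total + 1
      ss <- ms[ids[i]] == ms[ids[j]]
      sr <- mr[ids[i]] == mr[ids[j]]
      if (ss == sr) agree <- agree + 1
    }
  }
  agree / total
}

# Small random detection stream for oracle comparisons.
random_roosting <- function(n_ind = 6, n_days = 10, n_roosts = 3,
                            p_detect = 0.7) {
  ids <- letters[seq_len(n_ind)]
  rows <- list()
  for (d in seq_len(n_days)) {
    det <- ids[stats::runif(n_ind) < p_detect]
    if (!length(det)) next
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = det, day = d,
      roost_id = paste0("r", sample.int(n_roosts, length(det), replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(individual_id = character(), day = integer(),
                      roost_id = character()))
  }
  do.call(rbind, rows)
}

# Random symmetric weighted association matrix with sparse zeros.
random_assoc <- function(n, p_edge = 0.6) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) w[i, j] <- w[j, i] <- stats::runif(1)
    }
  }
  dimnames(w) <- list(letters[seq_len(n)], letters[seq_len(n)])
  w
}
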