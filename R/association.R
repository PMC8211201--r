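# Gambit-of-the-group daily grouping and dyadic association indices.
#
# RoostingData is a plain data.frame with columns individual_id, day,
# roost_id and at most one row per individual-day; every function here
# validates that contract before using it.

validate_roosting <- function(data) {
  need <- c("individual_id", "day", "roost_id")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("roosting data must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[need])) {
    stop("roosting data contains missing values", call. = FALSE)
  }
  dup <- duplicated(data[c("individual_id", "day")])
  if (any(dup)) {
    offending <- utils::head(which(dup), 5L)
    stop("duplicate (individual, day) records at rows ",
         paste(offending, collapse = ", "),
         if (sum(dup) > 5L) sprintf(" (and %d more)", sum(dup) - 5L) else "",
         call. = FALSE)
  }
  invisible(data)
}

#' Group detections into daily roosting groups
#'
#' Restructures long-format detection records into the
#' gambit-of-the-group representation: for each day, the disjoint sets
#' of individuals that shared each roost.  No records are dropped.
#'
#' @param data Roosting data: a `data.frame` with columns
#'   `individual_id`, `day`, `roost_id` and at most one record per
#'   individual-day.
#' @return A named list of class `daily_groups`, one element per day,
#'   each a named list mapping roost id to a character vector of
#'   individual ids.
#' @examples
#' d <- data.frame(individual_id = c("a", "b", "c"), day = c(1, 1, 1),
#'                 roost_id = c("r1", "r1", "r2"))
#' group_by_day(d)
#' @export
group_by_day <- function(data) {
  validate_roosting(data)
  if (nrow(data) == 0L) {
    return(structure(list(), class = "daily_groups"))
  }
  day_split <- split(data[c("individual_id", "roost_id")], data$day)
  out <- lapply(day_split, function(d) {
    lapply(split(d$individual_id, d$roost_id, drop = TRUE), as.character)
  })
  structure(out, class = "daily_groups")
}

groups_to_records <- function(groups) {
  if (length(groups) == 0L) {
    return(data.frame(individual_id = character(), day = integer(),
                      roost_id = character(), stringsAsFactors = FALSE))
  }
  days <- names(groups)
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(individual_id = unlist(g, use.names = FALSE),
               day = rep.int(days[i], sum(lengths(g))),
               roost_id = rep.int(names(g), lengths(g)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Core count engine. df must have <= 1 record per individual-day (or
# per individual-day-instance for bootstrap resamples). Returns the
# symmetric count matrices used by both association indices.
count_matrices <- function(df, ids) {
  n <- length(ids)
  di <- match(df$individual_id, ids)
  keep <- !is.na(di)
  df <- df[keep, , drop = FALSE]
  di <- di[keep]
  if (nrow(df) == 0L) {
    z <- matrix(0, n, n, dimnames = list(ids, ids))
    return(list(ids = ids, x = z, n_both = z, det = stats::setNames(numeric(n), ids)))
  }
  dayf <- factor(df$day)
  grp <- factor(paste(as.integer(dayf), df$roost_id, sep = "\1"))
  G <- Matrix::sparseMatrix(i = as.integer(grp), j = di, x = 1,
                            dims = c(nlevels(grp), n))
  D <- Matrix::sparseMatrix(i = as.integer(dayf), j = di, x = 1,
                            dims = c(nlevels(dayf), n))
  x <- as.matrix(Matrix::crossprod(G))
  n_both <- as.matrix(Matrix::crossprod(D))
  det <- diag(n_both)
  dimnames(x) <- dimnames(n_both) <- list(ids, ids)
  list(ids = ids, x = x, n_both = n_both, det = stats::setNames(det, ids))
}

#' Dyadic togetherness/apartness counts
#'
#' For every dyad (A, B), counts over the sampling periods (days): `x`
#' days roosting together, `y_ab` days both detected but in different
#' roosts, `y_a` days only A detected, `y_b` days only B detected.
#' These are the ingredients of the half-weight and simple-ratio
#' indices.  Individuals outside `ids` are ignored entirely, as if they
#' had never been recorded.
#'
#' @param x A `daily_groups` object from [group_by_day()] or a roosting
#'   `data.frame`.
#' @param ids Character vector of individuals to retain (default: all
#'   individuals present, sorted).
#' @return A list of class `dyad_counts` with the id vector and the
#'   symmetric matrices `x`, `y_ab`, `y_a`, `y_b` (`y_a[i, j]` counts
#'   days the row individual was detected without the column
#'   individual; `y_a = t(y_b)`).
#' @examples
#' d <- data.frame(individual_id = c("a", "b", "a", "b", "a", "b"),
#'                 day = c(1, 1, 2, 2, 3, 3),
#'                 roost_id = c("r1", "r1", "r1", "r1", "r1", "r2"))
#' dyad_counts(d)$x["a", "b"]
#' @export
dyad_counts <- function(x, ids = NULL) {
  df <- if (inherits(x, "daily_groups")) groups_to_records(x) else {
    validate_roosting(x)
    x
  }
  ids <- ids %||% sort(unique(as.character(df$individual_id)))
  cm <- count_matrices(df, ids)
  y_b <- sweep(-cm$n_both, 2, cm$det, "+")  # det_j - n_both
  out <- list(ids = ids,
              x = cm$x,
              y_ab = cm$n_both - cm$x,
              y_a = t(y_b),
              y_b = y_b)
  diag(out$x) <- diag(out$y_ab) <- diag(out$y_a) <- diag(out$y_b) <- 0
  structure(out, class = "dyad_counts")
}

index_from_counts <- function(counts, denom) {
  w <- counts$x / denom
  w[!is.finite(w)] <- 0  # zero-denominator dyads carry no edge
  diag(w) <- 0
  dimnames(w) <- list(counts$ids, counts$ids)
  w
}

#' Half-weight association index
#'
#' `HWI = x / (x + y_ab + (y_a + y_b) / 2)`: the proportion of sampling
#' periods a dyad spent together, down-weighting periods in which only
#' one member was detected and therefore suited to data streams with
#' incomplete daily detection.  Dyads with a zero denominator (never
#' detected) get index 0.
#'
#' @param counts A [dyad_counts()] object.
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal and
#'   the individual ids as dimnames.
#' @examples
#' # together 2 days, apart 1, each alone once: 2 / (2 + 1 + 1) = 0.5
#' d <- data.frame(
#'   individual_id = c("a", "b", "a", "b", "a", "b", "a", "b"),
#'   day = c(1, 1, 2, 2, 3, 3, 4, 5),
#'   roost_id = c("r1", "r1", "r1", "r1", "r1", "r2", "r1", "r1"))
#' half_weight_index(dyad_counts(d))["a", "b"]
#' @export
half_weight_index <- function(counts) {
  stopifnot(inherits(counts, "dyad_counts"))
  index_from_counts(counts,
                    counts$x + counts$y_ab + 0.5 * (counts$y_a + counts$y_b))
}

#' Simple-ratio association index
#'
#' `SRI = x / (x + y_ab + y_a + y_b)`: the proportion of sampling
#' periods in which at least one member of the dyad was detected that
#' the two spent together.  Always less than or equal to the
#' half-weight index.
#'
#' @inheritParams half_weight_index
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal.
#' @export
simple_ratio_index <- function(counts) {
  stopifnot(inherits(counts, "dyad_counts"))
  index_from_counts(counts,
                    counts$x + counts$y_ab + counts$y_a + counts$y_b)
}

#' Association matrix from roosting records
#'
#' Convenience wrapper composing [group_by_day()], [dyad_counts()] and
#' the chosen index.
#'
#' @param data Roosting `data.frame`.
#' @param ids Individuals to retain (default: all present).
#' @param index `"hwi"` (default) or `"sri"`.
#' @return Symmetric association matrix.
#' @export
association_matrix <- function(data, ids = NULL, index = c("hwi", "sri")) {
  index <- match.arg(index)
  counts <- dyad_counts(data, ids = ids)
  switch(index,
         hwi = half_weight_index(counts),
         sri = simple_ratio_index(counts))
}

# Fast internal HWI used in permutation/bootstrap loops. Relies on the
# one-record-per-individual-day invariant, under which the HWI
# denominator collapses to (det_i + det_j) / 2 and only the
# co-occurrence counts change between within-day permutations.
assoc_from_assignment <- function(gi, dj, n, n_groups, denom) {
  G <- Matrix::sparseMatrix(i = gi, j = dj, x = 1, dims = c(n_groups, n))
  w <- as.matrix(Matrix::crossprod(G)) / denom
  w[!is.finite(w)] <- 0
  diag(w) <- 0
  w
}

hwi_fast <- function(df, ids) {
  n <- length(ids)
  di <- match(df$individual_id, ids)
  keep <- !is.na(di)
  df <- df[keep, , drop = FALSE]
  di <- di[keep]
  if (nrow(df) == 0L) {
    return(matrix(0, n, n, dimnames = list(ids, ids)))
  }
  dayf <- factor(df$day)
  grp <- factor(paste(as.integer(dayf), df$roost_id, sep = "\1"))
  det <- tabulate(di, n)
  denom <- outer(det, det, "+") / 2
  w <- assoc_from_assignment(as.integer(grp), di, n, nlevels(grp), denom)
  dimnames(w) <- list(ids, ids)
  w
}
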