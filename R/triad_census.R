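#' The 16 MAN triad types
#'
#' Holland-Leinhardt codes for the 16 isomorphism classes of a 3-node directed
#' graph. The three digits count Mutual, Asymmetric and Null dyads; the letter
#' disambiguates orientation (D own, U up, T transitive, C cyclic).
#'
#' @return data frame with columns `code`, `mutual`, `asymmetric`, `null`.
#' @export
triad_types <- function() {
  data.frame(
    code = TRIAD_CODES,
    mutual = c(0,0,1,0,0,0,1,1,0,0,2,1,1,1,2,3),
    asymmetric = c(0,1,0,2,2,2,1,1,3,3,0,2,2,2,1,0),
    null = c(3,2,2,1,1,1,1,1,0,0,1,0,0,0,0,0),
    stringsAsFactors = FALSE)
}

TRIAD_CODES <- c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
                 "030T", "030C", "201", "120D", "120U", "120C", "210", "300")

#' Transitive / intransitive partition of the 16 triad types
#'
#' By default the transitive side holds the types containing at least one
#' non-vacuously transitive ordered triple and no intransitive one
#' (030T, 120D, 120U, 300 — 300 being the complete, fully balanced triad);
#' every other type, including the vacuous 003/012/102 and the mixed 111U,
#' is reported as intransitive. An optional `vacuous` set turns the binary
#' partition into a three-way one for sensitivity analysis.
#'
#' @param transitive character vector of codes counted as transitive.
#' @param vacuous optional character vector of codes reported separately as
#'   vacuous instead of intransitive.
#' @return object of class `transitivity_scheme`.
#' @export
transitivity_scheme <- function(transitive = c("030T", "120D", "120U", "300"),
                                vacuous = NULL) {
  bad <- setdiff(c(transitive, vacuous), TRIAD_CODES)
  if (length(bad) > 0) {
    ts_stop(sprintf("unknown triad code(s): %s", paste(bad, collapse = ", ")),
            "validation_error")
  }
  if (!"300" %in% transitive) {
    ts_stop("the complete triad 300 must be in the transitive set",
            "validation_error")
  }
  if (any(c("012", "102", "111U") %in% transitive)) {
    ts_stop("types 012, 102 and 111U cannot be counted as transitive",
            "validation_error")
  }
  if (length(intersect(transitive, vacuous)) > 0) {
    ts_stop("transitive and vacuous sets must be disjoint", "validation_error")
  }
  structure(list(transitive = transitive, vacuous = vacuous,
                 intransitive = setdiff(TRIAD_CODES, c(transitive, vacuous))),
            class = "transitivity_scheme")
}

# Rule-based MAN classification of a single labelled 3-node digraph.
# Dyad states: 0 null, 1/2 asymmetric, 3 mutual; the letter is resolved from
# in/out degrees among asymmetric arcs.
classify_triad_matrix <- function(a) {
  dy <- c(a[1, 2] + 2L * a[2, 1],
          a[1, 3] + 2L * a[3, 1],
          a[2, 3] + 2L * a[3, 2])
  m <- sum(dy == 3L)
  nn <- sum(dy == 0L)
  as_ <- 3L - m - nn
  base <- paste0(m, as_, nn)
  if (!base %in% c("021", "111", "030", "120")) {
    return(base)
  }
  outd <- rowSums(a)
  ind <- colSums(a)
  if (base == "021") {
    if (any(outd == 2)) return("021D")
    if (any(ind == 2)) return("021U")
    return("021C")
  }
  if (base == "030") {
    return(if (all(outd == 1)) "030C" else "030T")
  }
  # 111 and 120: locate the node outside the mutual dyad and look at the
  # direction of its asymmetric arc(s) relative to the mutual pair.
  pair_idx <- which(dy == 3L)[1]
  pair <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))[[pair_idx]]
  x <- setdiff(1:3, pair)
  sends <- sum(a[x, pair])
  if (base == "111") {
    return(if (sends == 1) "111D" else "111U")
  }
  if (sends == 2) return("120D")
  if (sends == 0) return("120U")
  "120C"
}

# 64-entry lookup: arc pattern bits (a12,a21,a13,a31,a23,a32) -> type index.
TRIAD_LOOKUP <- local({
  lk <- integer(64)
  for (code6 in 0:63) {
    bits <- as.integer(intToBits(code6))[1:6]
    a <- matrix(0L, 3, 3)
    a[1, 2] <- bits[1]; a[2, 1] <- bits[2]
    a[1, 3] <- bits[3]; a[3, 1] <- bits[4]
    a[2, 3] <- bits[5]; a[3, 2] <- bits[6]
    lk[code6 + 1L] <- match(classify_triad_matrix(a), TRIAD_CODES)
  }
  lk
})

#' Classify a single triad
#'
#' @param sub 3x3 0/1 adjacency matrix with zero diagonal (`sub[i, j] == 1`
#'   means `i -> j`).
#' @return the MAN code of the triad type isomorphic to `sub`, e.g. `"030T"`
#'   for the transitive pattern X->Y, Y->Z, X->Z.
#' @export
classify_triad <- function(sub) {
  sub <- as.matrix(sub)
  if (!all(dim(sub) == c(3, 3))) {
    ts_stop("a triad is a 3x3 adjacency matrix", "shape_error")
  }
  if (anyNA(sub) || !all(sub %in% c(0, 1)) || any(diag(sub) != 0)) {
    ts_stop("triad adjacency must be 0/1 with zero diagonal", "shape_error")
  }
  storage.mode(sub) <- "integer"
  TRIAD_CODES[TRIAD_LOOKUP[1L + sub[1, 2] + 2L * sub[2, 1] + 4L * sub[1, 3] +
                           8L * sub[3, 1] + 16L * sub[2, 3] + 32L * sub[3, 2]]]
}

# Type index (1..16) per unordered triple of a network; internal workhorse.
triple_types <- function(adj) {
  n <- nrow(adj)
  tri <- combn(n, 3)
  i <- tri[1, ]; j <- tri[2, ]; k <- tri[3, ]
  code <- adj[cbind(i, j)] + 2L * adj[cbind(j, i)] +
    4L * adj[cbind(i, k)] + 8L * adj[cbind(k, i)] +
    16L * adj[cbind(j, k)] + 32L * adj[cbind(k, j)]
  list(i = i, j = j, k = k, type = TRIAD_LOOKUP[code + 1L])
}

#' Triad census of a directed network
#'
#' Counts, over all `choose(n, 3)` unordered actor triples, how many fall in
#' each of the 16 MAN triad types, and partitions the total into transitive
#' and intransitive triads under `scheme`.
#'
#' @param net a [binary_network()].
#' @param scheme a [transitivity_scheme()].
#' @return object of class `triad_census`: a list with `counts` (named
#'   16-vector), `n_actors`, `n_triads`, `transitive_total`,
#'   `intransitive_total`, `vacuous_total` (when the scheme defines a vacuous
#'   set), `transitive_share`, `zero_triads` and the scheme. Networks with
#'   fewer than 3 actors yield an all-zero census flagged `zero_triads`.
#' @export
triad_census <- function(net, scheme = transitivity_scheme()) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$actor_order)
  counts <- setNames(integer(16), TRIAD_CODES)
  if (n < 3) {
    return(new_triad_census(counts, n, scheme, zero_triads = TRUE))
  }
  tt <- triple_types(net$adjacency)
  counts[] <- tabulate(tt$type, 16L)
  new_triad_census(counts, n, scheme)
}

new_triad_census <- function(counts, n_actors, scheme, zero_triads = FALSE) {
  total <- sum(counts)
  trans <- sum(counts[scheme$transitive])
  vac <- if (is.null(scheme$vacuous)) NULL else sum(counts[scheme$vacuous])
  structure(list(
    counts = counts,
    n_actors = n_actors,
    n_triads = total,
    transitive_total = trans,
    intransitive_total = sum(counts[scheme$intransitive]),
    vacuous_total = vac,
    transitive_share = if (total > 0) trans / total else 0,
    zero_triads = zero_triads || total == 0,
    scheme = scheme), class = "triad_census")
}

#' @export
print.triad_census <- function(x, ...) {
  cat(sprintf("<triad_census> %s actors, %d triads: %d transitive (%.2f%%), %d intransitive\n",
              paste(x$n_actors, collapse = "+"), x$n_triads,
              x$transitive_total, 100 * x$transitive_share,
              x$intransitive_total))
  nz <- x$counts[x$counts > 0]
  if (length(nz) > 0) {
    cat(" ", paste(sprintf("%s:%d", names(nz), nz), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Triad type percentages
#'
#' @param census a [triad_census()].
#' @return named numeric vector: percentage of all triads in each of the 16
#'   types (sums to 100).
#' @export
census_proportions <- function(census) {
  stopifnot(inherits(census, "triad_census"))
  if (census$n_triads == 0) {
    ts_stop("cannot compute proportions of a zero-triad census",
            "undefined_proportion_error")
  }
  100 * census$counts / census$n_triads
}

#' Per-actor triad participation profile
#'
#' For each actor, counts the transitive and intransitive triads (under
#' `scheme`) among the `choose(n - 1, 2)` triples containing that actor. Each
#' triad contains three actors, so each per-type column sums to three times
#' the corresponding census total.
#'
#' @inheritParams triad_census
#' @return data frame with columns `actor`, `transitive`, `intransitive`,
#'   `total`, one row per actor in `actor_order`.
#' @export
node_triad_profile <- function(net, scheme = transitivity_scheme()) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$actor_order)
  if (n < 3) {
    return(data.frame(actor = net$actor_order,
                      transitive = integer(n), intransitive = integer(n),
                      total = integer(n), stringsAsFactors = FALSE))
  }
  tt <- triple_types(net$adjacency)
  is_trans <- TRIAD_CODES[tt$type] %in% scheme$transitive
  nodes <- c(tt$i, tt$j, tt$k)
  flag <- rep(is_trans, 3)
  trans <- tabulate(nodes[flag], n)
  intr <- tabulate(nodes[!flag], n)
  # the vacuous set (if any) is counted inside "intransitive" here; the
  # profile partition is deliberately binary, mirroring the census labels
  data.frame(actor = net$actor_order, transitive = trans,
             intransitive = intr, total = trans + intr,
             stringsAsFactors = FALSE)
}

#' Aggregate censuses across classrooms
#'
#' Componentwise sum of per-classroom censuses, e.g. to form the rural and
#' urban setting totals. `n_actors` becomes the vector of classroom sizes and
#' `transitive_share` the ratio of summed transitive triads to summed triads.
#'
#' @param censuses nonempty list of [triad_census()] objects computed under
#'   the same scheme.
#' @return a [triad_census()].
#' @export
aggregate_censuses <- function(censuses) {
  if (!is.list(censuses) || length(censuses) == 0 ||
      !all(vapply(censuses, inherits, TRUE, "triad_census"))) {
    ts_stop("aggregate_censuses needs a nonempty list of triad_census objects",
            "usage_error")
  }
  schemes <- lapply(censuses, function(cc) cc$scheme$transitive)
  if (length(unique(lapply(schemes, sort))) != 1) {
    ts_stop("censuses were computed under different transitivity schemes",
            "usage_error")
  }
  counts <- Reduce(`+`, lapply(censuses, `[[`, "counts"))
  n_actors <- unlist(lapply(censuses, `[[`, "n_actors"))
  new_triad_census(counts, n_actors, censuses[[1]]$scheme)
}
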