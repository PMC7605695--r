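#' Same-attribute (homophilous) subnetwork
#'
#' Restricts a binary network to ties between actors sharing an attribute
#' value — the homophily reading of a gender-composed network: people tend to
#' tie with others of similar social characteristics, so the same-gender
#' subnetwork isolates the ties homophily can act on.
#'
#' @param net a [binary_network()].
#' @param ros a [roster()] covering every actor of `net`.
#' @param attribute roster column to compose on (default `"gender"`).
#' @return a [binary_network()] with ties `i -> j` kept iff
#'   `attribute(i) == attribute(j)`; layer is `"gender_homophilous"` for the
#'   gender attribute, `"<attribute>_homophilous"` otherwise.
#' @export
homophilous_subnetwork <- function(net, ros, attribute = "gender") {
  vals <- actor_attribute(net, ros, attribute)
  same <- outer(vals, vals, `==`)
  adj <- net$adjacency * (same * 1L)
  binary_network(adj, net$actor_order, classroom = net$classroom,
                 layer = paste0(attribute, "_homophilous"))
}

actor_attribute <- function(net, ros, attribute) {
  if (!attribute %in% names(ros)) {
    ts_stop(sprintf("roster has no attribute column '%s'", attribute),
            "validation_error")
  }
  idx <- match(net$actor_order, ros$id)
  if (anyNA(idx)) {
    ts_stop(sprintf("actor(s) missing from roster: %s",
                    paste(net$actor_order[is.na(idx)], collapse = ", ")),
            "validation_error")
  }
  vals <- ros[[attribute]][idx]
  if (anyNA(vals)) {
    ts_stop(sprintf("attribute '%s' missing for actor(s): %s", attribute,
                    paste(net$actor_order[is.na(vals)], collapse = ", ")),
            "validation_error")
  }
  as.character(vals)
}

#' Attribute-stratified triad census
#'
#' Partitions the `choose(n, 3)` actor triples by the multiset of attribute
#' values they carry (for gender: FFF, FFM, FMM, MMM) and computes a triad
#' census within each stratum. Summing any type's count over strata recovers
#' the unstratified census.
#'
#' @inheritParams homophilous_subnetwork
#' @param scheme a [transitivity_scheme()].
#' @return object of class `stratified_census`: named list of
#'   [triad_census()] objects, keyed by stratum (gender values are
#'   abbreviated to initials, e.g. `"FFM"`; other attributes use the sorted
#'   values joined by `"+"`).
#' @export
stratified_census <- function(net, ros, attribute = "gender",
                              scheme = transitivity_scheme()) {
  vals <- actor_attribute(net, ros, attribute)
  n <- length(net$actor_order)
  if (n < 3) {
    return(structure(list(), class = "stratified_census"))
  }
  tt <- triple_types(net$adjacency)
  keys <- stratum_keys(vals, tt, attribute)
  out <- lapply(split(tt$type, keys), function(types) {
    counts <- setNames(tabulate(types, 16L), TRIAD_CODES)
    new_triad_census(counts, n_actors = NA_integer_, scheme)
  })
  structure(out, class = "stratified_census")
}

stratum_keys <- function(vals, tt, attribute) {
  v <- if (attribute == "gender") toupper(substr(vals, 1, 1)) else vals
  sep <- if (attribute == "gender") "" else "+"
  m <- rbind(v[tt$i], v[tt$j], v[tt$k])
  apply(m, 2, function(x) paste(sort(x), collapse = sep))
}

#' Co-drinking consumption layer
#'
#' Builds the consumption network from the nomination question ("those
#' colleagues in class with whom you go out and have a drink with").
#' Nominations are directed and kept as such by default; optionally they are
#' intersected with an existing contact layer and/or union-symmetrized.
#'
#' @param nominations a [binary_network()] of drinking nominations.
#' @param contact optional [binary_network()] contact layer over the same
#'   actors (required when `restrict_to_contact = TRUE`).
#' @param restrict_to_contact keep a nomination only where the contact tie
#'   also exists (default `FALSE`).
#' @param symmetrize union-symmetrize the result (default `FALSE`).
#' @return a [binary_network()] with layer `"consumption"`.
#' @export
consumption_layer <- function(nominations, contact = NULL,
                              restrict_to_contact = FALSE, symmetrize = FALSE) {
  adj <- nominations$adjacency
  if (restrict_to_contact) {
    if (is.null(contact)) {
      ts_stop("restrict_to_contact requires a contact network", "usage_error")
    }
    if (!identical(nominations$actor_order, contact$actor_order)) {
      ts_stop("nomination and contact networks have different actor orders",
              "alignment_error")
    }
    adj <- adj * contact$adjacency
  }
  if (symmetrize) adj <- 1L * ((adj + t(adj)) > 0)
  binary_network(adj, nominations$actor_order,
                 classroom = nominations$classroom, layer = "consumption")
}
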