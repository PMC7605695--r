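#' Intensity thresholds for dichotomizing ordinal contact ratings
#'
#' A rating of 1 means "we never coincided", 5 "we are always together". A tie
#' exists at a level when the rating reaches that level's cut: by default
#' minimum >= 2, intermediate >= 3, maximum >= 4, so the three binary layers
#' are nested (maximum ties are a subset of intermediate ties, which are a
#' subset of minimum ties).
#'
#' @param minimum_cut,intermediate_cut,maximum_cut integer cuts; must satisfy
#'   `2 <= minimum_cut <= intermediate_cut <= maximum_cut <= 5` (enforced so
#'   the nesting property always holds).
#' @return object of class `intensity_thresholds`.
#' @export
intensity_thresholds <- function(minimum_cut = 2, intermediate_cut = 3,
                                 maximum_cut = 4) {
  cuts <- c(minimum = as.integer(minimum_cut),
            intermediate = as.integer(intermediate_cut),
            maximum = as.integer(maximum_cut))
  if (anyNA(cuts) || cuts[1] < 2 || cuts[3] > 5 || is.unsorted(cuts)) {
    ts_stop("cuts must satisfy 2 <= minimum <= intermediate <= maximum <= 5",
            "validation_error")
  }
  structure(list(minimum_cut = cuts[[1]], intermediate_cut = cuts[[2]],
                 maximum_cut = cuts[[3]]),
            class = "intensity_thresholds")
}

#' Dichotomize an ordinal contact matrix at one intensity level
#'
#' Converts 1--5 ratings to a 0/1 directed network: a tie `i -> j` exists iff
#' actor `i`'s rating of `j` reaches the level's cut. Missing ratings (`NA`)
#' dichotomize to 0 at every level; the diagonal is forced to 0.
#'
#' @param mat a [contact_matrix()].
#' @param level `"minimum"`, `"intermediate"` or `"maximum"`.
#' @param thresholds an [intensity_thresholds()] object.
#' @return a [binary_network()] with `layer` set to `level`.
#' @export
dichotomize <- function(mat, level = c("minimum", "intermediate", "maximum"),
                        thresholds = intensity_thresholds()) {
  if (!is.character(level) || !all(level %in% c("minimum", "intermediate", "maximum"))) {
    ts_stop(sprintf("unknown dichotomization level '%s'", level[1]), "usage_error")
  }
  level <- match.arg(level)
  cut <- switch(level, minimum = thresholds$minimum_cut,
                intermediate = thresholds$intermediate_cut,
                maximum = thresholds$maximum_cut)
  adj <- (!is.na(mat$values)) & (mat$values >= cut)
  storage.mode(adj) <- "integer"
  binary_network(adj, mat$actor_order, classroom = mat$classroom, layer = level)
}

#' Dichotomize at all three intensity levels
#'
#' @inheritParams dichotomize
#' @return named list of three [binary_network()]s (`minimum`, `intermediate`,
#'   `maximum`), satisfying ties(maximum) subset of ties(intermediate) subset
#'   of ties(minimum).
#' @export
dichotomize_all <- function(mat, thresholds = intensity_thresholds()) {
  list(minimum = dichotomize(mat, "minimum", thresholds),
       intermediate = dichotomize(mat, "intermediate", thresholds),
       maximum = dichotomize(mat, "maximum", thresholds))
}
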