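#' Construct and validate a roster of actors
#'
#' A roster holds one row per student with identifier, gender, age, classroom,
#' rural/urban setting and the ten AUDIT item scores (`audit_1` .. `audit_10`).
#' Gender labels are normalised to `"female"`/`"male"` (initials `F`/`M` are
#' accepted); identifiers are whitespace-trimmed and matched case-sensitively.
#'
#' @param df data frame with columns `id`, `gender`, `age`, `classroom`,
#'   `setting`, `audit_1` .. `audit_10`.
#' @param age_range plausibility window for ages, default `c(10, 25)`.
#' @return the validated roster (a `data.frame` of class `roster`), row order
#'   preserved.
#' @details Invariants enforced: unique ids; ages inside `age_range`; setting
#'   is `"rural"` or `"urban"` and constant within each classroom; AUDIT items
#'   1--8 in 0..4 and items 9--10 in \{0, 2, 4\}.
#' @export
roster <- function(df, age_range = c(10, 25)) {
  required <- c("id", "gender", "age", "classroom", "setting",
                paste0("audit_", 1:10))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    ts_stop(sprintf("roster is missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "schema_error")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$id <- trimws(as.character(df$id))
  if (anyDuplicated(df$id)) {
    ts_stop(sprintf("duplicate actor id(s): %s",
                    paste(unique(df$id[duplicated(df$id)]), collapse = ", ")),
            "validation_error")
  }
  df$gender <- normalize_gender(df$gender)
  df$setting <- tolower(trimws(as.character(df$setting)))
  if (!all(df$setting %in% c("rural", "urban"))) {
    ts_stop("setting must be 'rural' or 'urban'", "validation_error")
  }
  df$classroom <- as.character(df$classroom)
  by_class <- split(df$setting, df$classroom)
  mixed <- names(by_class)[vapply(by_class, function(s) length(unique(s)) > 1, TRUE)]
  if (length(mixed) > 0) {
    ts_stop(sprintf("setting is not constant within classroom(s): %s",
                    paste(mixed, collapse = ", ")),
            "validation_error")
  }
  df$age <- as.integer(df$age)
  bad_age <- which(is.na(df$age) | df$age < age_range[1] | df$age > age_range[2])
  if (length(bad_age) > 0) {
    ts_stop(sprintf("age outside plausibility window [%d, %d] for actor(s): %s",
                    age_range[1], age_range[2],
                    paste(df$id[bad_age], collapse = ", ")),
            "validation_error")
  }
  validate_audit_items(df)
  class(df) <- c("roster", "data.frame")
  df
}

normalize_gender <- function(g) {
  g <- tolower(trimws(as.character(g)))
  out <- ifelse(g %in% c("f", "female"), "female",
         ifelse(g %in% c("m", "male"), "male", NA_character_))
  if (anyNA(out)) {
    ts_stop(sprintf("unrecognised gender value(s): %s",
                    paste(unique(g[is.na(out)]), collapse = ", ")),
            "validation_error")
  }
  out
}

validate_audit_items <- function(df) {
  for (item in 1:10) {
    col <- df[[paste0("audit_", item)]]
    allowed <- if (item <= 8) 0:4 else c(0, 2, 4)
    bad <- which(!(col %in% allowed))
    if (length(bad) > 0) {
      ts_stop(sprintf(
        "AUDIT item %d out of range for actor %s: value %s (allowed: %s)",
        item, df$id[bad[1]], col[bad[1]],
        paste(allowed, collapse = ",")),
        "validation_error")
    }
  }
  invisible(df)
}

#' Ordinal contact matrix for one classroom
#'
#' Directed sociometric ratings answering "indicate how much time you spend
#' with your classmates", coded 1 ("we never coincided") to 5 ("we are always
#' together"). Row `i` holds the ratings given BY actor `i` OF each column
#' actor (rows are raters / out-ties). The diagonal is undefined (self-rating)
#' and ignored. `NA` marks a missing rating (e.g. an absent respondent).
#'
#' @param values square integer matrix with off-diagonal entries in 1..5 or `NA`.
#' @param actor_order character vector of actor ids in matrix order; defaults
#'   to the rownames of `values`.
#' @param classroom classroom label.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, actor_order = rownames(values), classroom = "") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    ts_stop(sprintf("contact matrix must be square (got %d x %d)",
                    nrow(values), ncol(values)),
            "shape_error")
  }
  n <- nrow(values)
  if (is.null(actor_order)) actor_order <- as.character(seq_len(n))
  actor_order <- trimws(as.character(actor_order))
  if (length(actor_order) != n || anyDuplicated(actor_order)) {
    ts_stop("actor_order must name each row once", "validation_error")
  }
  storage.mode(values) <- "integer"
  off <- values
  diag(off) <- NA_integer_
  bad <- which(!is.na(off) & (off < 1L | off > 5L), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ts_stop(sprintf("contact value out of range {1..5} at [%s, %s]: %d",
                    actor_order[bad[1, 1]], actor_order[bad[1, 2]],
                    values[bad[1, , drop = FALSE]]),
            "validation_error")
  }
  dimnames(values) <- list(actor_order, actor_order)
  structure(list(classroom = classroom, actor_order = actor_order,
                 values = values),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> classroom '%s', %d actors, ratings 1-5%s\n",
              x$classroom, length(x$actor_order),
              if (anyNA(x$values[row(x$values) != col(x$values)]))
                " (has missing ratings)" else ""))
  invisible(x)
}

#' Binary directed network layer for one classroom
#'
#' @param adjacency square 0/1 matrix; `adjacency[i, j] == 1` means actor `i`
#'   directs a tie to actor `j`. The diagonal is forced to 0.
#' @param actor_order character vector of actor ids in matrix order.
#' @param classroom classroom label.
#' @param layer one of `"minimum"`, `"intermediate"`, `"maximum"`,
#'   `"gender_homophilous"`, `"consumption"`, or another descriptive label for
#'   derived layers.
#' @return object of class `binary_network`.
#' @export
binary_network <- function(adjacency, actor_order = rownames(adjacency),
                           classroom = "", layer = "minimum") {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    ts_stop(sprintf("adjacency must be square (got %d x %d)",
                    nrow(adjacency), ncol(adjacency)),
            "shape_error")
  }
  n <- nrow(adjacency)
  if (is.null(actor_order)) actor_order <- as.character(seq_len(n))
  actor_order <- trimws(as.character(actor_order))
  if (length(actor_order) != n || anyDuplicated(actor_order)) {
    ts_stop("actor_order must name each row once", "validation_error")
  }
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1))) {
    ts_stop("adjacency entries must be 0 or 1", "validation_error")
  }
  storage.mode(adjacency) <- "integer"
  diag(adjacency) <- 0L
  dimnames(adjacency) <- list(actor_order, actor_order)
  structure(list(classroom = classroom, actor_order = actor_order,
                 adjacency = adjacency, layer = layer),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> classroom '%s', layer '%s', %d actors, %d ties\n",
              x$classroom, x$layer, length(x$actor_order), sum(x$adjacency)))
  invisible(x)
}

#' Score one AUDIT response
#'
#' Sums the ten item scores of the Alcohol Use Disorders Identification Test
#' (items 1--8 scored 0--4, items 9--10 scored 0/2/4; total 0--40) and
#' classifies the respondent as at risk of harmful consumption when the total
#' reaches `threshold`.
#'
#' @param items integer vector of the 10 item scores, in instrument order.
#' @param threshold risk cut-off on the total score; the instrument's
#'   conventional cut of 8 is the default.
#' @param actor_id optional actor identifier carried through to the result.
#' @return list with `actor_id`, `audit_total`, `at_risk`, `threshold`.
#' @export
score_audit <- function(items, threshold = 8, actor_id = NA_character_) {
  if (length(items) != 10) {
    ts_stop("an AUDIT response has exactly 10 items", "validation_error")
  }
  for (i in 1:10) {
    allowed <- if (i <= 8) 0:4 else c(0, 2, 4)
    if (!(items[i] %in% allowed)) {
      ts_stop(sprintf("AUDIT item %d value %s outside allowed set {%s}%s",
                      i, items[i], paste(allowed, collapse = ","),
                      if (is.na(actor_id)) "" else paste0(" for actor ", actor_id)),
              "validation_error")
    }
  }
  total <- as.integer(sum(items))
  list(actor_id = actor_id, audit_total = total,
       at_risk = total >= threshold, threshold = as.integer(threshold))
}

#' Score every AUDIT response on a roster
#'
#' @param ros a [roster()].
#' @param threshold risk cut-off on the AUDIT total, default 8.
#' @return data frame with columns `id`, `gender`, `classroom`, `setting`,
#'   `audit_total`, `at_risk`, `threshold`.
#' @export
score_audit_all <- function(ros, threshold = 8) {
  items <- as.matrix(ros[, paste0("audit_", 1:10)])
  total <- as.integer(rowSums(items))
  data.frame(id = ros$id, gender = ros$gender, classroom = ros$classroom,
             setting = ros$setting, audit_total = total,
             at_risk = total >= threshold,
             threshold = as.integer(threshold),
             stringsAsFactors = FALSE)
}
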