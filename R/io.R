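#' Read a roster CSV
#'
#' Expected columns: `id, gender, age, classroom, setting, audit_1..audit_10`.
#' Parsing preserves file row order; records are keyed by `id`, so shuffling
#' rows changes nothing but the order.
#'
#' @param path CSV file path.
#' @param age_range plausibility window passed to [roster()].
#' @return a validated [roster()].
#' @export
read_roster <- function(path, age_range = c(10, 25)) {
  if (!file.exists(path)) ts_stop(sprintf("no such file: %s", path), "io_error")
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 comment.char = "#")
  roster(df, age_range = age_range)
}

#' Write a roster CSV
#' @param ros a [roster()].
#' @param path output path.
#' @export
write_roster <- function(ros, path) {
  write.csv(as.data.frame(ros), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ordinal contact matrix
#'
#' Two dialects are supported: `csv` (first row and first column are actor
#' ids, body integer ratings 1--5) and `ucinet_dl` (the UCINET DL `fullmatrix`
#' variant, with an optional `labels:` section). Other DL variants are
#' rejected.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"ucinet_dl"`.
#' @param classroom classroom label to attach.
#' @param missing how to handle missing ratings (empty / `NA` cells):
#'   `"as_never"` (default) recodes them as 1, "we never coincided";
#'   `"drop_actor"` removes non-respondents (actors with missing given ratings);
#'   `"keep"` keeps `NA`, which later dichotomizes to no-tie at every level.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, dialect = c("csv", "ucinet_dl"),
                                classroom = "",
                                missing = c("as_never", "drop_actor", "keep")) {
  dialect <- match.arg(dialect)
  missing <- match.arg(missing)
  if (!file.exists(path)) ts_stop(sprintf("no such file: %s", path), "io_error")
  if (dialect == "csv") {
    df <- read.csv(path, row.names = 1, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
    values <- as.matrix(df)
    actor_order <- trimws(rownames(df))
    if (!identical(actor_order, trimws(colnames(values)))) {
      ts_stop("contact matrix row and column labels differ", "validation_error")
    }
  } else {
    dl <- parse_dl(path)
    if (dl$format != "fullmatrix") {
      ts_stop("contact matrices require the DL fullmatrix variant", "io_error")
    }
    values <- dl$matrix
    actor_order <- dl$labels
  }
  values <- resolve_missing_contact(values, actor_order, missing)
  contact_matrix(values$m, values$order, classroom = classroom)
}

resolve_missing_contact <- function(m, actor_order, missing) {
  storage.mode(m) <- "integer"
  off <- row(m) != col(m)
  if (missing == "as_never") {
    m[off & is.na(m)] <- 1L
  } else if (missing == "drop_actor") {
    # drop the non-respondents: actors whose GIVEN ratings are missing
    # (removing their rows and columns leaves no missing cells behind)
    incomplete <- is.na(m) & off
    drop <- which(rowSums(incomplete) > 0)
    if (length(drop) > 0) {
      keep <- setdiff(seq_len(nrow(m)), drop)
      m <- m[keep, keep, drop = FALSE]
      actor_order <- actor_order[keep]
    }
  }
  list(m = m, order = actor_order)
}

#' Write an ordinal contact matrix
#' @param mat a [contact_matrix()].
#' @param path output path.
#' @param dialect `"csv"` or `"ucinet_dl"`.
#' @export
write_contact_matrix <- function(mat, path, dialect = c("csv", "ucinet_dl")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    write.csv(as.data.frame(mat$values), path, quote = FALSE)
  } else {
    write_dl_fullmatrix(mat$values, mat$actor_order, path)
  }
  invisible(path)
}

#' Write a binary network
#'
#' Three dialects: a labelled adjacency `csv`, UCINET DL `fullmatrix`
#' (`ucinet_dl`), and an `edge_list` CSV (`source,target` rows, sorted
#' deterministically by source then target label). The csv and edge_list
#' dialects carry the classroom, layer and actor list in `#` comment lines so
#' the file round-trips exactly (isolates included).
#'
#' @param net a [binary_network()].
#' @param path output path.
#' @param dialect `"csv"`, `"ucinet_dl"` or `"edge_list"`.
#' @export
write_network <- function(net, path, dialect = c("csv", "ucinet_dl", "edge_list")) {
  dialect <- match.arg(dialect)
  con <- try(suppressWarnings(file(path, "w")), silent = TRUE)
  if (inherits(con, "try-error")) {
    ts_stop(sprintf("cannot open '%s' for writing", path), "io_error")
  }
  on.exit(close(con))
  meta <- c(sprintf("# classroom: %s", net$classroom),
            sprintf("# layer: %s", net$layer),
            sprintf("# actors: %s", paste(net$actor_order, collapse = ",")))
  if (dialect == "csv") {
    writeLines(meta, con)
    writeLines(paste(c("", net$actor_order), collapse = ","), con)
    for (i in seq_along(net$actor_order)) {
      writeLines(paste(c(net$actor_order[i], net$adjacency[i, ]), collapse = ","), con)
    }
  } else if (dialect == "ucinet_dl") {
    close(con); on.exit()
    write_dl_fullmatrix(net$adjacency, net$actor_order, path)
  } else {
    writeLines(meta, con)
    writeLines("source,target", con)
    e <- which(net$adjacency == 1L, arr.ind = TRUE)
    if (nrow(e) > 0) {
      src <- net$actor_order[e[, 1]]
      tgt <- net$actor_order[e[, 2]]
      o <- order(src, tgt, method = "radix")
      writeLines(paste(src[o], tgt[o], sep = ","), con)
    }
  }
  invisible(path)
}

#' Read a binary network
#'
#' @param path file path.
#' @param dialect `"csv"`, `"ucinet_dl"` or `"edge_list"`. For `ucinet_dl`
#'   both the `fullmatrix` and `edgelist1` variants are accepted.
#' @param classroom,layer metadata to attach; for csv/edge_list files written
#'   by [write_network()] these default to the values stored in the file's
#'   comment header.
#' @return a [binary_network()].
#' @export
read_network <- function(path, dialect = c("csv", "ucinet_dl", "edge_list"),
                         classroom = NULL, layer = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) ts_stop(sprintf("no such file: %s", path), "io_error")
  if (dialect == "ucinet_dl") {
    dl <- parse_dl(path)
    if (dl$format == "fullmatrix") {
      adj <- dl$matrix
    } else {
      adj <- matrix(0L, dl$n, dl$n, dimnames = list(dl$labels, dl$labels))
      if (nrow(dl$edges) > 0) adj[dl$edges] <- 1L
    }
    return(binary_network(adj, dl$labels, classroom = classroom %||% "",
                          layer = layer %||% "minimum"))
  }
  lines <- readLines(path)
  meta <- parse_comment_meta(lines)
  body <- lines[!startsWith(lines, "#")]
  classroom <- classroom %||% meta$classroom %||% ""
  layer <- layer %||% meta$layer %||% "minimum"
  if (dialect == "csv") {
    df <- read.csv(text = paste(body, collapse = "\n"), row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
    adj <- as.matrix(df)
    binary_network(adj, trimws(rownames(df)), classroom = classroom, layer = layer)
  } else {
    df <- read.csv(text = paste(body, collapse = "\n"),
                   stringsAsFactors = FALSE, check.names = FALSE)
    actors <- meta$actors %||% sort(unique(c(df$source, df$target)), method = "radix")
    adj <- matrix(0L, length(actors), length(actors),
                  dimnames = list(actors, actors))
    if (nrow(df) > 0) {
      unknown <- setdiff(unique(c(df$source, df$target)), actors)
      if (length(unknown) > 0) {
        ts_stop(sprintf("edge references unknown actor(s): %s",
                        paste(unknown, collapse = ", ")), "validation_error")
      }
      adj[cbind(match(df$source, actors), match(df$target, actors))] <- 1L
    }
    binary_network(adj, actors, classroom = classroom, layer = layer)
  }
}

parse_comment_meta <- function(lines) {
  meta <- list()
  for (ln in lines[startsWith(lines, "#")]) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key == "actors") val <- trimws(strsplit(val, ",")[[1]])
    meta[[key]] <- val
  }
  meta
}

# --- UCINET DL (fullmatrix and edgelist1 variants only) ---------------------

write_dl_fullmatrix <- function(m, labels, path) {
  con <- try(suppressWarnings(file(path, "w")), silent = TRUE)
  if (inherits(con, "try-error")) {
    ts_stop(sprintf("cannot open '%s' for writing", path), "io_error")
  }
  on.exit(close(con))
  writeLines(sprintf("dl n=%d format=fullmatrix", nrow(m)), con)
  writeLines("labels:", con)
  writeLines(paste(labels, collapse = ","), con)
  writeLines("data:", con)
  for (i in seq_len(nrow(m))) writeLines(paste(m[i, ], collapse = " "), con)
  invisible(path)
}

parse_dl <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  header <- tolower(lines[1])
  if (!grepl("^dl\\b", header)) {
    ts_stop("not a UCINET DL file (missing 'dl' header)", "io_error")
  }
  n_match <- regmatches(header, regexpr("n\\s*=\\s*[0-9]+", header))
  if (length(n_match) == 0) ts_stop("DL header lacks n=<count>", "io_error")
  n <- as.integer(sub(".*=\\s*", "", n_match))
  fmt <- "fullmatrix"
  f_match <- regmatches(header, regexpr("format\\s*=\\s*[a-z0-9]+", header))
  if (length(f_match) > 0) fmt <- sub(".*=\\s*", "", f_match)
  if (!fmt %in% c("fullmatrix", "edgelist1")) {
    ts_stop(sprintf(
      "unsupported DL variant '%s' (only fullmatrix and edgelist1 are read)",
      fmt), "io_error")
  }
  body <- lines[-1]
  lab_at <- which(tolower(body) == "labels:")
  data_at <- which(tolower(body) == "data:")
  if (length(data_at) != 1) ts_stop("DL file lacks a data: section", "io_error")
  labels <- as.character(seq_len(n))
  if (length(lab_at) == 1) {
    lab_lines <- body[(lab_at + 1):(data_at - 1)]
    labels <- trimws(unlist(strsplit(lab_lines, "[,[:space:]]+")))
    labels <- labels[nzchar(labels)]
    if (length(labels) != n) {
      ts_stop(sprintf("DL labels count (%d) does not match n=%d",
                      length(labels), n), "io_error")
    }
  }
  data_lines <- body[(data_at + 1):length(body)]
  if (fmt == "fullmatrix") {
    cells <- as.integer(unlist(strsplit(paste(data_lines, collapse = " "),
                                        "[,[:space:]]+")))
    cells <- cells[!is.na(cells)]
    if (length(cells) != n * n) {
      ts_stop(sprintf("DL fullmatrix expects %d cells, found %d",
                      n * n, length(cells)), "io_error")
    }
    m <- matrix(cells, nrow = n, byrow = TRUE, dimnames = list(labels, labels))
    list(format = "fullmatrix", n = n, labels = labels, matrix = m)
  } else {
    if (length(data_lines) == 0 || all(!nzchar(data_lines))) {
      edges <- matrix(integer(0), ncol = 2)
    } else {
      toks <- strsplit(data_lines, "[,[:space:]]+")
      edges <- t(vapply(toks, function(tk) {
        tk <- tk[nzchar(tk)]
        if (length(tk) < 2) ts_stop("malformed DL edgelist1 row", "io_error")
        idx <- match(tk[1:2], labels)
        if (anyNA(idx)) {
          idx2 <- suppressWarnings(as.integer(tk[1:2]))
          if (anyNA(idx2) || any(idx2 < 1 | idx2 > n)) {
            ts_stop(sprintf("DL edge references unknown label: %s %s",
                            tk[1], tk[2]), "io_error")
          }
          idx <- idx2
        }
        idx
      }, integer(2)))
    }
    list(format = "edgelist1", n = n, labels = labels, edges = edges)
  }
}
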