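# Independent oracles for the triad machinery, kept deliberately naive.

# Canonical representative of each MAN type, written down from the standard
# pictures (arc list per type), NOT derived from package code.
canonical_triads <- function() {
  arc <- function(...) {
    a <- matrix(0L, 3, 3)
    for (e in list(...)) a[e[1], e[2]] <- 1L
    a
  }
  list(
    "003"  = arc(),
    "012"  = arc(c(1, 2)),
    "102"  = arc(c(1, 2), c(2, 1)),
    "021D" = arc(c(2, 1), c(2, 3)),
    "021U" = arc(c(1, 2), c(3, 2)),
    "021C" = arc(c(1, 2), c(2, 3)),
    "111D" = arc(c(1, 2), c(2, 1), c(3, 2)),
    "111U" = arc(c(1, 2), c(2, 1), c(2, 3)),
    "030T" = arc(c(1, 2), c(3, 2), c(1, 3)),
    "030C" = arc(c(2, 1), c(3, 2), c(1, 3)),
    "201"  = arc(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),
    "120D" = arc(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),
    "120U" = arc(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),
    "120C" = arc(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),
    "210"  = arc(c(1, 2), c(2, 3), c(3, 2), c(1, 3), c(3, 1)),
    "300"  = arc(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1)))
}

# Exhaustive isomorphism matching: try all 6 node permutations against each
# canonical representative.
oracle_classify <- function(a) {
  dimnames(a) <- NULL
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  canon <- canonical_triads()
  for (code in names(canon)) {
    for (p in perms) {
      if (identical(a[p, p], canon[[code]])) return(code)
    }
  }
  stop("no canonical triad matched (oracle is broken)")
}

# Brute-force census: classify every triple with the isomorphism oracle.
oracle_census <- function(adj) {
  n <- nrow(adj)
  counts <- setNames(integer(16), names(canonical_triads()))
  if (n < 3) return(counts)
  for (trip in utils::combn(n, 3, simplify = FALSE)) {
    code <- oracle_classify(adj[trip, trip])
    counts[code] <- counts[code] + 1L
  }
  counts
}

rand_digraph <- function(n, p = 0.3) {
  a <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(a) <- 0L
  a
}

rand_contact_values <- function(n) {
  m <- matrix(sample(1:5, n * n, replace = TRUE), n, n)
  diag(m) <- 1L
  m
}

rand_network <- function(n, p = 0.3, classroom = "t", layer = "minimum") {
  binary_network(rand_digraph(n, p), sprintf("a%02d", seq_len(n)),
                 classroom = classroom, layer = layer)
}

tie_set <- function(net) {
  e <- which(net$adjacency == 1L, arr.ind = TRUE)
  paste(net$actor_order[e[, 1]], net$actor_order[e[, 2]], sep = "->")
}

# Small roster fixture built in code.
make_roster_df <- function(ids, genders, classroom = "c1", setting = "rural",
                           age = 17) {
  n <- length(ids)
  df <- data.frame(id = ids, gender = genders, age = rep_len(age, n),
                   classroom = classroom, setting = setting,
                   stringsAsFactors = FALSE)
  for (i in 1:10) df[[paste0("audit_", i)]] <- 0L
  df
}
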