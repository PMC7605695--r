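#' Configuration for the synthetic classroom-network generator
#'
#' Defines the study conditions a generated dataset emulates: how many rural
#' and urban classrooms, their sizes, the gender mix, and the tie-formation
#' mechanisms the triadic analysis assumes — reciprocity, gender homophily and
#' triadic closure in the friendship network, and co-drinking nominations
#' concentrated among pairs of at-risk friends.
#'
#' @param n_classrooms_rural,n_classrooms_urban classroom counts (default 6/4).
#' @param class_size_range inclusive size range classrooms are drawn from when
#'   explicit sizes are not given; must lie within `[4, 60]`.
#' @param class_sizes_rural,class_sizes_urban optional explicit size vectors
#'   (used by the `survey_shaped` preset to hit its fixed totals).
#' @param p_female probability an actor is female.
#' @param base_tie_prob baseline probability of each directed friendship tie.
#' @param reciprocity_boost added to the tie probability when the reverse tie
#'   was already drawn.
#' @param homophily_boost added when the two actors share a gender.
#' @param closure_prob probability of closing each open two-path
#'   (i -> j -> k with i -> k absent) per closure sweep.
#' @param closure_sweeps number of closure passes.
#' @param intensity_cuts three strictly increasing latent thresholds in (0, 1)
#'   mapping a tie's latent strength to ordinal ratings 2--5 (non-ties rate 1).
#' @param risk_prevalence probability an actor is at risk of harmful drinking.
#' @param risk_setting_effect added to `risk_prevalence` for rural actors.
#' @param drink_tie_prob_both_risk,drink_tie_prob_otherwise probability that a
#'   friendship tie carries a co-drinking nomination when both actors are at
#'   risk, respectively otherwise.
#' @param audit_threshold AUDIT total at and above which an actor counts as at
#'   risk; generated item scores are made consistent with the drawn risk status.
#' @param seed integer seed; the full study is a deterministic function of it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_classrooms_rural = 6,
                             n_classrooms_urban = 4,
                             class_size_range = c(18, 35),
                             class_sizes_rural = NULL,
                             class_sizes_urban = NULL,
                             p_female = 0.54,
                             base_tie_prob = 0.15,
                             reciprocity_boost = 0.35,
                             homophily_boost = 0.10,
                             closure_prob = 0.15,
                             closure_sweeps = 2,
                             intensity_cuts = c(0.5, 0.8, 0.95),
                             risk_prevalence = 0.41,
                             risk_setting_effect = 0.05,
                             drink_tie_prob_both_risk = 0.60,
                             drink_tie_prob_otherwise = 0.08,
                             audit_threshold = 8,
                             seed = 1) {
  cfg <- list(n_classrooms_rural = as.integer(n_classrooms_rural),
              n_classrooms_urban = as.integer(n_classrooms_urban),
              class_size_range = as.integer(class_size_range),
              class_sizes_rural = if (is.null(class_sizes_rural)) NULL
                                  else as.integer(class_sizes_rural),
              class_sizes_urban = if (is.null(class_sizes_urban)) NULL
                                  else as.integer(class_sizes_urban),
              p_female = p_female,
              base_tie_prob = base_tie_prob,
              reciprocity_boost = reciprocity_boost,
              homophily_boost = homophily_boost,
              closure_prob = closure_prob,
              closure_sweeps = as.integer(closure_sweeps),
              intensity_cuts = as.numeric(intensity_cuts),
              risk_prevalence = risk_prevalence,
              risk_setting_effect = risk_setting_effect,
              drink_tie_prob_both_risk = drink_tie_prob_both_risk,
              drink_tie_prob_otherwise = drink_tie_prob_otherwise,
              audit_threshold = as.integer(audit_threshold),
              seed = as.integer(seed))
  probs <- unlist(cfg[c("p_female", "base_tie_prob", "reciprocity_boost",
                        "homophily_boost", "closure_prob", "risk_prevalence",
                        "drink_tie_prob_both_risk", "drink_tie_prob_otherwise")])
  if (any(probs < 0 | probs > 1)) {
    ts_stop("all generator probabilities must lie in [0, 1]", "validation_error")
  }
  if (length(cfg$intensity_cuts) != 3 || any(diff(cfg$intensity_cuts) <= 0) ||
      any(cfg$intensity_cuts <= 0 | cfg$intensity_cuts >= 1)) {
    ts_stop("intensity_cuts must be three strictly increasing values in (0, 1)",
            "validation_error")
  }
  if (length(cfg$class_size_range) != 2 || cfg$class_size_range[1] < 4 ||
      cfg$class_size_range[2] > 60 || diff(cfg$class_size_range) < 0) {
    ts_stop("class_size_range must be an increasing interval within [4, 60]",
            "validation_error")
  }
  for (side in c("rural", "urban")) {
    sizes <- cfg[[paste0("class_sizes_", side)]]
    if (!is.null(sizes)) {
      if (length(sizes) != cfg[[paste0("n_classrooms_", side)]]) {
        ts_stop(sprintf("class_sizes_%s length must equal n_classrooms_%s",
                        side, side), "validation_error")
      }
      if (any(sizes < 4 | sizes > 60)) {
        ts_stop("explicit class sizes must lie in [4, 60]", "validation_error")
      }
    }
  }
  structure(cfg, class = "generator_config")
}

#' Named generator presets
#'
#' Presets are shipped as YAML config files under
#' `system.file("extdata/presets", package = "triadscope")`:
#' * `survey_shaped` — 6 rural classrooms totalling 100 students and 4 urban
#'   totalling 95 (195 actors, p_female 0.54, rural risk prevalence above
#'   urban): the shape of the original survey, with no claim of matching its
#'   unknown generating parameters.
#' * `null_model` — no reciprocity, homophily or closure effects and
#'   risk-independent nominations; identical rural and urban conditions.
#' * `high_closure` — strong triadic closure (closure_prob 0.6, 3 sweeps).
#'
#' @param name preset name.
#' @param seed optional seed overriding the preset's.
#' @return a [generator_config()].
#' @export
generator_preset <- function(name = c("survey_shaped", "null_model",
                                      "high_closure"),
                             seed = NULL) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "triadscope")
  if (path == "") ts_stop(sprintf("preset file for '%s' not found", name),
                          "io_error")
  args <- yaml::read_yaml(path)
  if (!is.null(seed)) args$seed <- seed
  do.call(generator_config, args)
}

#' Generate a synthetic sociometric study
#'
#' Produces, deterministically from `cfg$seed`, a full study: a roster with
#' AUDIT item responses, one ordinal contact matrix per classroom and one
#' co-drinking nomination network per classroom. Per classroom the generation
#' order is: genders; directed base ties (probability `base_tie_prob`, plus
#' `homophily_boost` for same-gender pairs, plus `reciprocity_boost` when the
#' reverse tie is already present); `closure_sweeps` passes closing open
#' two-paths with `closure_prob`; ordinal intensities (non-ties rate 1, ties
#' rate 2--5 via latent strengths against `intensity_cuts`); risk status
#' (Bernoulli, with the rural shift); nominations on friendship ties with
#' probability depending on the pair's joint risk status; and AUDIT items
#' whose total falls on the correct side of `audit_threshold`.
#'
#' Each classroom runs on its own sub-seed (drawn once up front), so a
#' classroom's data do not depend on how many classrooms precede it.
#'
#' @param cfg a [generator_config()].
#' @return object of class `synthetic_study`: list with `roster`,
#'   `contact_matrices`, `nomination_networks`, `true_risk` (the drawn risk
#'   status per actor) and `true_params` (a copy of `cfg`).
#' @export
generate_study <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n_class <- cfg$n_classrooms_rural + cfg$n_classrooms_urban
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_class)
  settings <- rep(c("rural", "urban"),
                  c(cfg$n_classrooms_rural, cfg$n_classrooms_urban))
  labels <- c(sprintf("rural_%d", seq_len(cfg$n_classrooms_rural)),
              sprintf("urban_%d", seq_len(cfg$n_classrooms_urban)))
  sizes <- integer(n_class)
  for (i in seq_len(n_class)) {
    side <- settings[i]
    fixed <- cfg[[paste0("class_sizes_", side)]]
    if (!is.null(fixed)) {
      sizes[i] <- fixed[sum(settings[seq_len(i)] == side)]
    } else {
      sizes[i] <- sample1(seq(cfg$class_size_range[1], cfg$class_size_range[2]))
    }
  }
  rooms <- vector("list", n_class)
  for (i in seq_len(n_class)) {
    rooms[[i]] <- generate_classroom(sizes[i], settings[i], labels[i], cfg,
                                     sub_seeds[i])
  }
  ros <- roster(do.call(rbind, lapply(rooms, `[[`, "roster")))
  structure(list(
    roster = ros,
    contact_matrices = setNames(lapply(rooms, `[[`, "contact"), labels),
    nomination_networks = setNames(lapply(rooms, `[[`, "nominations"), labels),
    true_risk = do.call(rbind, lapply(rooms, `[[`, "true_risk")),
    true_params = cfg), class = "synthetic_study")
}

generate_classroom <- function(n, setting, label, cfg, seed) {
  set.seed(seed)
  ids <- sprintf("%s_s%02d", label, seq_len(n))
  gender <- ifelse(runif(n) < cfg$p_female, "female", "male")
  # mean ~17 years, as in a final-cycle secondary classroom
  age <- sample(16:19, n, replace = TRUE, prob = c(0.30, 0.45, 0.20, 0.05))

  adj <- matrix(0L, n, n)
  same <- outer(gender, gender, `==`)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p1 <- clamp01(cfg$base_tie_prob + cfg$homophily_boost * same[i, j])
      adj[i, j] <- as.integer(runif(1) < p1)
      p2 <- clamp01(p1 + cfg$reciprocity_boost * adj[i, j])
      adj[j, i] <- as.integer(runif(1) < p2)
    }
  }
  for (sweep in seq_len(cfg$closure_sweeps)) {
    if (cfg$closure_prob <= 0) break
    two_paths <- (adj %*% adj) > 0
    open <- which(two_paths & adj == 0L & row(adj) != col(adj))
    if (length(open) == 0) next
    close_these <- open[runif(length(open)) < cfg$closure_prob]
    adj[close_these] <- 1L
  }

  values <- matrix(1L, n, n)
  ties <- which(adj == 1L)
  if (length(ties) > 0) {
    latent <- runif(length(ties))
    values[ties] <- 2L + findInterval(latent, cfg$intensity_cuts)
  }
  diag(values) <- 1L

  prev <- clamp01(cfg$risk_prevalence +
                    cfg$risk_setting_effect * (setting == "rural"))
  at_risk <- runif(n) < prev

  nom <- matrix(0L, n, n)
  if (length(ties) > 0) {
    both <- outer(at_risk, at_risk, `&`)
    p_nom <- ifelse(both[ties], cfg$drink_tie_prob_both_risk,
                    cfg$drink_tie_prob_otherwise)
    nom[ties] <- as.integer(runif(length(ties)) < p_nom)
  }

  audit <- t(vapply(at_risk, function(risk) {
    generate_audit_items(risk, cfg$audit_threshold)
  }, integer(10)))
  colnames(audit) <- paste0("audit_", 1:10)

  ros <- data.frame(id = ids, gender = gender, age = age, classroom = label,
                    setting = setting, stringsAsFactors = FALSE)
  ros <- cbind(ros, as.data.frame(audit))
  list(
    roster = ros,
    contact = contact_matrix(values, ids, classroom = label),
    nominations = binary_network(nom, ids, classroom = label,
                                 layer = "consumption"),
    true_risk = data.frame(id = ids, classroom = label, setting = setting,
                           at_risk = at_risk, stringsAsFactors = FALSE))
}

# Draw a total on the right side of the threshold, then partition it across
# the 10 items respecting each item's range (items 9-10 take even values
# only), so classification from the items always reproduces the drawn risk.
generate_audit_items <- function(at_risk, threshold) {
  total <- if (at_risk) {
    min(40L, threshold + sample1(0:12, prob = 0.8^(0:12)))
  } else {
    sample1(0:(threshold - 1), prob = 0.75^(0:(threshold - 1)))
  }
  lo_e <- max(0L, total - 32L)
  lo_e <- lo_e + lo_e %% 2L
  hi_e <- min(8L, total)
  hi_e <- hi_e - hi_e %% 2L
  r910 <- sample1(seq(lo_e, hi_e, by = 2))
  e9 <- sample1(seq(max(0L, r910 - 4L), min(4L, r910), by = 2))
  e10 <- r910 - e9
  rem <- total - r910
  items <- integer(8)
  for (t in 1:8) {
    cap_rest <- (8L - t) * 4L
    lo <- max(0L, rem - cap_rest)
    hi <- min(4L, rem)
    items[t] <- sample1(seq(lo, hi))
    rem <- rem - items[t]
  }
  as.integer(c(items, e9, e10))
}

#' Summaries of a synthetic study computed with the pipeline's own operations
#'
#' Dog-foods the analysis operations on generated data: per-classroom
#' same-gender tie fraction and reciprocity rate of the minimum-intensity
#' layer, its transitive share (via [triad_census()]), and at-risk prevalence
#' per setting (via [score_audit_all()]).
#'
#' @param study a [generate_study()] result.
#' @param scheme a [transitivity_scheme()].
#' @return list with `classrooms` (data frame) and `risk_by_setting`
#'   (data frame from [risk_proportions()]).
#' @export
summarize_truth <- function(study, scheme = transitivity_scheme()) {
  thr <- study$true_params$audit_threshold
  rows <- lapply(names(study$contact_matrices), function(cl) {
    mat <- study$contact_matrices[[cl]]
    net <- dichotomize(mat, "minimum")
    a <- net$adjacency
    ids <- net$actor_order
    g <- study$roster$gender[match(ids, study$roster$id)]
    same <- outer(g, g, `==`)
    ties <- sum(a)
    cen <- triad_census(net, scheme)
    data.frame(
      classroom = cl,
      setting = study$roster$setting[match(ids[1], study$roster$id)],
      n_actors = length(ids),
      density = ties / (length(ids) * (length(ids) - 1)),
      same_gender_tie_fraction = if (ties > 0) sum(a * same) / ties else NA_real_,
      reciprocity_rate = if (ties > 0) sum(a * t(a)) / ties else NA_real_,
      transitive_share = cen$transitive_share,
      stringsAsFactors = FALSE)
  })
  scored <- score_audit_all(study$roster, threshold = thr)
  list(classrooms = do.call(rbind, rows),
       risk_by_setting = risk_proportions(scored, by = "setting"))
}

#' Write a synthetic study to disk in the package's file formats
#'
#' Writes `roster.csv`, one contact-matrix CSV and DL file per classroom under
#' `matrices/`, and one nomination edge list per classroom under
#' `nominations/` — the exact formats [read_roster()],
#' [read_contact_matrix()] and [read_network()] read back.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "nominations"), showWarnings = FALSE)
  write_roster(study$roster, file.path(dir, "roster.csv"))
  for (cl in names(study$contact_matrices)) {
    write_contact_matrix(study$contact_matrices[[cl]],
                         file.path(dir, "matrices", paste0(cl, ".csv")), "csv")
    write_contact_matrix(study$contact_matrices[[cl]],
                         file.path(dir, "matrices", paste0(cl, ".dl")),
                         "ucinet_dl")
    write_network(study$nomination_networks[[cl]],
                  file.path(dir, "nominations", paste0(cl, ".csv")),
                  "edge_list")
  }
  invisible(dir)
}
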