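# Experiment design generation: stimulus dimensions, category-response
# mappings, counterbalanced versions, and learning/memory trial lists.

#' Define a binary stimulus dimension
#'
#' Each experiment crosses two dimensions with two levels each (e.g. border
#' color red/blue with shape square/circle, or face age young/old with gender
#' female/male), yielding four stimulus categories.
#'
#' @param name Dimension label.
#' @param levels Character vector of exactly two distinct level labels.
#' @return A list with elements `name` and `levels`, class `stim_dimension`.
#' @export
stim_dimension <- function(name, levels) {
  if (length(levels) != 2L || anyDuplicated(levels))
    .stopf("a stimulus dimension needs exactly 2 distinct levels, got: %s",
           paste(levels, collapse = ", "))
  structure(list(name = as.character(name), levels = as.character(levels)),
            class = "stim_dimension")
}

#' Stimulus dimensions used by each experiment
#'
#' Experiment 1 uses superficial border features (color, shape) around
#' task-irrelevant object images; Experiments 2-4 use inherent face features
#' (age, gender).
#'
#' @param experiment Integer 1-4.
#' @return List of two `stim_dimension` objects.
#' @export
experiment_dimensions <- function(experiment) {
  experiment <- .check_experiment(experiment)
  if (experiment == 1L) {
    list(stim_dimension("color", c("red", "blue")),
         stim_dimension("shape", c("square", "circle")))
  } else {
    list(stim_dimension("age", c("young", "old")),
         stim_dimension("gender", c("female", "male")))
  }
}

.check_experiment <- function(experiment) {
  if (!is.numeric(experiment) || length(experiment) != 1L ||
      !(experiment %in% 1:4))
    .stopf("experiment must be one of 1, 2, 3, 4")
  as.integer(experiment)
}

#' Full 2 x 2 category table for a dimension pair
#'
#' @param dims List of two `stim_dimension` objects.
#' @return data.frame with columns `category`, `dim1`, `dim2` (level labels),
#'   one row per category in canonical order (dim1 level varying slowest).
#' @export
category_table <- function(dims) {
  stopifnot(length(dims) == 2L)
  g <- expand.grid(dim2 = dims[[2]]$levels, dim1 = dims[[1]]$levels,
                   stringsAsFactors = FALSE)[, c("dim1", "dim2")]
  g$category <- paste(g$dim1, g$dim2, sep = ".")
  g[, c("category", "dim1", "dim2")]
}

#' Build a category-to-key response mapping
#'
#' Keys are numbered 1-4 left-to-right (v, b, n, m under the right hand). A
#' clustered mapping nests the sub-dimension within each level of the biased
#' (supraordinate) dimension at adjacent key pairs {1,2} and {3,4}; the
#' non-clustered mapping splits one supraordinate level across keys {1,4} and
#' the other across {3,2}, breaking adjacency while keeping a bijection.
#'
#' @param clustered Logical flag.
#' @param biased_dimension Name of the dimension along which keys are grouped
#'   (for non-clustered mappings this is the counterbalanced layout dimension).
#' @param dims List of two `stim_dimension` objects.
#' @return Object of class `response_mapping`: list with `assignment` (named
#'   integer vector, category label -> key), `clustered`, `biased_dimension`,
#'   `dims`.
#' @examples
#' dims <- experiment_dimensions(1)
#' response_mapping(TRUE, "color", dims)$assignment
#' @export
response_mapping <- function(clustered, biased_dimension, dims) {
  stopifnot(.is_flag(clustered))
  names2 <- vapply(dims, `[[`, "", "name")
  bi <- match(biased_dimension, names2)
  if (is.na(bi))
    .stopf("unknown biased dimension '%s' (have: %s)", biased_dimension,
           paste(names2, collapse = ", "))
  supra <- dims[[bi]]
  sub <- dims[[3L - bi]]
  # categories ordered (supra level, sub level)
  ord <- expand.grid(sub = sub$levels, supra = supra$levels,
                     stringsAsFactors = FALSE)
  labs <- if (bi == 1L) paste(ord$supra, ord$sub, sep = ".")
          else paste(ord$sub, ord$supra, sep = ".")
  keys <- if (clustered) c(1L, 2L, 3L, 4L) else c(1L, 4L, 3L, 2L)
  assignment <- stats::setNames(keys, labs)
  # report in canonical category order
  canon <- category_table(dims)$category
  assignment <- assignment[canon]
  m <- structure(list(assignment = assignment, clustered = clustered,
                      biased_dimension = supra$name, dims = dims),
                 class = "response_mapping")
  .validate_mapping(m)
  m
}

.validate_mapping <- function(m) {
  a <- m$assignment
  if (!setequal(a, 1:4) || length(a) != 4L)
    .stopf("response mapping must be a bijection onto keys 1-4")
  if (m$clustered) {
    for (lev in .dim_by_name(m, m$biased_dimension)$levels) {
      keys <- sort(unname(a[.categories_with_level(m, m$biased_dimension, lev)]))
      if (diff(keys) != 1L || !(keys[1] %in% c(1L, 3L)))
        .stopf("clustered mapping must place same-supraordinate categories at adjacent key pairs {1,2}/{3,4}")
    }
  }
  invisible(m)
}

.dim_by_name <- function(m, name) {
  nm <- vapply(m$dims, `[[`, "", "name")
  m$dims[[match(name, nm)]]
}

.categories_with_level <- function(m, dim_name, level) {
  tab <- category_table(m$dims)
  nm <- vapply(m$dims, `[[`, "", "name")
  col <- c("dim1", "dim2")[match(dim_name, nm)]
  tab$category[tab[[col]] == level]
}

#' @export
print.response_mapping <- function(x, ...) {
  cat(sprintf("Response mapping (%s, layout dimension: %s)\n",
              if (x$clustered) "clustered" else "non-clustered",
              x$biased_dimension))
  keys <- c("v", "b", "n", "m")
  for (i in seq_along(x$assignment))
    cat(sprintf("  %-20s -> key %d (%s)\n", names(x$assignment)[i],
                x$assignment[i], keys[x$assignment[i]]))
  invisible(x)
}

#' Mean keyboard distance between same-feature response keys
#'
#' For each of the four category pairs that share one feature level (two
#' levels on each of the two dimensions), takes the absolute difference of
#' their key positions (keys at consecutive integer positions) and averages.
#' The clustered layout gives distances (1, 1, 2, 2), mean 1.5.
#'
#' @param mapping A `response_mapping`.
#' @return List with `distances` (named numeric, one per shared level) and
#'   `mean` (their average in keyboard units).
#' @export
mean_key_distance <- function(mapping) {
  stopifnot(inherits(mapping, "response_mapping"))
  a <- mapping$assignment
  d <- c()
  for (dm in mapping$dims) {
    for (lev in dm$levels) {
      cats <- .categories_with_level(mapping, dm$name, lev)
      d[paste(dm$name, lev, sep = ".")] <- abs(diff(unname(a[cats])))
    }
  }
  list(distances = d, mean = mean(d))
}

#' Number of new memory-phase images
#'
#' Roughly one third of the learning trials, rounded up to the smallest
#' multiple of the category count so that new items stay balanced across
#' categories (128 old -> 44 new; 120 old -> 40 new).
#'
#' @param n_old Number of learning-phase (old) images.
#' @param n_categories Number of stimulus categories (default 4).
#' @return Integer count of new images.
#' @export
n_new_images <- function(n_old, n_categories = 4L) {
  stopifnot(n_old >= 1, n_categories >= 1)
  as.integer(ceiling(n_old / 3 / n_categories) * n_categories)
}

#' Construct an experiment design
#'
#' Bundles the trial counts, dimensions, response mapping and experiment
#' specific toggles: Experiment 1 has 128 learning trials, source-memory
#' probes and 8 counterbalanced versions; Experiments 2-4 have 120 learning
#' trials and 4 versions; Experiment 3 flips the response mappings halfway
#' through the learning phase; Experiment 4 instructs the mappings instead of
#' requiring trial-and-error learning.
#'
#' @param experiment Integer 1-4.
#' @param clustered Logical: motor-clustered key mapping?
#' @param biased_dimension Dimension name for the key layout (defaults to the
#'   first dimension).
#' @param version_id Counterbalance version index.
#' @param question_order For Experiment 1 only: `"dim1_first"` or
#'   `"dim2_first"`, the order of the two source-memory questions.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(experiment, clustered = TRUE,
                              biased_dimension = NULL, version_id = 1L,
                              question_order = c("dim1_first", "dim2_first")) {
  experiment <- .check_experiment(experiment)
  dims <- experiment_dimensions(experiment)
  if (is.null(biased_dimension)) biased_dimension <- dims[[1]]$name
  question_order <- match.arg(question_order)
  mapping <- response_mapping(clustered, biased_dimension, dims)
  n_lp <- if (experiment == 1L) 128L else 120L
  d <- structure(list(
    experiment_id = experiment,
    n_learning_trials = n_lp,
    n_memory_new = n_new_images(n_lp),
    dims = dims,
    mapping = mapping,
    clustered = clustered,
    biased_dimension = biased_dimension,
    rule_switch_at = if (experiment == 3L) n_lp %/% 2L else NULL,
    post_switch_mapping = NULL,
    instructed = experiment == 4L,
    source_memory = experiment == 1L,
    question_order = if (experiment == 1L) question_order else NULL,
    version_id = as.integer(version_id)
  ), class = "experiment_design")
  if (experiment == 3L) d <- apply_rule_switch(d)
  d
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment %d design, version %d (%s, layout: %s)\n",
              x$experiment_id, x$version_id,
              if (x$clustered) "clustered" else "non-clustered",
              x$biased_dimension))
  cat(sprintf("  learning trials: %d; memory trials: %d (%d old / %d new)\n",
              x$n_learning_trials, x$n_learning_trials + x$n_memory_new,
              x$n_learning_trials, x$n_memory_new))
  if (!is.null(x$rule_switch_at))
    cat(sprintf("  implicit rule switch after trial %d\n", x$rule_switch_at))
  if (x$source_memory) cat("  source-memory probes enabled\n")
  if (x$instructed) cat("  mappings instructed (no trial-and-error)\n")
  invisible(x)
}

#' Apply the Experiment-3 implicit rule switch to a design
#'
#' Halfway through the learning phase the response mappings change. For
#' clustered learners the clustering flips to the other stimulus dimension;
#' for non-clustered learners the two off-diagonal categories swap keys. In
#' both cases exactly two categories keep their key throughout ("positive
#' transfer") and two change ("negative transfer").
#'
#' @param design An `experiment_design` with `experiment_id == 3`.
#' @return The design with `post_switch_mapping` populated.
#' @export
apply_rule_switch <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$experiment_id != 3L)
    .stopf("the implicit rule switch applies to Experiment 3 designs only")
  pre <- design$mapping
  if (pre$clustered) {
    other <- setdiff(vapply(pre$dims, `[[`, "", "name"), pre$biased_dimension)
    post <- response_mapping(TRUE, other, pre$dims)
  } else {
    # swap keys of the two off-diagonal categories (supra level 1 + sub level
    # 2, supra level 2 + sub level 1); preserves non-adjacency
    nm <- vapply(pre$dims, `[[`, "", "name")
    bi <- match(pre$biased_dimension, nm)
    supra <- pre$dims[[bi]]; sub <- pre$dims[[3L - bi]]
    lab <- function(s, u) if (bi == 1L) paste(s, u, sep = ".") else paste(u, s, sep = ".")
    c1 <- lab(supra$levels[1], sub$levels[2])
    c2 <- lab(supra$levels[2], sub$levels[1])
    a <- pre$assignment
    tmp <- a[c1]; a[c1] <- a[c2]; a[c2] <- tmp
    post <- structure(list(assignment = a, clustered = FALSE,
                           biased_dimension = pre$biased_dimension,
                           dims = pre$dims),
                      class = "response_mapping")
    .validate_mapping(post)
  }
  kept <- sum(post$assignment[names(pre$assignment)] == pre$assignment)
  if (kept != 2L)
    .stopf("degenerate rule switch: %d categories kept their key (expected 2)", kept)
  design$post_switch_mapping <- post
  design
}

#' Positive/negative transfer classification of categories (Experiment 3)
#'
#' @param design An Experiment-3 `experiment_design` (rule switch applied).
#' @return Named character vector over categories: `"positive"` where the key
#'   is unchanged across the rule switch, `"negative"` where it changed.
#' @export
transfer_classes <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(design$post_switch_mapping))
    .stopf("design has no post-switch mapping; not an Experiment 3 design?")
  pre <- design$mapping$assignment
  post <- design$post_switch_mapping$assignment[names(pre)]
  stats::setNames(ifelse(post == pre, "positive", "negative"), names(pre))
}

#' Enumerate the counterbalanced task versions of an experiment
#'
#' Experiment 1 crosses learner group (clustered/non-clustered), layout
#' dimension, and source-question order, giving 8 versions; Experiments 2-4
#' cross group and layout dimension, giving 4.
#'
#' @param experiment Integer 1-4.
#' @return List of `experiment_design` objects with distinct `version_id`s.
#' @export
enumerate_versions <- function(experiment) {
  experiment <- .check_experiment(experiment)
  dims <- experiment_dimensions(experiment)
  dn <- vapply(dims, `[[`, "", "name")
  grid <- if (experiment == 1L) {
    expand.grid(clustered = c(TRUE, FALSE), biased = dn,
                qorder = c("dim1_first", "dim2_first"),
                stringsAsFactors = FALSE)
  } else {
    expand.grid(clustered = c(TRUE, FALSE), biased = dn,
                qorder = "dim1_first", stringsAsFactors = FALSE)
  }
  lapply(seq_len(nrow(grid)), function(i) {
    experiment_design(experiment, clustered = grid$clustered[i],
                      biased_dimension = grid$biased[i], version_id = i,
                      question_order = grid$qorder[i])
  })
}

#' Generate the learning-phase trial list
#'
#' Each of the four categories appears with equal frequency in a seeded random
#' order; images are trial-unique.
#'
#' @param design An `experiment_design`.
#' @param seed Integer seed.
#' @return data.frame with columns `trial`, `category`, `dim1`, `dim2`,
#'   `image_id`, `correct_key` (post-switch keys after the Experiment-3 rule
#'   switch).
#' @export
generate_learning_trials <- function(design, seed) {
  stopifnot(inherits(design, "experiment_design"))
  n <- design$n_learning_trials
  if (n %% 4L != 0L)
    .stopf("n_learning_trials (%d) must be divisible by the 4 categories", n)
  tab <- category_table(design$dims)
  set.seed(seed)
  cats <- sample(rep(seq_len(4L), each = n %/% 4L))
  out <- data.frame(
    trial = seq_len(n),
    category = tab$category[cats],
    dim1 = tab$dim1[cats],
    dim2 = tab$dim2[cats],
    image_id = seq_len(n),
    stringsAsFactors = FALSE
  )
  key <- unname(design$mapping$assignment[out$category])
  if (!is.null(design$rule_switch_at)) {
    post <- out$trial > design$rule_switch_at
    key[post] <- unname(design$post_switch_mapping$assignment[out$category[post]])
  }
  out$correct_key <- key
  out
}

#' Generate the memory-phase trial list
#'
#' Every learning image reappears once (status `old`) together with new images
#' balanced across categories (`n_new_images()` of them), all in seeded random
#' order. Old items carry their learning-phase trial of origin and bin.
#'
#' @param design An `experiment_design`.
#' @param learning Learning trial list from [generate_learning_trials()].
#' @param seed Integer seed.
#' @return data.frame with columns `position`, `image_id`, `status`,
#'   `category`, `dim1`, `dim2`, `lp_trial`, `lp_bin`.
#' @export
generate_memory_trials <- function(design, learning, seed) {
  stopifnot(inherits(design, "experiment_design"), nrow(learning) >= 1)
  n_old <- nrow(learning)
  n_new <- n_new_images(n_old)
  tab <- category_table(design$dims)
  bins <- assign_bins(design$n_learning_trials)
  old <- data.frame(
    image_id = learning$image_id, status = "old",
    category = learning$category, dim1 = learning$dim1, dim2 = learning$dim2,
    lp_trial = learning$trial,
    lp_bin = lp_bin_of_trial(learning$trial, design$n_learning_trials),
    stringsAsFactors = FALSE
  )
  newcat <- rep(seq_len(4L), each = n_new %/% 4L)
  new <- data.frame(
    image_id = n_old + seq_len(n_new), status = "new",
    category = tab$category[newcat], dim1 = tab$dim1[newcat],
    dim2 = tab$dim2[newcat], lp_trial = NA_integer_, lp_bin = NA_integer_,
    stringsAsFactors = FALSE
  )
  out <- rbind(old, new)
  set.seed(seed)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out <- cbind(position = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  stopifnot(sum(bins) == design$n_learning_trials)
  out
}

#' Synthetic face-stimulus catalog
#'
#' Builds the 208-image face set as a synthetic table: 52 faces per age x
#' gender category, each with 43 white/Caucasian faces plus 9 faces from other
#' racial categories in the documented per-category breakdown; all neutral in
#' emotion. No image files are involved; ids are synthetic.
#'
#' @return data.frame with columns `face_id`, `age`, `gender`, `race`,
#'   `emotion` (208 rows).
#' @export
face_catalog <- function() {
  other <- list(
    c("south_asian" = 4, "hispanic" = 3, "east_asian" = 1, "black" = 1),   # young female
    c("east_asian" = 4, "south_asian" = 3, "middle_eastern" = 2),          # old female
    c("hispanic" = 5, "south_asian" = 4),                                  # young male
    c("middle_eastern" = 5, "south_asian" = 2, "east_asian" = 2)           # old male
  )
  cats <- expand.grid(gender = c("female", "male"), age = c("young", "old"),
                      stringsAsFactors = FALSE)[c(1, 3, 2, 4), ]
  rows <- list()
  for (i in seq_len(4L)) {
    races <- c(rep("white", 43L), rep(names(other[[i]]), other[[i]]))
    rows[[i]] <- data.frame(age = cats$age[i], gender = cats$gender[i],
                            race = races, emotion = "neutral",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- cbind(face_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write a design and its trial lists to disk
#'
#' Serializes the phase trial lists to a single CSV (columns: phase, trial
#' index, category levels, image id, correct key, old/new status) plus a JSON
#' sidecar with the mapping and version metadata.
#'
#' @param design An `experiment_design`.
#' @param dir Output directory (created if needed).
#' @param seed Seed used for the trial lists.
#' @return Invisibly, the paths written.
#' @export
write_design <- function(design, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lp <- generate_learning_trials(design, seed)
  mp <- generate_memory_trials(design, lp, derive_seed(seed, "memory"))
  tab <- rbind(
    data.frame(phase = "learning", trial_index = lp$trial, dim1_level = lp$dim1,
               dim2_level = lp$dim2, image_id = lp$image_id,
               correct_key = lp$correct_key, status = "old",
               stringsAsFactors = FALSE),
    data.frame(phase = "memory", trial_index = mp$position,
               dim1_level = mp$dim1, dim2_level = mp$dim2,
               image_id = mp$image_id, correct_key = NA_integer_,
               status = mp$status, stringsAsFactors = FALSE)
  )
  csv <- file.path(dir, sprintf("design_exp%d_v%d.csv", design$experiment_id,
                                design$version_id))
  meta <- file.path(dir, sprintf("design_exp%d_v%d.json", design$experiment_id,
                                 design$version_id))
  utils::write.csv(tab, csv, row.names = FALSE)
  jsonlite::write_json(list(
    experiment = design$experiment_id, version = design$version_id,
    clustered = design$clustered, biased_dimension = design$biased_dimension,
    assignment = as.list(design$mapping$assignment),
    post_switch_assignment = if (!is.null(design$post_switch_mapping))
      as.list(design$post_switch_mapping$assignment) else NULL,
    rule_switch_at = design$rule_switch_at,
    source_memory = design$source_memory, instructed = design$instructed,
    seed = seed
  ), meta, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv, meta))
}
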