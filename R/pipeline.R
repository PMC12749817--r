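# End-to-end study orchestration: phantom -> render -> segment -> partition
# -> quantify -> compare, over a factorial study configuration
# (cell line x stroma x day), deterministic given (config, seed).

#' Assemble a study configuration
#'
#' @param conditions list of condition descriptors; each a list with
#'   `cell_line`, `stroma`, `day`, `n_replicates` (>= 2) and `spec` (a
#'   [phantom_spec()] stating that condition's programmed invasion).
#' @param training_spec [phantom_spec()] used to generate labeled training
#'   slices for the classifier (defaults to the first condition's spec).
#' @param n_training_slices number of labeled X-Z slices for training.
#' @param n_training_phantoms training slices are drawn from this many
#'   independent phantoms.
#' @param segmentation `"classifier"` (default), `"otsu"`, or `"truth"`
#'   (ground-truth labels; isolates the geometric/statistical stages).
#' @param classifier_type passed to [train_classifier()].
#' @param metrics metric columns to compare.
#' @param min_object_um3 cleanup threshold for the cancer mask.
#' @param require_full_design error if any cell of the full factorial
#'   (cell_line x stroma x day) is absent.
#' @return a `study_config` object.
#' @export
study_config <- function(conditions,
                         training_spec = NULL,
                         n_training_slices = 20,
                         n_training_phantoms = 2,
                         segmentation = c("classifier", "otsu", "truth"),
                         classifier_type = "qda",
                         metrics = c("v_iccr_um3", "hif_area_um2",
                                     "mass_invasion_index",
                                     "depth_of_invasion_um"),
                         min_object_um3 = 27,
                         require_full_design = TRUE) {
  segmentation <- match.arg(segmentation)
  if (!length(conditions)) stop_("no conditions given")
  for (i in seq_along(conditions)) {
    cd <- conditions[[i]]
    need <- setdiff(c("cell_line", "stroma", "day", "n_replicates", "spec"),
                    names(cd))
    if (length(need))
      stop_("condition %d is missing fields: %s", i,
            paste(need, collapse = ", "))
    if (cd$n_replicates < 2L)
      stop_("condition %d: n_replicates must be >= 2 for testing", i)
  }
  if (require_full_design) {
    have <- vapply(conditions, function(cd)
      paste(cd$cell_line, cd$stroma, cd$day, sep = "|"), "")
    lv <- function(f)
      unique(vapply(conditions, function(cd) as.character(cd[[f]]), ""))
    grid <- expand.grid(cell_line = lv("cell_line"), stroma = lv("stroma"),
                        day = lv("day"), stringsAsFactors = FALSE)
    want <- paste(grid$cell_line, grid$stroma, grid$day, sep = "|")
    absent <- setdiff(want, have)
    if (length(absent))
      stop_("incomplete factorial design; missing condition(s): %s",
            paste(gsub("\\|", " / ", absent), collapse = "; "))
  }
  structure(list(conditions = conditions,
                 training_spec = training_spec %||% conditions[[1]]$spec,
                 n_training_slices = n_training_slices,
                 n_training_phantoms = n_training_phantoms,
                 segmentation = segmentation,
                 classifier_type = classifier_type,
                 metrics = metrics,
                 min_object_um3 = min_object_um3),
            class = "study_config")
}

#' Labeled X-Z training slices from a phantom
#'
#' Renders the phantom and extracts `n` evenly spaced cross-sectional
#' (X-Z) intensity/label slice pairs, the phantom counterpart of labeling
#' cross-sectional images against stained sections.
#'
#' @param truth a `programmed_truth`.
#' @param volume the rendered [oct_volume()] of the same phantom.
#' @param n number of slices.
#' @return list of `list(image, labels)` pairs.
#' @export
training_slices_from_phantom <- function(truth, volume, n) {
  ny <- dim(volume$data)[2]
  ys <- unique(round(seq(1, ny, length.out = n)))
  lapply(ys, function(y) list(image = extract_slice(volume, "XZ", y),
                              labels = extract_slice(truth$label_volume,
                                                     "XZ", y)))
}

#' Train the study classifier from phantom cross-sections
#'
#' @param config a [study_config()].
#' @param seed RNG seed (phantom generation + training subsample).
#' @return a `voxel_classifier`.
#' @export
train_study_classifier <- function(config, seed = 1L) {
  spec <- config$training_spec
  per <- ceiling(config$n_training_slices / config$n_training_phantoms)
  slices <- list()
  for (i in seq_len(config$n_training_phantoms)) {
    s <- seed + 7919L * i
    truth <- build_label_volume(spec, seed = s)
    vol <- render_oct(truth, spec, seed = s + 1L)
    slices <- c(slices, training_slices_from_phantom(truth, vol, per))
  }
  train_classifier(slices[seq_len(min(length(slices),
                                      config$n_training_slices))],
                   type = config$classifier_type,
                   voxel_um = spec$voxel_um, seed = seed)
}

# cancer mask -> cleaned mask -> baseline -> partition -> metrics row
quantify_cancer_mask <- function(cancer_mask, voxel_um, min_object_um3 = 27) {
  mask <- clean_mask(cancer_mask, min_object_um3 = min_object_um3,
                     voxel_um = voxel_um)
  baseline <- estimate_baseline(mask, voxel_um)
  part <- partition_cancer(mask, baseline, voxel_um)
  cbind(invasion_metrics(part), baseline_z_um = baseline)
}

#' Quantify one volume end-to-end
#'
#' Segment (classifier, Otsu baseline, or supplied truth labels), clean the
#' cancer mask, estimate the baseline, partition, and compute all 3-D
#' invasion metrics.
#'
#' @param volume an [oct_volume()] (not needed when `labels` given and
#'   segmentation is `"truth"`).
#' @param classifier a `voxel_classifier` (for `segmentation = "classifier"`).
#' @param segmentation `"classifier"`, `"otsu"` or `"truth"`.
#' @param labels a [label_volume()] of ground truth (for `"truth"`).
#' @param min_object_um3 cleanup threshold.
#' @return one-row data.frame of metrics plus `baseline_z_um`.
#' @export
quantify_volume <- function(volume = NULL, classifier = NULL,
                            segmentation = c("classifier", "otsu", "truth"),
                            labels = NULL, min_object_um3 = 27) {
  segmentation <- match.arg(segmentation)
  if (segmentation == "classifier") {
    labs <- segment_volume(volume, classifier)
    cancer <- labs$data == 1L
    vx <- labs$voxel_um
  } else if (segmentation == "otsu") {
    cancer <- otsu_baseline(volume)
    vx <- volume$voxel_um
  } else {
    if (is.null(labels)) stop_("segmentation='truth' requires labels")
    cancer <- labels$data == 1L
    vx <- labels$voxel_um
  }
  quantify_cancer_mask(cancer, vx, min_object_um3)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full study pipeline
#'
#' Generates every replicate phantom, renders it, segments it with the
#' configured method, partitions the cancer mask and computes the metrics
#' table; then runs the comparison design on every configured metric:
#' Welch's t-test for the cell-line and stroma factors and Mann-Whitney U
#' for the day factor. Deterministic given `(config, seed)`; per-replicate
#' seeds are drawn once from `seed` and logged.
#'
#' @param config a [study_config()].
#' @param seed integer master seed.
#' @param out_dir optional output directory: writes `metrics.csv`,
#'   `comparisons.csv` and `log.json`.
#' @return list: `metrics` (per-replicate table), `comparisons`,
#'   `classifier` (or NULL), `log`.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL) {
  if (!inherits(config, "study_config")) stop_("expected a study_config")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  n_total <- sum(vapply(config$conditions, `[[`, 0, "n_replicates"))
  rep_seeds <- sample.int(.Machine$integer.max - 2L, 2L * n_total)

  classifier <- NULL
  if (config$segmentation == "classifier")
    classifier <- stage("train", train_study_classifier(config, seed = seed))

  rows <- list(); k <- 0L
  for (ci in seq_along(config$conditions)) {
    cd <- config$conditions[[ci]]
    for (r in seq_len(cd$n_replicates)) {
      k <- k + 1L
      s_build <- rep_seeds[2L * k - 1L]
      s_render <- rep_seeds[2L * k]
      truth <- stage("phantom", build_label_volume(cd$spec, seed = s_build))
      met <- if (config$segmentation == "truth") {
        stage("quantify", quantify_volume(segmentation = "truth",
                                          labels = truth$label_volume,
                                          min_object_um3 = config$min_object_um3))
      } else {
        vol <- stage("render", render_oct(truth, cd$spec, seed = s_render))
        stage("quantify", quantify_volume(vol, classifier,
                                          segmentation = config$segmentation,
                                          min_object_um3 = config$min_object_um3))
      }
      rows[[k]] <- cbind(data.frame(model_id = sprintf("%s_%s_d%s_r%d",
                                                       cd$cell_line, cd$stroma,
                                                       cd$day, r),
                                    cell_line = cd$cell_line,
                                    stroma = cd$stroma, day = cd$day,
                                    replicate = r,
                                    stringsAsFactors = FALSE),
                         met, seed_build = s_build, seed_render = s_render)
    }
  }
  metrics_tab <- do.call(rbind, rows)
  comparisons <- stage("compare", do.call(rbind, unlist(lapply(
    config$metrics, function(m)
      list(compare_factor(metrics_tab, "cell_line", m),
           compare_factor(metrics_tab, "stroma", m),
           compare_days(metrics_tab, m))),
    recursive = FALSE)))
  log <- list(seed = seed, n_models = n_total,
              segmentation = config$segmentation,
              n_comparisons = nrow(comparisons),
              package_version = as.character(utils::packageVersion("octinvasion")),
              r_version = R.version.string)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics(metrics_tab, file.path(out_dir, "metrics.csv"))
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE)
  }
  list(metrics = metrics_tab, comparisons = comparisons,
       classifier = classifier, log = log)
}

#' Factorial phantom study configuration with programmed effects
#'
#' Convenience builder for an 8-condition desk-scale study (2 cell lines x
#' 2 stromal conditions x 2 days). CAF-like stroma triples the programmed
#' invasion load relative to NOF-like stroma, and day 21 carries more
#' invasion than day 14, emulating the reported qualitative behaviour of
#' the organotypic models; cell line B uses island-dominated invasion,
#' cell line A finger/cohesive invasion.
#'
#' @param n_replicates replicates per condition (study range 3--6).
#' @param size voxel grid scale: `"small"` (64 x 48 x 48, fast) or
#'   `"medium"` (128 x 96 x 96).
#' @param caf_effect multiplier on invasion load for CAF-like stroma.
#' @param null_design if TRUE all eight conditions share one identical spec
#'   (no programmed effect), for type-I studies.
#' @param ... passed to [study_config()].
#' @return a `study_config`.
#' @export
default_study_config <- function(n_replicates = 4, size = c("small", "medium"),
                                 caf_effect = 3, null_design = FALSE, ...) {
  size <- match.arg(size)
  dims <- if (size == "small") list(depth = 64, lat = 48)
          else list(depth = 128, lat = 96)
  base <- function(pattern, load) {
    # `load` scales the number of invasion structures
    phantom_spec(lateral_size_um = c(dims$lat, dims$lat),
                 depth_um = dims$depth, voxel_um = 1,
                 cancer_thickness_um = round(dims$depth * 0.25),
                 invasion_pattern = pattern,
                 finger_count = max(1, round(2 * load)),
                 finger_depth_um = round(dims$depth * 0.3),
                 finger_radius_um = 5,
                 island_count = max(1, round(2 * load)),
                 island_radius_um = c(mean = 5, sd = 1),
                 island_depth_range_um = c(8, round(dims$depth * 0.35)),
                 fibroblast_density = 2000,
                 fibroblast_axis_um = c(6, 2, 2))
  }
  conds <- list()
  for (cl in c("A", "B")) for (st in c("CAF-like", "NOF-like"))
    for (dy in c(14, 21)) {
      load <- if (null_design) 1 else {
        l <- if (st == "CAF-like") caf_effect else 1
        l * (if (dy == 21) 1.5 else 1)
      }
      pattern <- if (null_design) "mixed" else if (cl == "A") "finger" else "island"
      conds[[length(conds) + 1L]] <-
        list(cell_line = cl, stroma = st, day = dy,
             n_replicates = n_replicates,
             spec = base(pattern, load))
    }
  study_config(conds, ...)
}
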