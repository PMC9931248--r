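#' Pipeline configuration
#'
#' Settings for the end-to-end grading run: where the scene rasters live,
#' which trained models to use, detector parameters and the validity
#' probability cutoff. Can be read from a YAML/JSON file with
#' [read_pipeline_config()]; individual arguments override file values.
#'
#' @param scene_dir directory of scene rasters (per image id:
#'   `{id}_fundus.png`, `{id}_vessel.png`, `{id}_av.png`, optional
#'   `{id}_cup.png`), or `NULL` when scenes are passed in memory.
#' @param out_dir output directory; all intermediates (refined maps,
#'   skeletons, candidate tables, patches) are persisted there.
#' @param validity_model,grading_model trained models (or checkpoint paths
#'   understood by [load_checkpoint()]).
#' @param merge_radius_px,check_radius_px detector parameters.
#' @param validity_cutoff probability above which a candidate is ruled a
#'   true crossing (in (0, 1)).
#' @param seed integer seed recorded in the report.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene_dir = NULL, out_dir = tempfile("mdtnet_run_"),
                            validity_model = NULL, grading_model = NULL,
                            merge_radius_px = 20, check_radius_px = 15,
                            validity_cutoff = 0.5, seed = 1L) {
  if (validity_cutoff <= 0 || validity_cutoff >= 1) {
    stop("validity_cutoff must lie in (0, 1)")
  }
  structure(list(scene_dir = scene_dir, out_dir = out_dir,
                 validity_model = validity_model,
                 grading_model = grading_model,
                 merge_radius_px = merge_radius_px,
                 check_radius_px = check_radius_px,
                 validity_cutoff = validity_cutoff, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML or JSON config file.
#' @param ... overrides for individual fields.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Write a scene's rasters to a directory
#'
#' @param scene a [vessel_scene()].
#' @param dir target directory.
#' @return the image id, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- scene$image_id
  write_fundus_png(scene$fundus, file.path(dir, paste0(id, "_fundus.png")))
  write_mask_png(scene$vessel_mask, file.path(dir, paste0(id, "_vessel.png")),
                 codes = 1L)
  write_mask_png(scene$av_map, file.path(dir, paste0(id, "_av.png")),
                 codes = 2L)
  if (!is.null(scene$cup_mask)) {
    write_mask_png(scene$cup_mask, file.path(dir, paste0(id, "_cup.png")),
                   codes = 1L)
  }
  invisible(id)
}

#' @rdname write_scene
#' @param id image id (file-name prefix).
#' @param subject_id subject identifier to attach (defaults to the id).
#' @export
read_scene <- function(dir, id, subject_id = id) {
  cup_path <- file.path(dir, paste0(id, "_cup.png"))
  vessel_scene(
    fundus = read_fundus_png(file.path(dir, paste0(id, "_fundus.png"))),
    vessel_mask = read_mask_png(file.path(dir, paste0(id, "_vessel.png")), 1L),
    av_map = read_mask_png(file.path(dir, paste0(id, "_av.png")), 2L),
    cup_mask = if (file.exists(cup_path)) read_mask_png(cup_path, 1L) else NULL,
    subject_id = subject_id, image_id = id)
}

list_scene_ids <- function(dir) {
  f <- list.files(dir, pattern = "_fundus\\.png$")
  sub("_fundus\\.png$", "", f)
}

#' Run the full grading pipeline
#'
#' For every scene: refine the artery/vein labels, skeletonize, detect
#' crossing candidates, cut 150 x 150 patches, filter candidates with the
#' validity classifier at the configured cutoff, and grade the survivors
#' with the grading model. Every intermediate (refined artery/vein map,
#' skeleton, candidate table, patches) is written under
#' `config$out_dir` so each step of the decision can be inspected, and the
#' report is reproducible byte for byte for a fixed config and seed.
#' Unreadable scenes are logged and skipped; the run continues.
#'
#' @param config a [pipeline_config()].
#' @param scenes optional list of [vessel_scene()]s (otherwise read from
#'   `config$scene_dir`).
#' @return an object of class `diagnosis_report`: list with `crossings`
#'   (data frame: ids, coordinates, validity probability and decision,
#'   grade probabilities and decision), `summary` (per-grade counts),
#'   `errors`, and the config echo. Also written as `report.json` /
#'   `crossings.csv` / `summary.csv` in `out_dir`.
#' @export
run_pipeline <- function(config, scenes = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  vm <- config$validity_model
  gm <- config$grading_model
  if (is.character(vm)) vm <- load_checkpoint(vm)
  if (is.character(gm)) gm <- load_checkpoint(gm)
  if (is.null(vm) || is.null(gm)) {
    stop("both a validity model and a grading model are required")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  patch_dir <- file.path(config$out_dir, "patches")
  inter_dir <- file.path(config$out_dir, "intermediates")
  dir.create(patch_dir, showWarnings = FALSE)
  dir.create(inter_dir, showWarnings = FALSE)

  ids <- if (!is.null(scenes)) {
    vapply(scenes, function(s) s$image_id, character(1))
  } else {
    list_scene_ids(config$scene_dir)
  }
  rows <- list()
  errors <- character(0)
  for (k in seq_along(ids)) {
    id <- ids[k]
    res <- tryCatch({
      scene <- if (!is.null(scenes)) scenes[[k]] else
        read_scene(config$scene_dir, id)
      scene <- refine_av_labels(scene)
      skel <- skeletonize(scene$vessel_mask)
      write_mask_png(scene$av_map,
                     file.path(inter_dir, paste0(id, "_av_refined.png")),
                     codes = 2L)
      write_mask_png(skel$skeleton_mask,
                     file.path(inter_dir, paste0(id, "_skeleton.png")),
                     codes = 1L)
      cand <- detect_candidates(scene, config$merge_radius_px,
                                config$check_radius_px)
      write.csv(cand, file.path(inter_dir, paste0(id, "_candidates.csv")),
                row.names = FALSE)
      if (nrow(cand) == 0) {
        empty_crossing_rows()
      } else {
        n <- nrow(cand)
        patches <- array(0, dim = c(150, 150, 3, n))
        paths <- character(n)
        for (j in seq_len(n)) {
          p <- extract_patch(scene, c(cand$row[j], cand$col[j]))
          patches[, , , j] <- p$pixels
          paths[j] <- file.path(patch_dir,
                                sprintf("%s_%d_%d.png", id,
                                        round(cand$row[j]),
                                        round(cand$col[j])))
          write_fundus_png(p$pixels, paths[j])
        }
        pv <- predict(vm, patches)
        valid <- pv$probs[, 2] >= config$validity_cutoff
        out <- data.frame(subject_id = scene$subject_id, image_id = id,
                          row = cand$row, col = cand$col, score = cand$score,
                          validity_prob = pv$probs[, 2], is_valid = valid,
                          patch_path = paths, stringsAsFactors = FALSE)
        out$grade <- NA_character_
        gp <- matrix(NA_real_, n, 4,
                     dimnames = list(NULL, paste0("p_", GRADE_LEVELS)))
        if (any(valid)) {
          pg <- predict(gm, patches[, , , valid, drop = FALSE])
          out$grade[valid] <- int_to_grade(pg$labels)
          gp[valid, ] <- pg$probs
        }
        cbind(out, as.data.frame(gp))
      }
    }, error = function(e) {
      errors <<- c(errors, paste0(id, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  crossings <- if (length(rows)) do.call(rbind, rows) else
    empty_crossing_rows()
  graded <- crossings$grade[!is.na(crossings$grade)]
  summary_df <- data.frame(grade = GRADE_LEVELS,
                           count = as.integer(table(factor(graded,
                                                           GRADE_LEVELS))))
  report <- structure(list(
    crossings = crossings, summary = summary_df, errors = errors,
    n_scenes = length(ids),
    config = list(merge_radius_px = config$merge_radius_px,
                  check_radius_px = config$check_radius_px,
                  validity_cutoff = config$validity_cutoff,
                  seed = config$seed),
    package_version = as.character(utils::packageVersion("mdtnet"))),
    class = "diagnosis_report")
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  write.csv(crossings, file.path(config$out_dir, "crossings.csv"),
            row.names = FALSE)
  write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
            row.names = FALSE)
  if (length(errors)) {
    warning(length(errors), " scene(s) failed: ",
            paste(errors, collapse = "; "))
  }
  report
}

empty_crossing_rows <- function() {
  gp <- matrix(numeric(0), 0, 4,
               dimnames = list(NULL, paste0("p_", GRADE_LEVELS)))
  cbind(data.frame(subject_id = character(0), image_id = character(0),
                   row = numeric(0), col = numeric(0), score = numeric(0),
                   validity_prob = numeric(0), is_valid = logical(0),
                   patch_path = character(0), grade = character(0),
                   stringsAsFactors = FALSE),
        as.data.frame(gp))
}

#' Evaluate a pipeline report against ground truth
#'
#' Matches reported crossings to the truth manifest per image
#' (greedy one-to-one within `tol_px`), then scores the two tasks the way
#' the grading protocol prescribes: validity precision/recall over matched
#' candidates (positive class = true crossing) and grading
#' accuracy/kappa over the matched crossings that are truly valid and were
#' ruled valid.
#'
#' @param report a `diagnosis_report` from [run_pipeline()].
#' @param truth data frame of ground-truth records (as from
#'   [generate_scene()] / [generate_dataset()]).
#' @param tol_px matching tolerance in pixels.
#' @return list with `validity` and `grading` [eval_report()]s plus
#'   detection counts (`detect_tp`, `detect_fp`, `detect_fn`).
#' @export
evaluate_pipeline <- function(report, truth, tol_px = 5) {
  stopifnot(inherits(report, "diagnosis_report"))
  cr <- report$crossings
  if (length(intersect(unique(cr$image_id), unique(truth$image_id))) == 0 &&
      nrow(cr) > 0) {
    stop("report and truth manifest cover disjoint image id sets")
  }
  v_truth <- integer(0); v_pred <- integer(0)
  g_truth <- integer(0); g_pred <- integer(0)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (id in unique(truth$image_id)) {
    tr <- truth[truth$image_id == id, , drop = FALSE]
    ca <- cr[cr$image_id == id, , drop = FALSE]
    m <- match_candidates(ca, tr, tol_px)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    if (m$tp > 0) {
      for (r in seq_len(nrow(m$pairs))) {
        i <- m$pairs[r, 1]; j <- m$pairs[r, 2]
        v_truth <- c(v_truth, as.integer(tr$is_valid[j]))
        v_pred <- c(v_pred, as.integer(ca$is_valid[i]))
        if (tr$is_valid[j] && ca$is_valid[i] && !is.na(ca$grade[i])) {
          g_truth <- c(g_truth, grade_to_int(tr$grade[j]))
          g_pred <- c(g_pred, grade_to_int(ca$grade[i]))
        }
      }
    }
  }
  list(validity = eval_report(v_truth, v_pred, 2L),
       grading = eval_report(g_truth, g_pred, 4L),
       detect_tp = tp, detect_fp = fp, detect_fn = fn)
}
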