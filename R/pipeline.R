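# Resumable end-to-end pipeline: teacher self-training with quality-screened
# pseudo-labels, CAM-guided student training, and mask-assisted disease
# classification, with per-stage artifact persistence and a JSON manifest.

#' Pipeline run configuration
#'
#' @param generator a [generator_config()] for the synthetic data stage (its
#'   seed is overridden by the pipeline's per-stage seed derived from
#'   `seed`).
#' @param n_pixel_labeled,n_image_labeled,n_unlabeled,n_test split sizes;
#'   defaults are the standard desk-scale scenario (100/100/200/50 at
#'   64 x 64).
#' @param n_val size of the pixel-labeled validation split used to monitor
#'   the student networks' convergence: each student keeps the weights of
#'   its best validation-Jaccard epoch. The teacher trains for the full
#'   epoch budget without monitoring so its checkpoint schedule stays
#'   fixed.
#' @param student_patience early-stopping patience for the students; the
#'   default `Inf` trains the full budget and only performs the best-epoch
#'   selection.
#' @param seg_cfg,quality_cfg,disease_cfg [train_config()]s for the
#'   segmentation networks, the quality classifier and the disease
#'   classifier.
#' @param t pseudo-label quality threshold (see [quality_threshold()]).
#' @param k number of teacher checkpoints.
#' @param data_dirs optional named list of ISIC-layout directories
#'   (`pixel`, `image`, `unlabeled`, `test`) used instead of the synthetic
#'   generator.
#' @param seed global seed; per-stage seeds are derived from it by stable
#'   hashing of the stage name so stages can be rerun independently.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       n_pixel_labeled = 100L, n_image_labeled = 100L,
                       n_unlabeled = 200L, n_test = 50L, n_val = 15L,
                       student_patience = Inf,
                       seg_cfg = train_config(learning_rate = 3e-4,
                                              max_epochs = 15L),
                       quality_cfg = train_config(learning_rate = 1e-3,
                                                  max_epochs = 10L),
                       disease_cfg = train_config(learning_rate = 1e-3,
                                                  max_epochs = 70L,
                                                  shift_max = 0L),
                       t = 0.8, k = 5L, data_dirs = NULL, seed = 1L) {
  structure(list(generator = generator,
                 n_pixel_labeled = as.integer(n_pixel_labeled),
                 n_image_labeled = as.integer(n_image_labeled),
                 n_unlabeled = as.integer(n_unlabeled),
                 n_test = as.integer(n_test), n_val = as.integer(n_val),
                 student_patience = student_patience,
                 seg_cfg = seg_cfg, quality_cfg = quality_cfg,
                 disease_cfg = disease_cfg, t = t, k = as.integer(k),
                 data_dirs = data_dirs, seed = as.integer(seed)),
            class = "run_config")
}

#' Derive a per-stage seed from the global seed
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u))
  as.integer((seed * 7919 + h * 104729) %% 2147483647)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

read_manifest <- function(out_dir) {
  mf <- file.path(out_dir, "manifest.json")
  if (file.exists(mf)) jsonlite::read_json(mf) else
    list(package = "pseudoseg", config_hash = NULL, stages = list())
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(manifest)
}

#' Run the collaborative-learning pipeline
#'
#' Executes the stages in order, persisting every intermediate artifact
#' under `out_dir` and recording status, artifact paths, seeds and summary
#' metrics in `manifest.json`. A stage whose artifacts already exist under a
#' matching configuration hash is skipped, so a rerun resumes from the first
#' missing stage; deleting a stage's artifact files forces it (and its
#' dependents' consumers) to recompute.
#'
#' Stages: (1) teacher training with k checkpoints; (2) quality-grade set
#' and quality classifier; (3) screening the unlabeled pool; (4) disease
#' classifiers without masks and with teacher masks; (5) CAMs and student
#' training (with and without pseudo-labels); (6) disease classifier with
#' student masks; (7) evaluation of both tasks on the held-out test set.
#' Data generation/loading runs first as stage "data".
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory for artifacts and the manifest.
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg[setdiff(names(cfg), "data_dirs")])
  manifest <- read_manifest(out_dir)
  if (!is.null(manifest$config_hash) &&
      !identical(manifest$config_hash, hash)) {
    manifest <- list(package = "pseudoseg", config_hash = hash, stages = list())
  }
  manifest$config_hash <- hash
  art <- function(...) file.path(out_dir, paste0(..., ".rds"))
  cache <- new.env(parent = emptyenv())
  get_art <- function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    cache[[name]] <- readRDS(art(name))
    cache[[name]]
  }
  dirty <- FALSE  # once any stage recomputes, downstream stages must too
  stage <- function(name, files, fn) {
    st <- manifest$stages[[name]]
    paths <- vapply(files, art, character(1))
    if (!dirty && !is.null(st) && identical(st$status, "done") &&
        all(file.exists(paths))) {
      if (!quiet) message("stage ", name, ": cached")
      return(invisible(NULL))
    }
    dirty <<- TRUE
    if (!quiet) message("stage ", name, ": running")
    t0 <- Sys.time()
    set.seed(stage_seed(cfg$seed, name))
    out <- fn()
    for (f in files) {
      saveRDS(out[[f]], art(f), compress = FALSE)
      cache[[f]] <- out[[f]]
    }
    manifest$stages[[name]] <<- list(
      status = "done", files = as.list(unname(paths)),
      seed = stage_seed(cfg$seed, name),
      elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
      summary = out$summary)
    write_manifest(manifest, out_dir)
    invisible(NULL)
  }

  stage("data", c("splits"), function() {
    if (!is.null(cfg$data_dirs)) {
      rd <- function(d) read_isic_dir(cfg$data_dirs[[d]])
      px <- rd("pixel"); im <- rd("image"); un <- rd("unlabeled"); te <- rd("test")
      splits <- list(
        dlp = pixel_labeled_set(lapply(px, function(s) s[c("image", "mask")])),
        dli = image_labeled_set(lapply(im, function(s) s[c("image", "label")])),
        du = unlabeled_set(lapply(un, function(s) s$image)),
        test = te)
    } else {
      gen <- cfg$generator
      gen$seed <- stage_seed(cfg$seed, "data")
      splits <- generate_splits(gen, cfg$n_pixel_labeled, cfg$n_image_labeled,
                                cfg$n_unlabeled, cfg$n_test, cfg$n_val)
    }
    list(splits = splits,
         summary = list(n_pixel = length(splits$dlp), n_image = length(splits$dli),
                        n_unlabeled = length(splits$du),
                        n_test = length(splits$test)))
  })

  stage("teacher", c("teacher", "checkpoints"), function() {
    splits <- get_art("splits")
    teacher0 <- seg_model()
    tr <- train_seg(teacher0, splits$dlp, cfg$seg_cfg,
                    checkpoint_epochs = default_checkpoint_epochs(
                      cfg$seg_cfg$max_epochs, cfg$k))
    list(teacher = tr$model, checkpoints = tr$checkpoints,
         summary = list(final_loss = unname(tail(tr$history$loss, 1)),
                        k = length(tr$checkpoints)))
  })

  stage("quality", c("quality", "quality_grades"), function() {
    splits <- get_art("splits")
    dq <- build_quality_dataset(splits$dlp, get_art("checkpoints"),
                                quality_threshold(cfg$t))
    q <- train_quality_cn(dq, cfg$quality_cfg)
    grades <- data.frame(
      quality = vapply(dq$items, function(it) it$quality, integer(1)),
      score = vapply(dq$items, function(it) it$score, numeric(1)))
    list(quality = q, quality_grades = grades,
         summary = list(n = nrow(grades), frac_reliable = mean(grades$quality)))
  })

  stage("screen", c("pseudo", "screen_report"), function() {
    splits <- get_art("splits")
    scr <- screen_pool(splits$du, get_art("teacher"), get_art("quality"))
    write.csv(scr$report, file.path(out_dir, "screening_report.csv"),
              row.names = FALSE)
    list(pseudo = scr$set, screen_report = scr$report,
         summary = list(n = length(splits$du), n_prime = length(scr$set)))
  })

  stage("disease", c("disease_base", "disease_teacher"), function() {
    splits <- get_art("splits")
    teacher <- get_art("teacher")
    images <- lapply(splits$dli$items, function(it) it$image)
    tmasks <- predict_masks(teacher, images)
    base <- train_disease_cn(splits$dli, masks = NULL, cfg$disease_cfg)
    dt <- train_disease_cn(splits$dli, masks = tmasks, cfg$disease_cfg)
    list(disease_base = base, disease_teacher = dt,
         summary = list(n_train = length(splits$dli)))
  })

  stage("student", c("student_cam", "student_full"), function() {
    splits <- get_art("splits")
    dt <- get_art("disease_teacher")
    pseudo <- get_art("pseudo")
    cams_dlp <- cam_batch_for_training(dt, splits$dlp)
    cams_ps <- if (length(pseudo) > 0L) cam_batch_for_training(dt, pseudo)
               else list()
    stud_cfg <- cfg$seg_cfg
    if (length(splits$val) > 0L) stud_cfg$patience <- cfg$student_patience
    s_cam0 <- seg_model(fusion = TRUE)
    s_cam <- train_student(s_cam0, splits$dlp, NULL, cams_dlp, stud_cfg,
                           val = splits$val)
    set.seed(stage_seed(cfg$seed, "student"))  # same init stream for both
    s_full0 <- seg_model(fusion = TRUE)
    s_full <- train_student(s_full0, splits$dlp, pseudo,
                            c(cams_dlp, cams_ps), stud_cfg,
                            val = splits$val)
    list(student_cam = s_cam, student_full = s_full,
         summary = list(n_cam = length(splits$dlp),
                        n_full = length(splits$dlp) + length(pseudo)))
  })

  stage("disease_student", c("disease_student"), function() {
    splits <- get_art("splits")
    images <- lapply(splits$dli$items, function(it) it$image)
    smasks <- lapply(images, function(im)
      binarize(two_pass_forward(get_art("student_full"), im,
                                get_art("teacher"), get_art("disease_teacher"))))
    ds <- train_disease_cn(splits$dli, masks = smasks, cfg$disease_cfg)
    list(disease_student = ds, summary = list(n_train = length(splits$dli)))
  })

  stage("evaluate", c("evaluation"), function() {
    ev <- evaluate_artifacts(
      test = get_art("splits")$test, teacher = get_art("teacher"),
      student_cam = get_art("student_cam"),
      student_full = get_art("student_full"),
      disease_base = get_art("disease_base"),
      disease_teacher = get_art("disease_teacher"),
      disease_student = get_art("disease_student"))
    write_metrics_csv(ev$segmentation, file.path(out_dir, "evaluation_seg.csv"))
    write_metrics_csv(ev$classification, file.path(out_dir, "evaluation_cls.csv"))
    list(evaluation = ev,
         summary = list(teacher_ja = ev$segmentation$ja[1],
                        student_full_ja = ev$segmentation$ja[3],
                        auc_none = ev$classification$auc[1],
                        auc_student = ev$classification$auc[3]))
  })

  invisible(read_manifest(out_dir))
}

# Ablation evaluation used by the final pipeline stage and evaluate_run():
# segmentation rows {teacher, student+CAMs, student+CAMs+PLs} and
# classification rows {no mask, teacher mask, student mask}, all on the same
# held-out test set. Students are evaluated with two-pass inference (teacher
# mask -> disease classifier CAM -> student).
evaluate_artifacts <- function(test, teacher, student_cam, student_full,
                               disease_base, disease_teacher,
                               disease_student) {
  truths <- lapply(test, function(s) s$mask)
  images <- lapply(test, function(s) s$image)
  pred_teacher <- predict_masks(teacher, images)
  two_pass_masks <- function(student) lapply(images, function(im)
    binarize(two_pass_forward(student, im, teacher, disease_teacher)))
  pred_scam <- two_pass_masks(student_cam)
  pred_sfull <- two_pass_masks(student_full)
  seg <- rbind(
    cbind(model = "teacher", evaluate_segmentation(pred_teacher, truths)),
    cbind(model = "student_cams", evaluate_segmentation(pred_scam, truths)),
    cbind(model = "student_cams_pls", evaluate_segmentation(pred_sfull, truths)))
  cls_case <- function(model, masks, source) {
    items <- lapply(seq_along(test), function(i)
      list(image = test[[i]]$image, label = test[[i]]$label,
           mask = if (!is.null(masks)) masks[[i]]))
    rep_df <- evaluate_disease_cn(model, items)
    cbind(mask_source = source, rep_df[rep_df$class == "average",
                                       c("ac", "se", "sp", "auc")])
  }
  cls <- rbind(
    cls_case(disease_base, NULL, "none"),
    cls_case(disease_teacher, pred_teacher, "teacher"),
    cls_case(disease_student, pred_sfull, "student"))
  rownames(seg) <- rownames(cls) <- NULL
  list(segmentation = seg, classification = cls)
}

#' Evaluate a completed pipeline run
#'
#' Loads the run's persisted artifacts and recomputes the ablation grid:
#' three segmentation rows (teacher; student with CAMs; student with CAMs
#' and pseudo-labels) and three classification rows (no mask; teacher mask;
#' student mask), all on the run's held-out test split.
#'
#' @param out_dir directory of a completed [run_pipeline()] run.
#' @return list with data frames `segmentation` and `classification`.
#' @export
evaluate_run <- function(out_dir) {
  need <- c("splits", "teacher", "student_cam", "student_full",
            "disease_base", "disease_teacher", "disease_student")
  paths <- file.path(out_dir, paste0(need, ".rds"))
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing artifacts (incomplete stages): ",
         paste(missing, collapse = ", "))
  a <- lapply(paths, readRDS)
  names(a) <- need
  evaluate_artifacts(a$splits$test, a$teacher, a$student_cam, a$student_full,
                     a$disease_base, a$disease_teacher, a$disease_student)
}
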