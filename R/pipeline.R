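# End-to-end orchestration: generate (or load) -> extract -> split ->
# train -> rank -> report, with one master seed and a structured log.

#' Pipeline configuration
#'
#' Defaults follow the study design the package implements: 6x6 patches,
#' 10 patches per image, 8 gray levels for the GLCM, distances 1..5 at
#' angles 0/45/90/135 degrees, an image-level 75/25 split, and the full
#' 12-classifier zoo.
#'
#' @param manifest path to a labeled image manifest CSV, or `NULL` to
#'   generate the default synthetic dataset.
#' @param synthetic a [synthetic_config()] used when `manifest` is
#'   `NULL` (its seed is re-derived from `seed`).
#' @param patch_size patch side length in pixels.
#' @param n_per_image patches sampled per image.
#' @param L gray-level count for GLCM quantization.
#' @param distances,angles GLCM offset grid.
#' @param train_fraction image-level training proportion.
#' @param models classifier names, see [zoo_model_names()].
#' @param top_k how many top models the ranking flags.
#' @param seed master integer seed for every random stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, synthetic = NULL,
                            patch_size = 6L, n_per_image = 10L, L = 8L,
                            distances = 1:5, angles = GLCM_ANGLES,
                            train_fraction = 0.75,
                            models = zoo_model_names(), top_k = 5L,
                            seed = 1L) {
  structure(
    list(manifest = manifest,
         synthetic = synthetic %||% synthetic_config(seed = seed),
         patch_size = as.integer(patch_size),
         n_per_image = as.integer(n_per_image), L = as.integer(L),
         distances = distances, angles = angles,
         train_fraction = train_fraction, models = models,
         top_k = as.integer(top_k), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Stages: (1) load the manifest or generate the synthetic dataset;
#' (2) extract the patch-level feature table; (3) split at the image
#' level; (4) train the classifier zoo; (5) rank models by test AUC;
#' (6) write artifacts.  Artifacts in `out_dir`: `features.csv`,
#' `ranking.csv` (AUC order), `report.csv` (per-model metrics),
#' `report.json`, `pipeline.log`, and one `models/<name>.rds` per
#' fitted model.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created if missing).
#' @return list with `features`, `split`, `models`, `ranking`,
#'   `out_dir`, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  on.exit(writeLines(log_lines, log_path))

  say("stage=data seed=%d", cfg$seed)
  manifest <- if (is.null(cfg$manifest)) {
    syn <- cfg$synthetic
    syn$seed <- derive_seed(cfg$seed, "synthetic")
    dir_img <- file.path(out_dir, "images")
    say("stage=data generating synthetic dataset: %d/class, %dx%d px",
        syn$n_images_per_class, syn$image_size, syn$image_size)
    read_manifest(generate_dataset(syn, dir_img))
  } else {
    read_manifest(cfg$manifest)
  }

  say("stage=extract images=%d patches_per_image=%d patch_size=%d L=%d",
      nrow(manifest), cfg$n_per_image, cfg$patch_size, cfg$L)
  ds <- extract_dataset(manifest, n_per_image = cfg$n_per_image,
                        patch_size = cfg$patch_size,
                        seed = derive_seed(cfg$seed, "extract"),
                        L = cfg$L, distances = cfg$distances,
                        angles = cfg$angles)
  write_feature_csv(ds, file.path(out_dir, "features.csv"))
  say("stage=extract rows=%d", nrow(ds))

  split <- split_dataset(ds, train_fraction = cfg$train_fraction,
                         seed = derive_seed(cfg$seed, "split"))
  say("stage=split train_rows=%d test_rows=%d train_images=%d test_images=%d",
      nrow(split$train), nrow(split$test), length(split$train_ids),
      length(split$test_ids))

  say("stage=train models=%s", paste(cfg$models, collapse = ","))
  models <- train_zoo(split$train, model_names = cfg$models,
                      seed = derive_seed(cfg$seed, "train"))
  mdir <- file.path(out_dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (m in models) save_model(m, file.path(mdir, paste0(m$name, ".rds")))

  ranking <- rank_by_auc(models, split$test, k = cfg$top_k)
  for (i in seq_len(nrow(ranking$entries))) {
    say("stage=rank model=%s auc=%.4f", ranking$entries$name[i],
        ranking$entries$auc[i])
  }
  utils::write.csv(ranking$entries, file.path(out_dir, "ranking.csv"),
                   row.names = FALSE)
  write_report_csv(ranking, file.path(out_dir, "report.csv"))
  report <- list(
    seed = cfg$seed,
    n_images = nrow(manifest),
    n_patches = nrow(ds),
    train_rows = nrow(split$train),
    test_rows = nrow(split$test),
    ranking = ranking$entries,
    top_model = ranking$entries$name[1],
    top_auc = ranking$entries$auc[1]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  say("stage=done top_model=%s top_auc=%.4f", report$top_model,
      report$top_auc)
  invisible(list(features = ds, split = split, models = models,
                 ranking = ranking, out_dir = out_dir))
}
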