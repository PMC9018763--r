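# End-to-end orchestration: preprocess -> tooth branch -> bone branch ->
# fusion -> outputs.

#' Pipeline configuration
#'
#' @param scale `"desk"` (32^3 tiling patches, 24^3 tooth crops — sized for
#'   CPU runs on small phantoms) or `"paper"` (256^3 / 96^3, the full-scale
#'   preset).
#' @param models `list(roi, centroid, skeleton, tooth, bone)`: predictors, or
#'   paths to checkpoints from [save_model()]; `bone` may be a list of two
#'   (cascade). Ignored in oracle mode.
#' @param oracle_gt optional `phantom_gt`; when set, ground-truth oracle
#'   predictors replace all networks.
#' @param no_skeleton,no_multitask,no_haar ablation switches.
#' @param clustering a [cluster_params()].
#' @param target_mm working isotropic resolution (mm).
#' @param clip intensity clipping window before normalization.
#' @param overlap_fraction sliding-window overlap.
#' @param fdi_source `"classifier"` (default; the FDI head overrides the
#'   arch-position heuristic) or `"heuristic"`.
#' @param seed run seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(scale = c("desk", "paper"), models = NULL,
                            oracle_gt = NULL, no_skeleton = FALSE,
                            no_multitask = FALSE, no_haar = FALSE,
                            clustering = cluster_params(), target_mm = 0.4,
                            clip = c(0, 2500), overlap_fraction = 0,
                            fdi_source = c("classifier", "heuristic"),
                            seed = 1L) {
  scale <- match.arg(scale)
  fdi_source <- match.arg(fdi_source)
  patches <- if (scale == "desk") list(vol = c(32L, 32L, 32L), tooth = c(24L, 24L, 24L))
             else list(vol = c(256L, 256L, 256L), tooth = c(96L, 96L, 96L))
  structure(list(scale = scale, models = models, oracle_gt = oracle_gt,
                 no_skeleton = no_skeleton, no_multitask = no_multitask,
                 no_haar = no_haar, clustering = clustering,
                 target_mm = target_mm, clip = clip,
                 overlap_fraction = overlap_fraction, fdi_source = fdi_source,
                 patches = patches, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_predictors <- function(cfg) {
  if (!is.null(cfg$oracle_gt)) {
    gt <- cfg$oracle_gt
    return(list(roi = oracle_predictor(gt, "roi"),
                centroid = oracle_predictor(gt, "centroid"),
                skeleton = if (!cfg$no_skeleton) oracle_predictor(gt, "skeleton"),
                tooth = oracle_predictor(gt, "tooth"),
                bone = list(oracle_predictor(gt, "bone"))))
  }
  m <- cfg$models
  need <- c("roi", "centroid", "tooth", "bone")
  if (!cfg$no_skeleton) need <- c(need, "skeleton")
  for (nm in need) {
    if (is.null(m[[nm]]))
      stopf("pipeline: model '%s' not configured (and not in oracle mode)", nm)
    if (is.character(m[[nm]]) && !file.exists(m[[nm]]))
      stopf("pipeline: model file missing: %s", m[[nm]])
  }
  load1 <- function(x) if (is.character(x)) load_model(x) else x
  bone <- m$bone
  if (inherits(bone, "dent_predictor") || is.character(bone)) bone <- list(bone)
  list(roi = load1(m$roi), centroid = load1(m$centroid),
       skeleton = if (!cfg$no_skeleton) load1(m$skeleton),
       tooth = load1(m$tooth), bone = lapply(bone, load1))
}

#' Run the full two-branch segmentation pipeline
#'
#' Preprocesses the scan (resampling to the working isotropic resolution,
#' clipping to the configured window, normalizing to `[0, 1]`), runs the
#' tooth and bone branches, fuses overlapping claims by probability, and
#' optionally writes all outputs (NIfTI label volumes, per-tooth JSON, run
#' log) to a directory. Deterministic given models/oracle and seed.
#'
#' @param image a [volume()] or path to a NIfTI file.
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return `list(teeth, bones, tooth_prob, bone_prob, instances, conflicts,
#'   preprocessed, log)`.
#' @export
run_pipeline <- function(image, cfg = pipeline_config(), out_dir = NULL) {
  t0 <- proc.time()[3]
  predictors <- resolve_predictors(cfg)   # fail fast on missing models
  v <- if (is.character(image)) read_volume(image) else image
  stopifnot(is_volume(v))
  timings <- c()
  tick <- function(nm) {
    timings[nm] <<- proc.time()[3] - t0
    t0 <<- proc.time()[3]
  }
  if (max(abs(v$spacing - cfg$target_mm)) > 1e-6)
    v <- resample_isotropic(v, cfg$target_mm)
  v <- clip_normalize(v, cfg$clip[1], cfg$clip[2])
  tick("preprocess")

  tooth <- run_tooth_branch(v, predictors, patch = cfg$patches$vol,
                            tooth_patch = cfg$patches$tooth,
                            params = cfg$clustering,
                            overlap_fraction = cfg$overlap_fraction,
                            use_skeleton = !cfg$no_skeleton,
                            use_classifier = cfg$fdi_source == "classifier")
  tick("tooth_branch")

  pair <- enhanced_pair(v, use_haar = !cfg$no_haar)
  bone <- segment_bones(pair, predictors$bone, patch = cfg$patches$vol,
                        overlap_fraction = cfg$overlap_fraction)
  bone_conf <- channel_max(bone$prob)
  tick("bone_branch")

  fused <- fuse(tooth$labels, tooth$prob, bone$labels, bone_conf)
  tick("fuse")

  res <- list(teeth = fused$teeth, bones = fused$bones,
              tooth_prob = tooth$prob, bone_prob = volume(bone_conf, v$spacing),
              instances = tooth$instances, instance_ids = tooth$instance_ids,
              conflicts = tooth$conflicts,
              preprocessed = v,
              log = list(config = summarize_config(cfg), timings = as.list(timings)))
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir, cfg)
  res
}

summarize_config <- function(cfg) {
  list(scale = cfg$scale, oracle = !is.null(cfg$oracle_gt),
       no_skeleton = cfg$no_skeleton, no_multitask = cfg$no_multitask,
       no_haar = cfg$no_haar, clustering = cfg$clustering,
       target_mm = cfg$target_mm, clip = cfg$clip,
       overlap_fraction = cfg$overlap_fraction, fdi_source = cfg$fdi_source,
       patches = cfg$patches, seed = cfg$seed)
}

write_pipeline_outputs <- function(res, out_dir, cfg) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(res$teeth, file.path(out_dir, "tooth_labels.nii.gz"), datatype = "uint16")
  write_volume(res$bones, file.path(out_dir, "bone_labels.nii.gz"), datatype = "uint16")
  sp <- res$teeth$spacing
  inst <- lapply(res$instances, function(i) {
    list(instance_id = i$instance_id, fdi = i$fdi,
         centroid_mm = unname(i$centroid * sp),
         volume_mm3 = sum(i$mask_crop) * prod(sp),
         crop_origin = unname(i$crop_origin))
  })
  jsonlite::write_json(inst, file.path(out_dir, "teeth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Vectorized per-voxel max over the channel dimension of a (3,D,H,W) array.
channel_max <- function(prob) {
  m <- prob[1L, , , ]
  for (c in 2:dim(prob)[1]) m <- pmax(m, prob[c, , , ])
  m
}
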