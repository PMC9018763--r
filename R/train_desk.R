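# Desk-scale training study: builds training samples from synthetic
# phantoms, trains all five networks (ROI, centroid offsets, skeleton
# offsets, multi-task single tooth, cascaded bone), and evaluates the
# learned pipeline on held-out phantoms.

#' Options for the desk-scale training study
#'
#' @param epochs maximum training epochs per network.
#' @param crops_per_phantom random volume crops drawn per phantom for the
#'   ROI / offset / bone networks.
#' @param teeth_per_phantom teeth sampled per phantom for the single-tooth
#'   network.
#' @param learning_rate,patience_epochs,patience_tolerance passed to
#'   [train_config()].
#' @param levels,base_channels,convs_per_stage backbone size.
#' @param vol_patch,tooth_patch patch sizes (volume networks / tooth crops).
#' @param no_skeleton,no_multitask,no_haar ablation switches; they change
#'   which networks and heads are built and trained.
#' @param cascade if `TRUE`, train the two-stage bone cascade.
#' @param bone_levels backbone depth of the bone networks; the default 3
#'   widens the receptive field enough to tell midface from mandible.
#' @param bone_patch training crop for the bone networks; the default spans
#'   the full z extent of the 48-voxel study phantoms, so vertical position
#'   (which separates the two bones) is always visible.
#' @param bone_learning_rate Adam step size for the (deeper) bone networks.
#' @param cascade_epochs epoch cap for the second (refinement) cascade
#'   stage, which converges quickly given the coarse probabilities.
#' @param bone_class_weights cross-entropy class weights (background,
#'   midface, mandible) for the bone networks.
#' @param tooth_epochs epoch cap for the single-tooth network (its steps are
#'   cheap, so it trains longer).
#' @param offset_scale offset regression targets are multiplied by this
#'   during training (and predictions rescaled back at inference) so the
#'   regression lives near unit magnitude.
#' @param class_weight loss weight of the FDI classifier head.
#' @param seed study seed (initialization, crop and data order).
#' @return a `desk_options` list.
#' @export
desk_options <- function(epochs = 10L, crops_per_phantom = 1L,
                         teeth_per_phantom = 3L, learning_rate = 4e-3,
                         patience_epochs = 5L, patience_tolerance = 1e-4,
                         levels = 2L, base_channels = 4L, convs_per_stage = 1L,
                         vol_patch = c(24L, 24L, 24L),
                         tooth_patch = c(24L, 24L, 24L),
                         no_skeleton = FALSE, no_multitask = FALSE,
                         no_haar = FALSE, cascade = TRUE, offset_scale = 0.2,
                         class_weight = 0.3, bone_levels = 3L,
                         bone_patch = c(48L, 24L, 24L),
                         bone_learning_rate = 2e-3, cascade_epochs = 5L,
                         bone_class_weights = c(1, 3, 3),
                         tooth_epochs = 16L, seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 crops_per_phantom = as.integer(crops_per_phantom),
                 teeth_per_phantom = as.integer(teeth_per_phantom),
                 learning_rate = learning_rate,
                 patience_epochs = as.integer(patience_epochs),
                 patience_tolerance = patience_tolerance,
                 levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 convs_per_stage = as.integer(convs_per_stage),
                 vol_patch = as.integer(vol_patch),
                 tooth_patch = as.integer(tooth_patch),
                 no_skeleton = no_skeleton, no_multitask = no_multitask,
                 no_haar = no_haar, cascade = cascade,
                 offset_scale = offset_scale, class_weight = class_weight,
                 bone_levels = as.integer(bone_levels),
                 bone_patch = as.integer(bone_patch),
                 bone_learning_rate = bone_learning_rate,
                 cascade_epochs = as.integer(cascade_epochs),
                 bone_class_weights = bone_class_weights,
                 tooth_epochs = as.integer(tooth_epochs),
                 seed = as.integer(seed)),
            class = "desk_options")
}

#' Precompute per-phantom training arrays
#'
#' Normalized image, foreground masks, bone labels and the Haar enhancement,
#' in the form the sample builders consume; compute once and pass to
#' [train_dental_system()] when training several seeds on the same phantoms.
#'
#' @param phantoms list of `generate_phantom()` outputs.
#' @param use_haar whether to compute the Haar channel.
#' @return list of per-phantom data lists.
#' @export
prepare_training_data <- function(phantoms, use_haar = TRUE) {
  lapply(phantoms, phantom_training_data, use_haar = use_haar)
}

# Cache the per-phantom arrays used by several sample builders.
phantom_training_data <- function(ph, use_haar = TRUE) {
  v <- clip_normalize(ph$image)
  labels <- ph$gt$tooth_labels$voxels
  list(img = v$voxels, v = v, labels = labels, fg = labels > 0L,
       bones = ph$gt$bone_labels$voxels,
       haar = if (use_haar) haar_enhance(v)$voxels else array(0, dim(v$voxels)),
       gt = ph$gt)
}

random_window <- function(d, patch, center = NULL, jitter = 4L) {
  if (is.null(center)) {
    start <- vapply(1:3, function(ax) sample.int(max(1L, d[ax] - patch[ax] + 1L), 1L), 1L)
  } else {
    start <- round(center - patch / 2) + sample(seq(-jitter, jitter), 3, replace = TRUE)
    start <- clampi(start, 1L, d - patch + 1L)
  }
  list(start = as.integer(start), size = as.integer(patch))
}

# Samples for the ROI network: image crop -> tooth-foreground mask.
roi_samples <- function(datas, patch, n_per) {
  out <- list()
  for (td in datas) {
    d <- dim(td$img)
    ctr <- colMeans(mask_coords(td$fg))
    for (i in seq_len(n_per)) {
      win <- random_window(d, patch, center = ctr, jitter = 6L)
      out[[length(out) + 1L]] <- list(
        x = array(crop_window(td$img, win), c(1L, patch)),
        targets = list(mask = array(as.numeric(crop_window(td$fg, win)), c(1L, patch))))
    }
  }
  out
}

# Samples for the centroid/skeleton offset networks.
offset_samples <- function(datas, patch, n_per, mode, scale = 1) {
  out <- list()
  for (td in datas) {
    d <- dim(td$img)
    off <- make_offset_targets(td$labels, mode, td$gt)
    ctr <- colMeans(mask_coords(td$fg))
    for (i in seq_len(n_per)) {
      win <- random_window(d, patch, center = ctr, jitter = 4L)
      m <- crop_window(td$fg, win)
      out[[length(out) + 1L]] <- list(
        x = array(crop_window(td$img, win), c(1L, patch)),
        targets = list(offset = scale * crop_window(off$vectors, win),
                       mask = array(as.numeric(m), c(1L, patch))),
        mask = m)
    }
  }
  out
}

# Samples for the multi-task single-tooth network: GT-centered 3-channel
# crops with mask/boundary/apex targets and the FDI class.
tooth_samples <- function(datas, patch, n_per, no_multitask = FALSE) {
  out <- list()
  for (td in datas) {
    gt <- td$gt
    fdis <- as.integer(rownames(gt$centroids))
    if (!length(fdis)) next
    take <- if (length(fdis) > n_per) sort(sample(fdis, n_per)) else fdis
    for (fdi in take) {
      key <- as.character(fdi)
      # emulate the inference-time skeleton channel: many votes per skeleton
      # voxel, scattered by regression error
      sk <- gt$skeletons[[key]]
      skrep <- sk[rep(seq_len(nrow(sk)), each = 12L), , drop = FALSE] +
               matrix(stats::rnorm(nrow(sk) * 36L, sd = 1), ncol = 3)
      inst <- list(centroid = gt$centroids[key, ] + stats::runif(3, -1, 1),
                   skeleton_voxels = skrep)
      inp <- build_tooth_input(td$v, inst, patch)
      m <- crop_window(td$labels == fdi, inp$window)
      targets <- list(mask = array(as.numeric(m), c(1L, dim(m))))
      if (!no_multitask) {
        arch <- if ((fdi %/% 10L) %in% c(1L, 2L)) "upper" else "lower"
        ba <- derive_boundary_and_apex(td$labels == fdi, arch = arch)
        targets$boundary <- array(crop_window(ba$boundary_map, inp$window), c(1L, dim(m)))
        targets$apex <- array(crop_window(ba$apex_map, inp$window), c(1L, dim(m)))
      }
      out[[length(out) + 1L]] <- list(x = inp$x, targets = targets,
                                      class = fdi_to_class(fdi))
    }
  }
  out
}

# Stage-wise variant: build single-tooth samples from the *predicted*
# first-stage outputs (detected centroids and skeleton votes), with targets
# from the GT tooth best matching each detection. Closes the train/inference
# gap of the skeleton and centroid channels. Falls back to GT-centered crops
# (with emulated vote scatter) when detection fails on a phantom.
tooth_samples_stagewise <- function(datas, first_stage, patch, n_per,
                                    no_multitask = FALSE, use_skeleton = TRUE) {
  out <- list()
  for (td in datas) {
    gt <- td$gt
    if (nrow(gt$centroids) == 0L) next
    det <- try(detect_tooth_instances(td$v, first_stage,
                                      patch = pmin(c(48L, 48L, 48L), dim(td$img)),
                                      use_skeleton = use_skeleton), silent = TRUE)
    samples <- list()
    if (!inherits(det, "try-error")) {
      gtc <- gt$centroids
      for (inst in det$instances) {
        d2 <- colSums((t(gtc) - inst$centroid)^2)
        if (min(d2) > 9) next                       # no GT tooth within 3 voxels
        fdi <- as.integer(rownames(gtc)[which.min(d2)])
        samples[[length(samples) + 1L]] <- list(inst = inst, fdi = fdi)
      }
    }
    if (!length(samples)) {
      # detection failed: GT-centered crops with emulated vote scatter
      for (fdi in as.integer(rownames(gt$centroids))) {
        key <- as.character(fdi)
        sk <- gt$skeletons[[key]]
        skrep <- sk[rep(seq_len(nrow(sk)), each = 12L), , drop = FALSE] +
                 matrix(stats::rnorm(nrow(sk) * 36L, sd = 1), ncol = 3)
        inst <- list(centroid = gt$centroids[key, ] + stats::runif(3, -1, 1),
                     skeleton_voxels = skrep)
        samples[[length(samples) + 1L]] <- list(inst = inst, fdi = fdi)
      }
    }
    if (length(samples) > n_per) samples <- sample(samples, n_per)
    for (sm in samples) {
      inp <- build_tooth_input(td$v, sm$inst, patch, use_skeleton = use_skeleton)
      m <- crop_window(td$labels == sm$fdi, inp$window)
      targets <- list(mask = array(as.numeric(m), c(1L, dim(m))))
      if (!no_multitask) {
        arch <- if ((sm$fdi %/% 10L) %in% c(1L, 2L)) "upper" else "lower"
        ba <- derive_boundary_and_apex(td$labels == sm$fdi, arch = arch)
        targets$boundary <- array(crop_window(ba$boundary_map, inp$window), c(1L, dim(m)))
        targets$apex <- array(crop_window(ba$apex_map, inp$window), c(1L, dim(m)))
      }
      out[[length(out) + 1L]] <- list(x = inp$x, targets = targets,
                                      class = fdi_to_class(sm$fdi))
    }
  }
  out
}

# Samples for the bone networks: (image, enhanced) crops -> one-hot classes.
bone_samples <- function(datas, patch, n_per) {
  out <- list()
  for (td in datas) {
    d <- dim(td$img)
    patch <- pmin(patch, d)
    ctr <- colMeans(mask_coords(td$bones > 0L))
    for (i in seq_len(n_per)) {
      win <- random_window(d, patch, center = ctr, jitter = 6L)
      b <- crop_window(td$bones, win)
      pr <- array(0, c(3L, patch))
      pr[1L, , , ] <- b == 0L
      pr[2L, , , ] <- b == 1L
      pr[3L, , , ] <- b == 2L
      x <- array(0, c(2L, patch))
      x[1L, , , ] <- crop_window(td$img, win)
      x[2L, , , ] <- crop_window(td$haar, win)
      out[[length(out) + 1L]] <- list(x = x, targets = list(prob = pr))
    }
  }
  out
}

# Second-stage cascade samples: append the coarse probabilities predicted by
# the first-stage network to each first-stage sample.
cascade_samples <- function(samples, net1) {
  lapply(samples, function(s) {
    coarse <- predict_patch(net1, s$x)$prob
    x5 <- array(0, c(5L, dim(s$x)[2:4]))
    x5[1:2, , , ] <- s$x
    x5[3:5, , , ] <- coarse
    list(x = x5, targets = s$targets)
  })
}

#' Train the full desk-scale system on synthetic phantoms
#'
#' Builds seeded training/validation samples from the phantom lists and
#' trains the ROI, centroid-offset, skeleton-offset, single-tooth and bone
#' networks with Adam and validation-loss early stopping.
#'
#' @param train_phantoms,val_phantoms lists of `generate_phantom()` outputs.
#' @param opts a [desk_options()].
#' @param train_data,val_data optional precomputed [prepare_training_data()]
#'   outputs for the same phantom lists (lets repeated runs over the same
#'   data, e.g. multiple seeds, skip the preprocessing).
#' @return `list(models, histories, opts)`; `models` plugs directly into
#'   [pipeline_config()].
#' @export
train_dental_system <- function(train_phantoms, val_phantoms, opts = desk_options(),
                                train_data = NULL, val_data = NULL) {
  tdat <- train_data %||% prepare_training_data(train_phantoms, use_haar = !opts$no_haar)
  vdat <- val_data %||% prepare_training_data(val_phantoms, use_haar = !opts$no_haar)
  p <- opts$vol_patch
  tp <- opts$tooth_patch
  histories <- list()

  tc <- function(k, epochs = opts$epochs, lr = opts$learning_rate)
    train_config(learning_rate = lr,
                 patience_epochs = opts$patience_epochs,
                 patience_tolerance = opts$patience_tolerance,
                 max_epochs = epochs,
                 loss_weights = c(offset = 1, class = opts$class_weight),
                 max_grad_norm = 5,
                 seed = opts$seed + k)
  fit <- function(cfg, tr, va, k, epochs = opts$epochs, lr = opts$learning_rate) {
    net <- build_segnet(cfg, seed = opts$seed + k)
    r <- train_model(net, tr, va, tc(k, epochs, lr))
    histories[[length(histories) + 1L]] <<- r$history
    r$net
  }

  mk_samples <- function(builder, k, ...) {
    list(tr = with_seed(opts$seed * 1000L + k, builder(tdat, ...)),
         va = with_seed(opts$seed * 1000L + k + 500L, builder(vdat, ...)))
  }

  s <- mk_samples(roi_samples, 1L, p, opts$crops_per_phantom)
  roi <- fit(net_config(1L, opts$levels, opts$base_channels, p,
                        heads = list(head_spec("mask", 1L, "sigmoid")),
                        convs_per_stage = opts$convs_per_stage),
             s$tr, s$va, 1L)

  s <- mk_samples(offset_samples, 2L, p, opts$crops_per_phantom, "centroid",
                  opts$offset_scale)
  centroid <- fit(net_config(1L, opts$levels, opts$base_channels, p,
                             heads = list(head_spec("offset", 3L, "linear", masked = TRUE),
                                          head_spec("mask", 1L, "sigmoid")),
                             convs_per_stage = opts$convs_per_stage),
                  s$tr, s$va, 2L)
  centroid$offset_scale <- opts$offset_scale

  skeleton <- NULL
  if (!opts$no_skeleton) {
    s <- mk_samples(offset_samples, 3L, p, opts$crops_per_phantom, "skeleton",
                    opts$offset_scale)
    skeleton <- fit(net_config(1L, opts$levels, opts$base_channels, p,
                               heads = list(head_spec("offset", 3L, "linear", masked = TRUE),
                                            head_spec("mask", 1L, "sigmoid")),
                               convs_per_stage = opts$convs_per_stage),
                    s$tr, s$va, 3L)
    skeleton$offset_scale <- opts$offset_scale
  }

  first_stage <- list(roi = roi, centroid = centroid, skeleton = skeleton)
  s <- mk_samples(tooth_samples_stagewise, 4L, first_stage, tp,
                  opts$teeth_per_phantom, opts$no_multitask, !opts$no_skeleton)
  tooth_samples_used <- s
  theads <- list(head_spec("mask", 1L, "sigmoid"))
  if (!opts$no_multitask)
    theads <- c(theads, list(head_spec("boundary", 1L, "sigmoid", loss = "l2"),
                             head_spec("apex", 1L, "sigmoid", loss = "l2")))
  tooth <- fit(net_config(3L, opts$levels, opts$base_channels, tp,
                          heads = theads, classifier = list(n_classes = 32L),
                          convs_per_stage = opts$convs_per_stage),
               s$tr, s$va, 4L, epochs = opts$tooth_epochs)

  bp <- opts$bone_patch
  s <- mk_samples(bone_samples, 5L, bp, opts$crops_per_phantom)
  bone_cfg <- function(cin) net_config(cin, opts$bone_levels, opts$base_channels, bp,
                                       heads = list(head_spec("prob", 3L, "softmax",
                                                              class_weights = opts$bone_class_weights)),
                                       convs_per_stage = opts$convs_per_stage)
  bone1 <- fit(bone_cfg(2L), s$tr, s$va, 5L, lr = opts$bone_learning_rate)
  bone <- list(bone1)
  if (opts$cascade) {
    tr2 <- cascade_samples(s$tr, bone1)
    va2 <- cascade_samples(s$va, bone1)
    bone[[2L]] <- fit(bone_cfg(5L), tr2, va2, 6L, epochs = opts$cascade_epochs,
                      lr = opts$bone_learning_rate)
  }

  list(models = list(roi = roi, centroid = centroid, skeleton = skeleton,
                     tooth = tooth, bone = bone),
       histories = histories, opts = opts,
       tooth_samples = tooth_samples_used)
}

#' Train a single-tooth network from prebuilt samples
#'
#' Used for controlled ablation variants: e.g. retrain the tooth network on
#' exactly the crops the full model saw, with the skeleton channel zeroed.
#'
#' @param samples `list(tr =, va =)` of single-tooth samples (as stored in
#'   `train_dental_system()$tooth_samples`).
#' @param opts a [desk_options()]; `no_skeleton = TRUE` zeroes channel 2.
#' @return a trained tooth predictor.
#' @export
train_tooth_net_from_samples <- function(samples, opts = desk_options()) {
  tr <- samples$tr; va <- samples$va
  if (opts$no_skeleton) {
    zero_ch2 <- function(smp) { smp$x[2L, , , ] <- 0; smp }
    tr <- lapply(tr, zero_ch2)
    va <- lapply(va, zero_ch2)
  }
  theads <- list(head_spec("mask", 1L, "sigmoid"))
  if (!opts$no_multitask)
    theads <- c(theads, list(head_spec("boundary", 1L, "sigmoid", loss = "l2"),
                             head_spec("apex", 1L, "sigmoid", loss = "l2")))
  cfg <- net_config(3L, opts$levels, opts$base_channels, opts$tooth_patch,
                    heads = theads, classifier = list(n_classes = 32L),
                    convs_per_stage = opts$convs_per_stage)
  net <- build_segnet(cfg, seed = opts$seed + 4L)
  tc <- train_config(learning_rate = opts$learning_rate,
                     patience_epochs = opts$patience_epochs,
                     patience_tolerance = opts$patience_tolerance,
                     max_epochs = opts$tooth_epochs,
                     loss_weights = c(offset = 1, class = opts$class_weight),
                     max_grad_norm = 5,
                     seed = opts$seed + 4L)
  train_model(net, tr, va, tc)$net
}

#' Evaluate a trained (or oracle) pipeline on test phantoms
#'
#' Runs the full pipeline per phantom and reports the instance-matched mean
#' tooth Dice, the mean bone Dice over the two bone classes, and the
#' detected/true tooth counts.
#'
#' @param cfg a [pipeline_config()] (models or oracle mode configured).
#' @param phantoms list of `generate_phantom()` outputs.
#' @return data frame, one row per phantom.
#' @export
evaluate_dental_system <- function(cfg, phantoms) {
  rows <- lapply(seq_along(phantoms), function(i) {
    ph <- phantoms[[i]]
    this_cfg <- cfg
    if (!is.null(cfg$oracle_gt)) this_cfg$oracle_gt <- ph$gt
    res <- run_pipeline(ph$image, this_cfg)
    td <- instance_matched_dice(res$instance_ids, ph$gt$tooth_labels)
    be <- evaluate_labels(res$bones, ph$gt$bone_labels)
    bd <- mean(be$dice[be$label %in% c(1L, 2L)])
    data.frame(case = i,
               tooth_dice = td, bone_dice = bd,
               n_teeth_detected = length(res$instances),
               n_teeth_true = nrow(ph$gt$centroids))
  })
  do.call(rbind, rows)
}

#' Retrain only the single-tooth network (ablation variants)
#'
#' Trains a single-tooth segmentation network from the same phantom lists
#' under the given options (e.g. `no_skeleton = TRUE`), reusing nothing from
#' a previous run except the data definition; used to compare ablation
#' variants without retraining the other four networks.
#'
#' @param train_phantoms,val_phantoms lists of `generate_phantom()` outputs.
#' @param opts a [desk_options()].
#' @param train_data,val_data optional precomputed [prepare_training_data()]
#'   outputs (with `use_haar = FALSE`).
#' @param first_stage optional `list(roi, centroid, skeleton)` predictors;
#'   when given, training crops come from their detections (stage-wise
#'   training on predicted inputs) rather than ground-truth centroids.
#' @return a trained tooth predictor.
#' @export
train_tooth_net <- function(train_phantoms, val_phantoms, opts = desk_options(),
                            train_data = NULL, val_data = NULL,
                            first_stage = NULL) {
  tdat <- train_data %||% prepare_training_data(train_phantoms, use_haar = FALSE)
  vdat <- val_data %||% prepare_training_data(val_phantoms, use_haar = FALSE)
  tp <- opts$tooth_patch
  use_sk <- !opts$no_skeleton
  if (!is.null(first_stage)) {
    tr <- with_seed(opts$seed * 1000L + 4L,
                    tooth_samples_stagewise(tdat, first_stage, tp,
                                            opts$teeth_per_phantom,
                                            opts$no_multitask, use_sk))
    va <- with_seed(opts$seed * 1000L + 504L,
                    tooth_samples_stagewise(vdat, first_stage, tp,
                                            opts$teeth_per_phantom,
                                            opts$no_multitask, use_sk))
  } else {
    tr <- with_seed(opts$seed * 1000L + 4L,
                    tooth_samples(tdat, tp, opts$teeth_per_phantom, opts$no_multitask))
    va <- with_seed(opts$seed * 1000L + 504L,
                    tooth_samples(vdat, tp, opts$teeth_per_phantom, opts$no_multitask))
  }
  if (opts$no_skeleton) {
    zero_ch2 <- function(s) { s$x[2L, , , ] <- 0; s }
    tr <- lapply(tr, zero_ch2)
    va <- lapply(va, zero_ch2)
  }
  theads <- list(head_spec("mask", 1L, "sigmoid"))
  if (!opts$no_multitask)
    theads <- c(theads, list(head_spec("boundary", 1L, "sigmoid", loss = "l2"),
                             head_spec("apex", 1L, "sigmoid", loss = "l2")))
  cfg <- net_config(3L, opts$levels, opts$base_channels, tp,
                    heads = theads, classifier = list(n_classes = 32L),
                    convs_per_stage = opts$convs_per_stage)
  net <- build_segnet(cfg, seed = opts$seed + 4L)
  tc <- train_config(learning_rate = opts$learning_rate,
                     patience_epochs = opts$patience_epochs,
                     patience_tolerance = opts$patience_tolerance,
                     max_epochs = opts$tooth_epochs,
                     loss_weights = c(offset = 1, class = opts$class_weight),
                     max_grad_norm = 5,
                     seed = opts$seed + 4L)
  train_model(net, tr, va, tc)$net
}

#' Tooth-branch-only evaluation
#'
#' Instance-matched mean tooth Dice of the tooth branch alone (no bone
#' branch, no fusion) on a list of phantoms; used for ablation comparisons.
#'
#' @param models model list as from [train_dental_system()].
#' @param phantoms list of `generate_phantom()` outputs.
#' @param use_skeleton if `FALSE`, run the skeleton ablation.
#' @param vol_patch,tooth_patch inference patch sizes.
#' @return numeric vector of per-phantom Dice values.
#' @export
evaluate_tooth_branch <- function(models, phantoms, use_skeleton = TRUE,
                                  vol_patch = c(48L, 48L, 48L),
                                  tooth_patch = c(24L, 24L, 24L)) {
  vapply(phantoms, function(ph) {
    v <- clip_normalize(ph$image)
    res <- run_tooth_branch(v, models, patch = pmin(vol_patch, dim(v$voxels)),
                            tooth_patch = tooth_patch,
                            use_skeleton = use_skeleton)
    instance_matched_dice(res$instance_ids, ph$gt$tooth_labels)
  }, 0)
}
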