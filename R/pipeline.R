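#' Training configuration
#'
#' Defaults follow the published training recipe for the full-scale
#' model: Adam with learning rate 0.0005, learning momentum 0.9 (Adam's
#' beta1), weight decay 0.0001, 400 epochs at 256x256. Desk-scale phantom
#' experiments override `epochs`, `input_size` and `batch_size`.
#'
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate,momentum,weight_decay optimizer hyperparameters.
#' @param epochs training epochs.
#' @param input_size image side length.
#' @param label_fraction fraction of training samples whose labels are
#'   used (the semi-supervision dial; 0 = fully unsupervised).
#' @param batch_size minibatch size.
#' @param alpha weight of the supervised loss term.
#' @param v area-penalty weight of the unsupervised loss.
#' @param warmup_epochs initial epochs in which the membership map is
#'   regressed toward the normalized image instead of descending the
#'   region energy. This is the network-training analogue of the
#'   image-based initialization of [chan_vese_segment()]: the region
#'   energy has an empty-region local optimum, and a start uncorrelated
#'   (or anti-correlated) with the image can collapse into it; one
#'   warm-up epoch breaks the symmetry toward bright-equals-foreground.
#' @param seed seed controlling batching order.
#' @return a `train_config` list.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 5e-4,
                         momentum = 0.9, weight_decay = 1e-4,
                         epochs = 400L, input_size = 256L,
                         label_fraction = 0.37, batch_size = 10L,
                         alpha = 0.4, v = 0.004, warmup_epochs = 1L,
                         seed = 1L) {
  stopifnot(identical(optimizer, "adam"),
            label_fraction >= 0, label_fraction <= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Patient-grouped train/test split
#'
#' Randomly assigns whole patients to the training or test side so that
#' no patient's samples (including augmented copies) straddle the split;
#' the training share is the achievable count nearest
#' `train_fraction`. A seeded uniform draw then marks `label_fraction`
#' of the label-bearing training samples as labeled.
#'
#' @param manifest data frame with columns `sample_id`, `patient` and
#'   `has_label`.
#' @param train_fraction target training share (default 0.7).
#' @param label_fraction fraction of training samples used with labels.
#' @param seed RNG seed.
#' @return a `split_plan` list: `train_ids`, `test_ids`,
#'   `labeled_train_ids`, `grouping_key`.
#' @export
make_split <- function(manifest, train_fraction = 0.7, label_fraction = 0.37,
                       seed = 1L) {
  stopifnot(all(c("sample_id", "patient") %in% names(manifest)))
  n <- nrow(manifest)
  with_seed(seed, {
    patients <- unique(manifest$patient)
    patients <- sample(patients)
    counts <- vapply(patients, function(p) sum(manifest$patient == p),
                     integer(1))
    cum <- cumsum(counts)
    target <- train_fraction * n
    k <- which.min(abs(cum - target))
    if (max(counts) > n - cum[k] && max(counts) > cum[k])
      warning("a single patient dominates the dataset; best-effort split")
    train_pat <- patients[seq_len(k)]
    train_ids <- manifest$sample_id[manifest$patient %in% train_pat]
    test_ids <- setdiff(manifest$sample_id, train_ids)
    has_lab <- if ("has_label" %in% names(manifest))
      manifest$sample_id[manifest$has_label] else manifest$sample_id
    pool <- intersect(train_ids, has_lab)
    n_lab <- round(label_fraction * length(train_ids))
    labeled <- if (n_lab > 0) sample(pool, min(n_lab, length(pool)))
    else character(0)
    structure(list(train_ids = train_ids, test_ids = test_ids,
                   labeled_train_ids = labeled, grouping_key = "patient",
                   train_fraction = train_fraction,
                   label_fraction = label_fraction, seed = seed),
              class = "split_plan")
  })
}

samples_by_id <- function(samples) {
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  names(samples) <- ids
  samples
}

stack_images <- function(samples, ids) {
  imgs <- lapply(ids, function(id) samples[[id]]$image)
  S <- nrow(imgs[[1]])
  array(unlist(imgs), c(S, S, 1L, length(ids)))
}

#' Semi-supervised training
#'
#' Minimizes the combined loss over minibatches: every sample contributes
#' the unsupervised Chan-Vese region energy; samples in
#' `split$labeled_train_ids` additionally contribute `alpha` times the
#' supervised label-guided term. Losses are averaged per pixel and per
#' batch for scale stability; gradients flow through the logistic pixel
#' classifier into the recurrent extractor. Fully seeded and
#' deterministic on CPU.
#'
#' @param model a `seg_model` (modified in place and returned).
#' @param samples list of samples with `$sample_id`, `$image` (normalized
#'   matrix) and `$truth` (a [lesion_mask]; required for labeled ids).
#' @param split a `split_plan`.
#' @param cfg a [train_config].
#' @param validate_each evaluate test DSC every this many epochs
#'   (0 = never).
#' @return list with `model` and `history` (data frame per epoch:
#'   `loss`, `l_U`, `l_S`, and `val_dsc` when computed).
#' @export
train_semisupervised <- function(model, samples, split, cfg = train_config(),
                                 validate_each = 0L) {
  samples <- samples_by_id(samples)
  train_ids <- split$train_ids
  labeled <- split$labeled_train_ids
  if (!all(labeled %in% train_ids))
    stop_fmt("labeled_train_ids must be a subset of train_ids")
  S <- cfg$input_size
  npix <- S * S
  opt <- nn_adam(list(model$extractor, model$head), lr = cfg$learning_rate,
                 beta1 = cfg$momentum, weight_decay = cfg$weight_decay)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    order_ids <- with_seed(derive_seed(cfg$seed, ep),
                           sample(train_ids))
    ep_lu <- ep_ls <- ep_loss <- 0; n_lab <- 0L
    for (b0 in seq(1L, length(order_ids), by = cfg$batch_size)) {
      ids <- order_ids[b0:min(b0 + cfg$batch_size - 1L, length(order_ids))]
      x <- stack_images(samples, ids)
      nn_zero_grad(list(model$extractor, model$head))
      out <- seg_forward_batch(model, x, train = TRUE)
      mm <- out$membership
      dm <- array(0, dim(mm))
      warmup <- ep <= cfg$warmup_epochs
      for (i in seq_along(ids)) {
        g <- samples[[ids[i]]]$image
        mi <- mm[, , 1L, i]
        lu <- unsupervised_loss(g, mi, cfg$v)
        gr <- if (warmup) 2 * (mi - g) else unsupervised_loss_grad(g, mi, cfg$v)
        if (ids[i] %in% labeled) {
          mu <- as_mask_matrix(samples[[ids[i]]]$truth)
          ls <- supervised_loss(mi, mu)
          if (!warmup) gr <- gr + cfg$alpha * supervised_loss_grad(mi, mu)
          ep_ls <- ep_ls + ls / npix
          n_lab <- n_lab + 1L
          ep_loss <- ep_loss + (lu + cfg$alpha * ls) / npix
        } else {
          ep_loss <- ep_loss + lu / npix
        }
        ep_lu <- ep_lu + lu / npix
        dm[, , 1L, i] <- gr / (npix * length(ids))
      }
      dlogits <- dm * mm * (1 - mm)
      seg_backward_batch(model, dlogits)
      nn_adam_step(opt)
    }
    ep_loss <- ep_loss / length(train_ids)
    if (!is.finite(ep_loss))
      stop_fmt(paste0("divergence: non-finite training loss at epoch %d ",
                      "(l_U = %.4g, l_S = %.4g)"),
               ep, ep_lu, ep_ls)
    row <- data.frame(epoch = ep, loss = ep_loss,
                      l_U = ep_lu / length(train_ids),
                      l_S = if (n_lab > 0) ep_ls / n_lab else 0,
                      val_dsc = NA_real_)
    if (validate_each > 0L && (ep %% validate_each == 0L) &&
        length(split$test_ids)) {
      ev <- evaluate_model(model, samples, split$test_ids)
      row$val_dsc <- ev$mean[["DSC"]]
    }
    hist[[ep]] <- row
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Evaluate a model on a set of samples
#'
#' Deterministic single evaluation: per-image confusion counts at the
#' model's threshold, per-image metrics, and the dataset means (images
#' with undefined CPA or Recall are excluded from those averages).
#'
#' @param model trained `seg_model`.
#' @param samples sample list (as in [train_semisupervised()]).
#' @param ids sample identifiers to evaluate.
#' @param batch forward-pass batch size.
#' @return list with `per_image` (data frame) and `mean` (named vector).
#' @export
evaluate_model <- function(model, samples, ids, batch = 20L) {
  samples <- samples_by_id(samples)
  per <- vector("list", length(ids))
  for (b0 in seq(1L, length(ids), by = batch)) {
    bid <- ids[b0:min(b0 + batch - 1L, length(ids))]
    x <- stack_images(samples, bid)
    out <- seg_forward_batch(model, x, train = FALSE)
    for (i in seq_along(bid)) {
      mi <- out$membership[, , 1L, i]
      pred <- (mi > model$config$threshold) * 1L
      cc <- confusion_counts(pred, samples[[bid[i]]]$truth)
      met <- seg_metrics(cc)
      per[[b0 + i - 1L]] <- data.frame(sample_id = bid[i], t(met))
    }
  }
  per <- do.call(rbind, per)
  list(per_image = per,
       mean = c(DSC = mean(per$DSC),
                CPA = mean(per$CPA, na.rm = TRUE),
                Recall = mean(per$Recall, na.rm = TRUE)))
}

#' Repeated test-set evaluation
#'
#' Runs the trained model on the test set `runs` times and reports the
#' arithmetic mean and standard deviation of each metric across runs
#' (the repeated-runs protocol; with a fully deterministic model the
#' runs coincide and the standard deviation is zero, which is still
#' reported).
#'
#' @param model trained `seg_model`.
#' @param samples sample list (as in [train_semisupervised()]).
#' @param test_ids identifiers of the test samples.
#' @param runs number of repeated runs (default 10).
#' @param seeds optional per-run seeds (re-seeding any stochastic
#'   evaluation-time components).
#' @return list with `mean`, `sd` (named DSC/CPA/Recall) and `per_run`
#'   (one row per run).
#' @export
evaluate_repeated <- function(model, samples, test_ids, runs = 10L,
                              seeds = seq_len(runs)) {
  if (length(test_ids) == 0L) stop_fmt("empty test set")
  per_run <- vector("list", runs)
  for (r in seq_len(runs)) {
    ev <- with_seed(seeds[r], evaluate_model(model, samples, test_ids))
    per_run[[r]] <- data.frame(run = r, t(ev$mean))
  }
  per_run <- do.call(rbind, per_run)
  list(mean = c(DSC = mean(per_run$DSC), CPA = mean(per_run$CPA),
                Recall = mean(per_run$Recall)),
       sd = c(DSC = sd(per_run$DSC), CPA = sd(per_run$CPA),
              Recall = sd(per_run$Recall)),
       per_run = per_run)
}

#' Extract lesion boundary polygons from a segmentation
#'
#' Labels the 8-connected components of the binarized mask, discards
#' those smaller than `min_area` pixels, and traces each remaining
#' component's iso-contour at level 0.5 on the (zero-padded) component
#' indicator, yielding one closed boundary polygon per lesion in pixel
#' coordinates.
#'
#' @param seg a `soft_segmentation` (or a [lesion_mask]).
#' @param min_area minimum component area in pixels (default 4,
#'   suppressing single-pixel noise).
#' @return list of [polygon_label]s (empty for an empty mask).
#' @export
extract_lesion_boundaries <- function(seg, min_area = 4L) {
  mask <- if (inherits(seg, "soft_segmentation")) seg$mask$mask
  else as_mask_matrix(seg)
  lab <- .cpp_label_components(mask == 1L)
  out <- list()
  k <- 0L
  for (id in seq_len(max(lab))) {
    comp <- lab == id
    if (sum(comp) < min_area) next
    H <- nrow(comp); W <- ncol(comp)
    padded <- matrix(0, H + 2L, W + 2L)
    padded[2:(H + 1L), 2:(W + 1L)] <- comp
    cl <- grDevices::contourLines(x = seq(-1L, H), y = seq(-1L, W),
                                  z = padded, levels = 0.5)
    if (length(cl) == 0L) next
    lens <- vapply(cl, function(co) length(co$x), integer(1))
    co <- cl[[which.max(lens)]]
    k <- k + 1L
    out[[k]] <- polygon_label(cbind(x = co$y, y = co$x),
                              lesion_id = sprintf("lesion%02d", k),
                              annotator_id = "model")
  }
  out
}

#' Structure-ablation experiment
#'
#' Trains one model per structural variant on the same data, split and
#' seed set, and tabulates the mean test metrics. The four canonical
#' cases are the plain-convolution baseline (no dilation, no inception,
#' no residual), then adding dilation, inception, and the residual unit.
#'
#' @param variants named list of [model_config]s.
#' @param samples,split,cfg as in [train_semisupervised()].
#' @param seeds integer vector; each variant is trained once per seed
#'   (seeding both weight initialization and batching).
#' @return data frame: one row per variant with mean and sd of test DSC,
#'   CPA and Recall across seeds.
#' @export
run_ablation <- function(variants, samples, split, cfg, seeds = 0:2) {
  rows <- vector("list", length(variants))
  for (vi in seq_along(variants)) {
    mets <- matrix(NA_real_, length(seeds), 3,
                   dimnames = list(NULL, c("DSC", "CPA", "Recall")))
    for (si in seq_along(seeds)) {
      vcfg <- variants[[vi]]
      vcfg$seed <- derive_seed(seeds[si], vi)
      tcfg <- cfg
      tcfg$seed <- derive_seed(seeds[si], 1000L + vi)
      model <- build_model(vcfg)
      fit <- train_semisupervised(model, samples, split, tcfg)
      ev <- evaluate_model(fit$model, samples_by_id(samples),
                           split$test_ids)
      mets[si, ] <- ev$mean
    }
    rows[[vi]] <- data.frame(case = names(variants)[vi],
                             dsc_mean = mean(mets[, 1]),
                             dsc_sd = sd(mets[, 1]),
                             cpa_mean = mean(mets[, 2]),
                             recall_mean = mean(mets[, 3]))
  }
  do.call(rbind, rows)
}

#' Canonical ablation variants
#'
#' @param base a [model_config] taken as the full model; switches are
#'   turned off to form the other cases.
#' @return named list of four configs (`case1` plain ... `case4` full).
#' @export
ablation_variants <- function(base) {
  c1 <- base; c1$use_dilation <- FALSE; c1$use_inception <- FALSE
  c1$use_residual <- FALSE
  c2 <- base; c2$use_inception <- FALSE; c2$use_residual <- FALSE
  c3 <- base; c3$use_residual <- FALSE
  list(case1 = c1, case2 = c2, case3 = c3, case4 = base)
}


#' Label-fraction sweep on phantom data
#'
#' The semi-supervision experiment: for each seed, generates a fresh
#' phantom dataset, fixes one patient-grouped split, and trains one model
#' per label fraction from scratch, evaluating test DSC/CPA/Recall. This
#' is the desk-scale mirror of the clinical finding that segmentation
#' quality grows with the number of labeled samples.
#'
#' @param fractions label fractions to sweep.
#' @param seeds integer seeds; each seed draws its own dataset, split,
#'   initialization and batching streams.
#' @param n_train,n_test dataset sizes (one patient per image).
#' @param epochs training epochs per run.
#' @param image_size phantom side length.
#' @param model_cfg base [model_config] (its seed is overridden per run).
#' @param spec base [phantom_spec] (its seed is overridden per seed).
#' @return data frame with one row per (seed, fraction): DSC, CPA, Recall.
#' @export
run_label_sweep <- function(fractions = c(0, 0.1, 0.37, 0.7),
                            seeds = 0:4, n_train = 200L, n_test = 60L,
                            epochs = 20L, image_size = 64L,
                            model_cfg = model_config(recurrence_t = 1L,
                                                     stage_channels = c(3L, 6L),
                                                     input_size = image_size),
                            spec = phantom_spec(image_size = image_size)) {
  rows <- list()
  n_total <- n_train + n_test
  for (seed in seeds) {
    spec$seed <- derive_seed(seed, 101L)
    ds <- generate_dataset(spec, n_total)
    for (frac in fractions) {
      sp <- make_split(ds$manifest, train_fraction = n_train / n_total,
                       label_fraction = frac, seed = derive_seed(seed, 7L))
      mcfg <- model_cfg
      mcfg$seed <- derive_seed(seed, 31L)
      model <- build_model(mcfg)
      tc <- train_config(epochs = epochs, input_size = image_size,
                         batch_size = 10L, label_fraction = frac,
                         seed = derive_seed(seed, 13L))
      fit <- train_semisupervised(model, ds$samples, sp, tc)
      ev <- evaluate_model(fit$model, ds$samples, sp$test_ids)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = seed, fraction = frac,
                   DSC = ev$mean[["DSC"]], CPA = ev$mean[["CPA"]],
                   Recall = ev$mean[["Recall"]])
    }
  }
  do.call(rbind, rows)
}
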