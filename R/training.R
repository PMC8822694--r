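## Training orchestration: BR detection pre-training, DTI fine-tuning and
## the 3:1 alternating scheme. BR epochs optimize the detection loss
## through the encoder and BR blocks only (DTI blocks and head are never
## touched); DTI epochs optimize binary cross-entropy through every weight.

## ---- dataset preparation ---------------------------------------------------

## One sample per (protein, ligand) binding record.
.br_samples <- function(corpus) {
  key <- paste(corpus$brs$protein_id, corpus$brs$ligand_id, sep = "::")
  seq_ints <- lapply(corpus$proteins, encode_sequence)
  lapply(split(seq_len(nrow(corpus$brs)), key), function(rows) {
    pid <- corpus$brs$protein_id[rows[1L]]
    lid <- corpus$brs$ligand_id[rows[1L]]
    list(protein_id = pid, ligand_id = lid,
         seq_int = seq_ints[[pid]],
         fp = as.numeric(corpus$compounds[lid, ]),
         brs = cbind(start = corpus$brs$start[rows],
                     end = corpus$brs$end[rows]))
  })
}

.dti_samples <- function(corpus) {
  seq_ints <- lapply(corpus$proteins, encode_sequence)
  lapply(seq_len(nrow(corpus$dti)), function(r) {
    pid <- corpus$dti$protein_id[r]
    cid <- corpus$dti$compound_id[r]
    list(protein_id = pid, compound_id = cid,
         seq_int = seq_ints[[pid]],
         fp = as.numeric(corpus$compounds[cid, ]),
         label = corpus$dti$label[r])
  })
}

.ensure_split <- function(data, seed) {
  if (inherits(data, "hots_corpus")) {
    train_validation_split(data, 0.9, seed = seed)
  } else {
    stopifnot(is.list(data), !is.null(data$train), !is.null(data$validation))
    data
  }
}

## ---- epoch runners ---------------------------------------------------------

.run_br_epoch <- function(params, opt, cfg, samples, lr, batch_size,
                          jitter, jitter_iou, clip = 1) {
  idx <- sample.int(length(samples))
  total <- 0
  for (b0 in seq(1L, length(idx), by = batch_size)) {
    batch <- idx[b0:min(b0 + batch_size - 1L, length(idx))]
    ge <- .grad_env()
    lut <- .conv_lut(params, cfg)
    for (s in batch) {
      sm <- samples[[s]]
      brs <- sm$brs
      if (jitter) {
        L <- length(sm$seq_int)
        brs <- t(apply(brs, 1L, jitter_br, protein_length = L,
                       iou_min = jitter_iou))
      }
      fwd <- .hots_fwd(params, cfg, sm$seq_int, sm$fp, mode = "br",
                       train = TRUE, need_cache = TRUE, lut = lut)
      tgt <- encode_targets(brs, fwd$spec, cfg$anchors, cfg$width_eps)
      tgt$valid <- fwd$det$valid
      out <- detection_tensor(fwd$det$c, fwd$det$w, fwd$det$p,
                              valid = fwd$det$valid)
      total <- total + as.numeric(
        br_loss(tgt, out, cfg$lambda_reg, cfg$lambda_conf, cfg$gamma))
      dZ <- .br_loss_grad_z(tgt, out, cfg)
      .hots_bwd(params, cfg, fwd, dZdet = dZ, ge = ge)
    }
    acc <- lapply(ge$get(), function(x) x / length(batch))
    st <- .adam_step(params, acc, opt, lr, clip = clip)
    params <- st$params; opt <- st$state
  }
  list(params = params, opt = opt, loss = total / length(samples))
}

.run_dti_epoch <- function(params, opt, cfg, samples, lr, batch_size,
                           clip = 1, shared_lr_factor = 1) {
  lr_scale <- NULL
  if (shared_lr_factor != 1) {
    shared <- grep("^(dti|comp)", names(params), value = TRUE,
                   invert = TRUE)
    lr_scale <- stats::setNames(rep(shared_lr_factor, length(shared)),
                                shared)
  }
  idx <- sample.int(length(samples))
  total <- 0
  for (b0 in seq(1L, length(idx), by = batch_size)) {
    batch <- idx[b0:min(b0 + batch_size - 1L, length(idx))]
    ge <- .grad_env()
    lut <- .conv_lut(params, cfg)
    for (s in batch) {
      sm <- samples[[s]]
      fwd <- .hots_fwd(params, cfg, sm$seq_int, sm$fp, mode = "dti",
                       train = TRUE, need_cache = TRUE, lut = lut)
      p <- min(max(fwd$p_dti, 1e-7), 1 - 1e-7)
      total <- total - (sm$label * log(p) + (1 - sm$label) * log(1 - p))
      .hots_bwd(params, cfg, fwd, dz_dti = fwd$p_dti - sm$label, ge = ge)
    }
    acc <- lapply(ge$get(), function(x) x / length(batch))
    st <- .adam_step(params, acc, opt, lr, clip = clip,
                     lr_scale = lr_scale)
    params <- st$params; opt <- st$state
  }
  list(params = params, opt = opt, loss = total / length(samples))
}

## Names of every DTI-stage parameter (blocks + head).
.dti_param_names <- function(params, cfg) {
  grep("^(dti)", names(params), value = TRUE)
}

## ---- validation helpers ----------------------------------------------------

.validation_ap <- function(params, cfg, samples, conf_threshold = 0.05) {
  preds <- list(); truths <- list()
  lut <- .conv_lut(params, cfg)
  for (sm in samples) {
    cx <- paste(sm$protein_id, sm$ligand_id, sep = "::")
    fwd <- .hots_fwd(params, cfg, sm$seq_int, sm$fp, mode = "br",
                     train = FALSE, need_cache = FALSE, lut = lut)
    out <- detection_tensor(fwd$det$c, fwd$det$w, fwd$det$p,
                            valid = fwd$det$valid)
    dec <- decode(out, fwd$spec, cfg$anchors, conf_threshold = conf_threshold)
    if (nrow(dec)) {
      dec$complex_id <- cx
      preds[[length(preds) + 1L]] <- dec
    }
    truths[[length(truths) + 1L]] <-
      data.frame(complex_id = cx, start = sm$brs[, 1L], end = sm$brs[, 2L])
  }
  preds <- if (length(preds)) do.call(rbind, preds) else
    data.frame(complex_id = character(), start = numeric(),
               end = numeric(), confidence = numeric())
  truths <- do.call(rbind, truths)
  list(ap = average_precision(preds, truths), predictions = preds,
       truths = truths)
}

.validation_dti <- function(params, cfg, samples) {
  lut <- .conv_lut(params, cfg)
  scores <- vapply(samples, function(sm)
    .hots_fwd(params, cfg, sm$seq_int, sm$fp, mode = "dti",
              train = FALSE, need_cache = FALSE, lut = lut)$p_dti,
    numeric(1L))
  labels <- vapply(samples, `[[`, numeric(1L), "label")
  dti_metrics(scores, labels)
}

## ---- training entry points -------------------------------------------------

#' Pre-train the binding-region detector
#'
#' Trains encoder, BR transformer blocks and detection head with the
#' combined detection loss on (protein, compound, BRs) records. Ground
#' truth is augmented each epoch by IoU-constrained jitter. Validation AP
#' is tracked every epoch and the best-AP weights are kept (early stop
#' after `patience` epochs without improvement).
#'
#' @param data A `hots_corpus` (internally split 9:1 by protein) or a
#'   list with `train` and `validation` corpora.
#' @param cfg A [hots_config()].
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size (small batches, i.e. many Adam
#'   steps per epoch, proved the faster recipe at desk scale).
#' @param lr Adam learning rate.
#' @param clip Global-norm gradient clip.
#' @param patience Early-stopping patience on validation AP.
#' @param jitter,jitter_iou Augment BRs each epoch by [jitter_br()] with
#'   this minimum IoU.
#' @param seed RNG seed for init, shuffling, jitter and dropout.
#' @param model Optionally continue from an existing `hots_model`.
#' @param verbose Print per-epoch progress.
#' @return A `hots_model` with `history` (per-epoch data frame) and the
#'   best-validation-AP weights.
#' @export
pretrain_br <- function(data, cfg = hots_config(), epochs = 30L,
                        batch_size = 8L, lr = 1e-3, clip = 5,
                        patience = 10L, jitter = TRUE, jitter_iou = 0.7,
                        seed = 1L, model = NULL, verbose = FALSE) {
  split <- .ensure_split(data, seed)
  train_samples <- .br_samples(split$train)
  val_samples <- .br_samples(split$validation)
  if (length(train_samples) == 0L) stop("empty BR training dataset")
  set.seed(seed)
  if (is.null(model)) model <- hots_init_model(cfg)
  cfg <- model$cfg
  params <- model$params
  opt <- model$opt %||% .adam_init(params)
  best_ap <- -Inf; best_params <- params; since_best <- 0L
  hist <- list()
  for (ep in seq_len(epochs)) {
    run <- .run_br_epoch(params, opt, cfg, train_samples, lr, batch_size,
                         jitter, jitter_iou, clip)
    params <- run$params; opt <- run$opt
    val_ap <- .validation_ap(params, cfg, val_samples)$ap
    hist[[ep]] <- data.frame(phase = "br_pretrain", epoch = ep,
                             br_loss = run$loss, val_ap = val_ap,
                             dti_loss = NA_real_, val_auroc = NA_real_)
    if (verbose)
      message(sprintf("pretrain epoch %d: loss %.4f, val AP %.3f",
                      ep, run$loss, val_ap))
    if (val_ap > best_ap) {
      best_ap <- val_ap; best_params <- params; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
  }
  structure(list(params = best_params, cfg = cfg, opt = opt,
                 history = do.call(rbind, c(list(model$history), hist)),
                 seed = seed),
            class = "hots_model")
}

#' Alternating BR/DTI fine-tuning
#'
#' Runs cycles of `ratio_br_to_dti` BR epochs followed by one DTI epoch
#' (default 3:1, reflecting the smaller BR dataset). DTI epochs optimize
#' binary cross-entropy on the DTI probability through all weights; BR
#' epochs train the detection loss and leave every DTI-stage weight
#' bit-identical (the per-epoch DTI weight snapshots are kept in
#' `weight_log` so this can be audited). Validation AP and DTI metrics
#' are recorded every cycle.
#'
#' @param model A pre-trained `hots_model`; if `NULL`, training starts
#'   from scratch with a warning.
#' @param data A `hots_corpus` or `train`/`validation` split.
#' @param cycles Number of alternating cycles.
#' @param ratio_br_to_dti BR epochs per DTI epoch (default 3).
#' @param lr_br,lr_dti Adam learning rates for the two phases. The BR
#'   default is a maintenance rate: after pre-training the BR phases only
#'   need to hold detection quality while the DTI phases learn.
#' @param dti_batch_size Minibatch size of the DTI epochs (default 4;
#'   the DTI objective benefits from more optimizer steps per epoch).
#' @param clip Global-norm gradient clip (default 5).
#' @param shared_lr_factor DTI epochs scale the learning rate of weights
#'   outside the DTI stage by this factor (default 0.1). All weights are
#'   still fine-tuned, but discriminative rates stop each DTI epoch from
#'   wrecking the detector the interleaved BR epochs just trained.
#' @param batch_size Minibatch size.
#' @param jitter,jitter_iou BR augmentation (as in [pretrain_br()]).
#' @param seed RNG seed.
#' @param cfg Configuration (only used when starting from scratch).
#' @param keep_best Return the weights of the validation-best state
#'   (highest AP + AUROC, scored after each cycle's BR phase and after
#'   its DTI epoch) rather than the final state. Detection AP typically
#'   dips right after a DTI epoch before recovering, so the final state
#'   can be a poor representative of the trajectory.
#' @param verbose Print progress.
#' @return The fine-tuned `hots_model` with extended `history` and
#'   `weight_log`.
#' @export
finetune_alternating <- function(model, data, cycles = 4L,
                                 ratio_br_to_dti = 3L, lr_br = 3e-4,
                                 lr_dti = 1e-3, batch_size = 8L,
                                 dti_batch_size = 4L, clip = 5,
                                 shared_lr_factor = 0.1,
                                 jitter = TRUE, jitter_iou = 0.7,
                                 seed = 1L, cfg = hots_config(),
                                 keep_best = TRUE, verbose = FALSE) {
  split <- .ensure_split(data, seed)
  set.seed(seed)
  if (is.null(model)) {
    warning("no pre-trained model supplied; starting from scratch")
    model <- hots_init_model(cfg)
  }
  cfg <- model$cfg
  params <- model$params
  ## each phase keeps its own Adam moment estimates: the two objectives'
  ## gradient statistics differ, and sharing state lets one phase wreck
  ## the other's adaptive scales
  opt_br <- model$opt %||% .adam_init(params)
  opt_dti <- .adam_init(params)
  br_train <- .br_samples(split$train)
  br_val <- .br_samples(split$validation)
  dti_train <- .dti_samples(split$train)
  dti_val <- .dti_samples(split$validation)
  if (length(dti_train) == 0L) stop("empty DTI training dataset")
  hist <- list(); wlog <- list()
  dnames <- .dti_param_names(params, cfg)
  best_params <- params; best_score <- -Inf
  score_state <- function(ap, auroc) {
    s <- sum(c(ap, auroc), na.rm = TRUE)
    if (keep_best && s > best_score) {
      best_score <<- s
      best_params <<- params
    }
    invisible(s)
  }
  for (cy in seq_len(cycles)) {
    for (be in seq_len(ratio_br_to_dti)) {
      before <- params[dnames]
      run <- .run_br_epoch(params, opt_br, cfg, br_train, lr_br,
                           batch_size, jitter, jitter_iou, clip)
      params <- run$params; opt_br <- run$opt
      wlog[[length(wlog) + 1L]] <-
        list(cycle = cy, phase = "br", dti_before = before,
             dti_after = params[dnames])
      ## validation metrics at the end of the BR phase: detection AP
      ## recovers here from the dip a DTI epoch induces, so this state is
      ## a checkpoint candidate alongside the cycle end
      last_br <- be == ratio_br_to_dti
      mid_ap <- if (last_br && length(br_val))
        .validation_ap(params, cfg, br_val)$ap else NA_real_
      mid_m <- if (last_br && length(dti_val))
        .validation_dti(params, cfg, dti_val) else NULL
      if (last_br)
        score_state(mid_ap, if (is.null(mid_m)) NA_real_ else mid_m$auroc)
      hist[[length(hist) + 1L]] <-
        data.frame(phase = "finetune_br", epoch = length(hist) + 1L,
                   br_loss = run$loss, val_ap = mid_ap,
                   dti_loss = NA_real_,
                   val_auroc = if (is.null(mid_m)) NA_real_
                               else mid_m$auroc)
    }
    run <- .run_dti_epoch(params, opt_dti, cfg, dti_train, lr_dti,
                          dti_batch_size, clip, shared_lr_factor)
    params <- run$params; opt_dti <- run$opt
    val_ap <- if (length(br_val)) .validation_ap(params, cfg, br_val)$ap
              else NA_real_
    val_m <- if (length(dti_val)) .validation_dti(params, cfg, dti_val)
             else NULL
    score_state(val_ap, if (is.null(val_m)) NA_real_ else val_m$auroc)
    hist[[length(hist) + 1L]] <-
      data.frame(phase = "finetune_dti", epoch = length(hist) + 1L,
                 br_loss = NA_real_, val_ap = val_ap,
                 dti_loss = run$loss,
                 val_auroc = if (is.null(val_m)) NA_real_ else val_m$auroc)
    if (verbose)
      message(sprintf("cycle %d: DTI loss %.4f, val AP %.3f, val AUROC %s",
                      cy, run$loss, val_ap,
                      if (is.null(val_m)) "NA" else sprintf("%.3f",
                                                            val_m$auroc)))
  }
  structure(list(params = if (keep_best) best_params else params,
                 cfg = cfg, opt = opt_br,
                 history = do.call(rbind, c(list(model$history), hist)),
                 weight_log = wlog, seed = seed),
            class = "hots_model")
}

#' Train a DTI-only model (no binding-region training)
#'
#' Ablation baseline: the same architecture trained from scratch with the
#' DTI objective only.
#'
#' @inheritParams finetune_alternating
#' @param epochs Number of DTI epochs.
#' @param lr Adam learning rate.
#' @return A `hots_model`.
#' @export
train_dti_only <- function(data, cfg = hots_config(), epochs = 5L,
                           batch_size = 4L, lr = 1e-3, clip = 5, seed = 1L,
                           verbose = FALSE) {
  split <- .ensure_split(data, seed)
  set.seed(seed)
  model <- hots_init_model(cfg)
  params <- model$params
  opt <- .adam_init(params)
  dti_train <- .dti_samples(split$train)
  dti_val <- .dti_samples(split$validation)
  hist <- list()
  for (ep in seq_len(epochs)) {
    run <- .run_dti_epoch(params, opt, cfg, dti_train, lr, batch_size,
                          clip)
    params <- run$params; opt <- run$opt
    val_m <- if (length(dti_val)) .validation_dti(params, cfg, dti_val)
             else NULL
    hist[[ep]] <- data.frame(phase = "dti_only", epoch = ep,
                             br_loss = NA_real_, val_ap = NA_real_,
                             dti_loss = run$loss,
                             val_auroc = if (is.null(val_m)) NA_real_
                                         else val_m$auroc)
    if (verbose)
      message(sprintf("dti-only epoch %d: loss %.4f", ep, run$loss))
  }
  structure(list(params = params, cfg = cfg, opt = opt,
                 history = do.call(rbind, hist), seed = seed),
            class = "hots_model")
}

## ---- prediction and evaluation wrappers ------------------------------------

#' Predict binding regions for protein-compound pairs
#'
#' @param model A trained `hots_model`.
#' @param corpus A `hots_corpus` (pairs taken from its binding records) or
#'   a list with `proteins`, `compounds` and a `pairs` data frame
#'   (`protein_id`, `ligand_id`).
#' @param conf_threshold Minimum decoded confidence.
#' @param nms_iou,nms Non-maximum suppression settings.
#' @return Data frame of decoded predictions with `protein_id`,
#'   `ligand_id`, `complex_id` and the [decode()] columns.
#' @export
predict_brs <- function(model, corpus, conf_threshold = 0.05,
                        nms_iou = 0.5, nms = TRUE) {
  stopifnot(inherits(model, "hots_model"))
  samples <- if (inherits(corpus, "hots_corpus")) .br_samples(corpus) else {
    lapply(seq_len(nrow(corpus$pairs)), function(r) {
      pid <- corpus$pairs$protein_id[r]; lid <- corpus$pairs$ligand_id[r]
      list(protein_id = pid, ligand_id = lid,
           seq_int = encode_sequence(corpus$proteins[[pid]]),
           fp = as.numeric(corpus$compounds[lid, ]), brs = NULL)
    })
  }
  rows <- lapply(samples, function(sm) {
    fwd <- .hots_fwd(model$params, model$cfg, sm$seq_int, sm$fp,
                     mode = "br", train = FALSE, need_cache = FALSE)
    out <- detection_tensor(fwd$det$c, fwd$det$w, fwd$det$p,
                            valid = fwd$det$valid)
    dec <- decode(out, fwd$spec, model$cfg$anchors, conf_threshold,
                  nms_iou, nms)
    if (nrow(dec) == 0L) return(NULL)
    cbind(data.frame(protein_id = sm$protein_id, ligand_id = sm$ligand_id,
                     complex_id = paste(sm$protein_id, sm$ligand_id,
                                        sep = "::")),
          dec)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), ligand_id = character(),
                      complex_id = character(), start = numeric(),
                      end = numeric(), center = numeric(), width = numeric(),
                      confidence = numeric(), grid = integer(),
                      anchor = integer())
  rownames(out) <- NULL
  out
}

#' Predict DTI probabilities
#'
#' @param model A trained `hots_model`.
#' @param corpus A `hots_corpus` (pairs from its `dti` table) or list with
#'   `proteins`, `compounds`, `pairs` (`protein_id`, `compound_id`).
#' @return Data frame `compound_id`, `protein_id`, `p_dti` (+ `label` when
#'   available).
#' @export
predict_dti <- function(model, corpus) {
  stopifnot(inherits(model, "hots_model"))
  if (inherits(corpus, "hots_corpus")) {
    samples <- .dti_samples(corpus)
  } else {
    samples <- lapply(seq_len(nrow(corpus$pairs)), function(r) {
      pid <- corpus$pairs$protein_id[r]
      cid <- corpus$pairs$compound_id[r]
      list(protein_id = pid, compound_id = cid,
           seq_int = encode_sequence(corpus$proteins[[pid]]),
           fp = as.numeric(corpus$compounds[cid, ]), label = NA_real_)
    })
  }
  data.frame(
    compound_id = vapply(samples, `[[`, character(1L), "compound_id"),
    protein_id = vapply(samples, `[[`, character(1L), "protein_id"),
    p_dti = vapply(samples, function(sm)
      .hots_fwd(model$params, model$cfg, sm$seq_int, sm$fp, mode = "dti",
                train = FALSE, need_cache = FALSE)$p_dti, numeric(1L)),
    label = vapply(samples, `[[`, numeric(1L), "label"))
}

#' Evaluate binding-region detection on a corpus
#'
#' @param model A trained `hots_model`.
#' @param corpus A `hots_corpus` with ground-truth BRs.
#' @param conf_threshold Decoding confidence floor for the AP prediction
#'   pool.
#' @return List with `ap`, `top_n`, `top_n2` (top-(n+2)), the prediction
#'   pool and truth table.
#' @export
evaluate_br <- function(model, corpus, conf_threshold = 0.05) {
  samples <- .br_samples(corpus)
  va <- .validation_ap(model$params, model$cfg, samples,
                       conf_threshold = conf_threshold)
  list(ap = va$ap,
       top_n = topn_success(va$predictions, va$truths, extra = 0L),
       top_n2 = topn_success(va$predictions, va$truths, extra = 2L),
       predictions = va$predictions, truths = va$truths)
}

#' Evaluate DTI classification on a corpus
#'
#' @param model A trained `hots_model`.
#' @param corpus A `hots_corpus` with a labelled `dti` table.
#' @return [dti_metrics()] output.
#' @export
evaluate_dti <- function(model, corpus) {
  pred <- predict_dti(model, corpus)
  dti_metrics(pred$p_dti, pred$label)
}
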