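# Few-shot training protocol: pre-training on simulated acquisitions and
# fine-tuning on a small number of measured slabs, with L1 + SSIM loss,
# Adam, per-load Poisson-disc mask randomisation and validation-based early
# stopping.

#' Training configuration
#'
#' Defaults follow the published protocol: 50 epochs per acceleration
#' factor, Adam with learning rate 3e-4, L1 + SSIM loss (unit weights) and
#' validation-based early stopping (patience 5 is this package's default;
#' only "validation-based early stopping" is prescribed).
#'
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param w_l1,w_ssim loss weights.
#' @param R fixed acceleration factor for the run.
#' @param pf_fraction omitted readout partial-Fourier fraction.
#' @param calib calibration block `(cy, cz)`.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param seed master seed: every per-epoch, per-item mask draw is derived
#'   from it.
#' @param val_hook optional `function(epoch, loss)` returning a (possibly
#'   modified) validation loss; used to inject schedules in tests.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50, lr = 3e-4, w_l1 = 1, w_ssim = 1,
                         R = 4, pf_fraction = 0, calib = c(12, 6),
                         early_stop_patience = 5, seed = 1L,
                         val_hook = NULL) {
  assert_that(lr > 0 && epochs >= 1, "lr must be > 0 and epochs >= 1",
              "tofrecon_invalid_config")
  structure(list(epochs = as.integer(epochs), lr = lr, w_l1 = w_l1,
                 w_ssim = w_ssim, R = R, pf_fraction = pf_fraction,
                 calib = as.integer(calib),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), val_hook = val_hook),
            class = "train_config")
}

#' L1 + SSIM loss
#'
#' `w_l1 * mean(|pred - target|) + w_ssim * (1 - SSIM(pred, target))` with
#' the package SSIM convention (uniform 7-wide window, dynamic range from the
#' target). Non-negative, zero iff `pred == target`.
#'
#' @param pred,target same-shaped non-negative arrays.
#' @param weights length-2 `(w_l1, w_ssim)`.
#' @return scalar loss.
#' @export
loss_l1_ssim <- function(pred, target, weights = c(1, 1)) {
  weights[1] * mean(abs(pred - target)) +
    weights[2] * (1 - ssim3d(pred, target))
}

# loss + analytic gradient wrt pred (verified against finite differences)
loss_l1_ssim_grad <- function(pred, target, weights = c(1, 1), window = 7L) {
  n <- length(pred)
  L <- max(target)
  parts <- ssim_parts(pred, target, window, 0.01, 0.03, L)
  val <- weights[1] * mean(abs(pred - target)) +
    weights[2] * (1 - mean(parts$S))
  g <- -weights[2] / n # dL/dS at every map pixel
  with(parts, {
    dmx <- g * (2 * my * A2 / (B1 * B2) - 2 * mx * S / B1)
    dsxx <- g * (-S / B2)
    dsxy <- g * (2 * A1 / (B1 * B2))
    grad <- box_mean(dmx, window, adjoint = TRUE) +
      2 * pred * box_mean(dsxx, window, adjoint = TRUE) -
      2 * box_mean(dsxx * mx, window, adjoint = TRUE) +
      target * box_mean(dsxy, window, adjoint = TRUE) -
      box_mean(dsxy * my, window, adjoint = TRUE)
    grad <- grad + weights[1] * sign(pred - target) / n
    list(value = val, grad = grad)
  })
}

# ---- Adam ---------------------------------------------------------------------

adam_init <- function(envs) {
  lapply(envs, function(p) list(mW = 0 * p$W, vW = 0 * p$W,
                                mb = if (!is.null(p$bshape)) 0 * p$b,
                                vb = if (!is.null(p$bshape)) 0 * p$b))
}

adam_step <- function(envs, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(envs)) {
    p <- envs[[i]]; s <- state[[i]]
    if (is.null(p$gW)) next
    g <- array(p$gW, dim(p$W))
    s$mW <- beta1 * s$mW + (1 - beta1) * g
    s$vW <- beta2 * s$vW + (1 - beta2) * g^2
    p$W <- p$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    if (!is.null(p$bshape) && !is.null(p$gb)) {
      s$mb <- beta1 * s$mb + (1 - beta1) * p$gb
      s$vb <- beta2 * s$vb + (1 - beta2) * p$gb^2
      p$b <- p$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    }
    state[[i]] <- s
  }
  state
}

# ---- dataset plumbing -----------------------------------------------------------

split_train_val <- function(dataset) {
  if (!is.null(dataset$train)) {
    list(train = dataset$train, val = dataset$val)
  } else {
    assert_that(length(dataset) >= 2,
                "need >= 2 acquisitions (>= 1 train, >= 1 validation)",
                "tofrecon_invalid_config")
    list(train = dataset[-length(dataset)],
         val = dataset[length(dataset)])
  }
}

# fresh mask for an item: Poisson-disc (seeded) x fixed readout PF
draw_item_mask <- function(acq, cfg, tag, item, epoch) {
  d <- dim(acq$kspace)
  pe <- if (cfg$R > 1) {
    make_poisson_mask(d[3], d[4], cfg$R, cfg$calib,
                      seed = derive_seed(cfg$seed, paste0(tag, "-", item),
                                         epoch))$pe_mask
  } else matrix(1L, d[3], d[4])
  sampling_mask(pe, make_pf_mask(d[2], cfg$pf_fraction), cfg$calib, cfg$R)
}

# normalise so the zero-filled RSS max is 1; returns inputs for one step
prepare_item <- function(acq, msk) {
  und <- undersample(acq, msk)
  zf <- zero_fill_recon(und$kspace)
  scale <- max(zf)
  list(k = und$kspace / scale, mask = msk,
       target = Mod(acq$truth_image) / scale, scale = scale)
}

eval_loss <- function(model, items, cfg, tag) {
  tot <- 0
  for (i in seq_along(items)) {
    msk <- draw_item_mask(items[[i]], cfg, tag, i, 0L)
    it <- prepare_item(items[[i]], msk)
    out <- varnet_apply(model, it$k, it$mask)$out
    tot <- tot + loss_l1_ssim(out, it$target, c(cfg$w_l1, cfg$w_ssim))
  }
  tot / length(items)
}

# ---- training loops --------------------------------------------------------------

train_loop <- function(model, train_items, val_items, cfg,
                       epoch0_val = FALSE) {
  envs <- varnet_param_envs(model)
  state <- adam_init(envs)
  history <- data.frame(epoch = integer(), train_loss = double(),
                        val_loss = double())
  best <- list(loss = Inf, weights = get_weights(model), epoch = 0L)
  if (epoch0_val) {
    v0 <- eval_loss(model, val_items, cfg, "valmask")
    history <- rbind(history, data.frame(epoch = 0L, train_loss = NA_real_,
                                         val_loss = v0))
    best <- list(loss = v0, weights = get_weights(model), epoch = 0L)
  }
  t_step <- 0L
  stall <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    tr <- 0
    for (i in seq_along(train_items)) {
      msk <- draw_item_mask(train_items[[i]], cfg, "mask", i, epoch)
      it <- prepare_item(train_items[[i]], msk)
      zero_grads(envs)
      r <- varnet_apply(model, it$k, it$mask, with_tape = TRUE)
      lg <- loss_l1_ssim_grad(r$out, it$target, c(cfg$w_l1, cfg$w_ssim))
      if (!is.finite(lg$value))
        abort(sprintf("training diverged (NaN loss) at epoch %d", epoch),
              "tofrecon_divergence")
      varnet_backward(model, r$tape, lg$grad)
      t_step <- t_step + 1L
      state <- adam_step(envs, state, cfg$lr, t_step)
      tr <- tr + lg$value
    }
    vl <- eval_loss(model, val_items, cfg, "valmask")
    if (!is.null(cfg$val_hook)) vl <- cfg$val_hook(epoch, vl)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tr / length(train_items),
                                         val_loss = vl))
    if (vl < best$loss) {
      best <- list(loss = vl, weights = get_weights(model), epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
  }
  list(best = best, history = history)
}

new_checkpoint <- function(model, best, history, cfg) {
  structure(list(weights = best$weights, model_cfg = model$cfg,
                 train_cfg = cfg, best_val_loss = best$loss,
                 epoch = best$epoch, history = history,
                 init_seed = model$init_seed,
                 normalization = "zero-filled RSS max scaled to 1 per item"),
            class = "tofrecon_checkpoint")
}

#' Pre-train a variational network on simulated acquisitions
#'
#' Per epoch and per item a FRESH Poisson-disc mask is drawn (seeded from
#' `cfg$seed`, the item index and the epoch, so reruns are bit-identical),
#' the acquisition is undersampled and normalised (zero-filled RSS max = 1),
#' and one Adam step on the L1 + SSIM loss against the ground-truth magnitude
#' is taken. Validation loss (fixed seeded masks) drives early stopping; the
#' best-validation weights are returned.
#'
#' @param model a `varnet_model` with initialised weights.
#' @param dataset either `list(train = ..., val = ...)` of
#'   [simulated_acquisition()]s (fully sampled, with `truth_image`), or a
#'   plain list whose last element becomes the validation item.
#' @param cfg a [train_config()].
#' @return object of class `tofrecon_checkpoint` with fields `weights`,
#'   `model_cfg`, `train_cfg`, `best_val_loss`, `epoch`, `history` (the
#'   per-epoch train/validation loss curve).
#' @export
pretrain <- function(model, dataset, cfg = train_config()) {
  stopifnot(inherits(model, "varnet_model"), inherits(cfg, "train_config"))
  ds <- split_train_val(dataset)
  res <- train_loop(model, ds$train, ds$val, cfg)
  set_weights(model, res$best$weights)
  new_checkpoint(model, res$best, res$history, cfg)
}

#' Fine-tune from a checkpoint on a small dataset
#'
#' Identical loop to [pretrain()], warm-started from the checkpoint weights
#' (all layers are trainable). The epoch-0 row of the returned history is the
#' validation loss of the unmodified checkpoint on the new data, and the
#' returned checkpoint is never worse than that initial value on the
#' validation items.
#'
#' @param checkpoint a `tofrecon_checkpoint`.
#' @param dataset as in [pretrain()]; at least one training and one
#'   validation item.
#' @param cfg a [train_config()].
#' @param model optional pre-built model matching the checkpoint (rebuilt
#'   from `checkpoint$model_cfg` when NULL).
#' @return a `tofrecon_checkpoint`.
#' @export
finetune <- function(checkpoint, dataset, cfg = train_config(),
                     model = NULL) {
  stopifnot(inherits(checkpoint, "tofrecon_checkpoint"))
  if (is.null(model)) model <- build_model(checkpoint$model_cfg)
  set_weights(model, checkpoint$weights) # errors on architecture mismatch
  ds <- split_train_val(dataset)
  res <- train_loop(model, ds$train, ds$val, cfg, epoch0_val = TRUE)
  set_weights(model, res$best$weights)
  new_checkpoint(model, res$best, res$history, cfg)
}

#' Save / load a checkpoint
#'
#' Checkpoints bundle the best weights, the architecture and training
#' configurations, the initialisation seed, the normalisation convention and
#' the loss history.
#'
#' @param checkpoint a `tofrecon_checkpoint`.
#' @param path file path (`.rds`).
#' @return `path` invisibly / the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "tofrecon_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "tofrecon_checkpoint"))
  ck
}

#' Instantiate the model stored in a checkpoint
#'
#' @param checkpoint a `tofrecon_checkpoint`.
#' @return a `varnet_model` carrying the checkpoint weights.
#' @export
checkpoint_model <- function(checkpoint) {
  model <- build_model(checkpoint$model_cfg)
  set_weights(model, checkpoint$weights)
  model
}
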