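# Training loop: Adam, mini-batch size 1 by default, early stopping when the
# best validation loss has not improved for `patience_epochs` epochs.

#' Early-stopping epoch under the patience rule
#'
#' Given a sequence of per-epoch validation losses, returns the 1-based epoch
#' after which training stops: the first epoch at which the running best loss
#' has not improved by more than `tolerance` for `patience` consecutive
#' epochs. Returns `length(val_losses)` if the rule never fires.
#'
#' @param val_losses numeric vector of validation losses, one per epoch.
#' @param patience consecutive non-improving epochs required (default 5).
#' @param tolerance minimum decrease that counts as an improvement.
#' @return integer stopping epoch.
#' @export
early_stop_epoch <- function(val_losses, patience = 5L, tolerance = 0) {
  best <- Inf
  streak <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - tolerance) {
      best <- val_losses[e]
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= patience) return(e)
    }
  }
  length(val_losses)
}

# One forward/backward pass for a sample; returns loss value and gradients.
train_step_grads <- function(net, sample, cfg) {
  fwd <- net_forward(net, sample$x, need_cache = TRUE)
  grad_heads <- list()
  total <- 0
  for (spec in net$cfg$heads) {
    nm <- spec$name
    y <- sample$targets[[nm]]
    if (is.null(y)) next
    hl <- head_loss(spec, fwd$heads[[nm]]$pre, fwd$heads[[nm]]$act, y,
                    sample$mask, want_grad = TRUE)
    w <- head_weight(cfg, nm)
    grad_heads[[nm]] <- w * hl$grad
    total <- total + w * hl$loss
  }
  grad_logits <- NULL
  if (!is.null(fwd$logits) && !is.null(sample$class)) {
    pr <- exp(fwd$logits - max(fwd$logits))
    pr <- pr / sum(pr)
    onehot <- numeric(length(pr)); onehot[sample$class] <- 1
    w <- head_weight(cfg, "class")
    grad_logits <- w * (pr - onehot)
    total <- total + w * -log(pmax(pr[sample$class], EPS_P))
  }
  grads <- net_backward(net, fwd, grad_heads, grad_logits)
  list(loss = total, grads = grads)
}

# Validation loss of a sample (no gradients).
sample_loss <- function(net, sample, cfg) {
  fwd <- net_forward(net, sample$x, need_cache = FALSE)
  pred <- lapply(fwd$heads, `[[`, "act")
  pred$logits <- fwd$logits
  compute_losses(pred, c(sample$targets, list(class = sample$class)),
                 sample$mask, net$cfg$heads, cfg)$total
}

#' Train a network predictor
#'
#' Adam optimization at `cfg$learning_rate` with mini-batches of
#' `cfg$batch_size` samples. After each epoch the mean validation loss is
#' appended to the history; training stops when the best validation loss has
#' not improved by more than `cfg$patience_tolerance` for
#' `cfg$patience_epochs` consecutive epochs, or at `cfg$max_epochs`. The
#' snapshot with the best validation loss is returned. All randomness (data
#' order) is driven by `cfg$seed`.
#'
#' @param net a predictor from [build_segnet()].
#' @param train_set,val_set lists of samples; each sample is
#'   `list(x, targets, mask = NULL, class = NULL)` with `x` a
#'   `(C, z, y, x)` array and `targets` named per head.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return `list(net, history)` with `history` a data frame
#'   `(epoch, train_loss, val_loss)`.
#' @export
train_model <- function(net, train_set, val_set, cfg = train_config(), verbose = FALSE) {
  if (length(train_set) == 0L || length(val_set) == 0L)
    stopf("train_model(): train and validation sets must be nonempty")
  with_seed(cfg$seed, {
    state <- adam_init(net$params)
    history <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())
    best_loss <- Inf
    best_params <- net$params
    streak <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(train_set))
      tl <- 0
      acc <- NULL
      nb <- 0L
      for (i in seq_along(ord)) {
        sg <- train_step_grads(net, train_set[[ord[i]]], cfg)
        tl <- tl + sg$loss
        acc <- nested_add(acc, sg$grads)
        nb <- nb + 1L
        if (nb == cfg$batch_size || i == length(ord)) {
          if (nb > 1L) acc <- scale_grads(acc, 1 / nb)
          if (is.finite(cfg$max_grad_norm)) {
            gn <- sqrt(nested_sumsq(acc))
            if (gn > cfg$max_grad_norm) acc <- scale_grads(acc, cfg$max_grad_norm / gn)
          }
          st <- adam_step(net$params, acc, state, cfg$learning_rate)
          net$params <- st$params
          state <- st$state
          acc <- NULL; nb <- 0L
        }
      }
      vl <- mean(vapply(val_set, function(s) sample_loss(net, s, cfg), 0))
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = tl / length(train_set),
                                           val_loss = vl))
      if (verbose) message(sprintf("epoch %d: train %.4f val %.4f", epoch, tl / length(train_set), vl))
      # same rule as early_stop_epoch(), applied incrementally
      if (vl < best_loss - cfg$patience_tolerance) {
        best_loss <- vl
        best_params <- net$params
        streak <- 0L
      } else {
        streak <- streak + 1L
        if (streak >= cfg$patience_epochs) break
      }
    }
    net$params <- best_params
    list(net = net, history = history)
  })
}

scale_grads <- function(g, s) {
  if (is.numeric(g)) return(g * s)
  if (is.list(g)) for (i in seq_along(g)) if (!is.null(g[[i]])) g[[i]] <- scale_grads(g[[i]], s)
  g
}

#' Save / load a model checkpoint (config embedded)
#'
#' @param net a predictor.
#' @param path checkpoint file path.
#' @export
save_model <- function(net, path) {
  saveRDS(list(obj = unclass(net), class = class(net)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  structure(x$obj, class = x$class)
}
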