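# Per-head losses. BCE supervises sigmoid mask heads, L2 the offset /
# boundary / apex heads (offsets averaged over foreground voxels only),
# multi-class cross-entropy the softmax heads and the FDI classifier.

EPS_P <- 1e-7

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam at learning rate
#' 0.001, mini-batch size 1, and early stopping when the validation loss has
#' not improved for 5 consecutive epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size samples per gradient step.
#' @param patience_epochs consecutive non-improving epochs before stopping.
#' @param patience_tolerance minimum decrease of the best validation loss
#'   that counts as an improvement.
#' @param max_epochs hard cap on epochs.
#' @param loss_weights named numeric vector of per-head weights (default 1;
#'   the classifier uses weight `loss_weights["class"]` if present).
#' @param max_grad_norm gradient updates are rescaled so their global L2 norm
#'   never exceeds this (Inf disables clipping); guards small-batch training
#'   against occasional exploding steps.
#' @param seed run seed controlling initialization-independent randomness
#'   (data order).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 1L,
                         patience_epochs = 5L, patience_tolerance = 1e-4,
                         max_epochs = 30L, loss_weights = NULL,
                         max_grad_norm = Inf, seed = 1L) {
  if (patience_epochs < 1L) stopf("train_config(): patience_epochs must be >= 1")
  if (!is.null(loss_weights) && any(loss_weights < 0))
    stopf("train_config(): loss weights must be >= 0")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 patience_epochs = as.integer(patience_epochs),
                 patience_tolerance = patience_tolerance,
                 max_epochs = as.integer(max_epochs),
                 loss_weights = loss_weights, max_grad_norm = max_grad_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

head_weight <- function(cfg, name) {
  w <- cfg$loss_weights
  if (is.null(w) || is.null(w[name]) || is.na(w[name])) 1 else unname(w[name])
}

# Loss (and optionally gradient w.r.t. the head pre-activation) for one head.
head_loss <- function(spec, pre, act, target, mask = NULL, want_grad = FALSE) {
  n <- length(target)
  if (spec$loss == "bce") {
    p <- pmin(pmax(act, EPS_P), 1 - EPS_P)
    loss <- -mean(target * log(p) + (1 - target) * log(1 - p))
    grad <- if (want_grad) (act - target) / n
  } else if (spec$loss == "ce") {
    p <- pmax(act, EPS_P)
    C <- dim(act)[1]
    if (!is.null(spec$class_weights)) {
      # per-voxel weight = weight of the true class (counters background
      # dominance in the 3-class bone task)
      wmap <- colSums(matrix(target * spec$class_weights, nrow = C))
      wrep <- array(rep(wmap, each = C), dim(act))
      wtot <- sum(wmap)
      loss <- -sum(wrep * target * log(p)) / wtot
      grad <- if (want_grad) wrep * (act - target) / wtot
    } else {
      nvox <- n / C
      loss <- -sum(target * log(p)) / nvox
      grad <- if (want_grad) (act - target) / nvox
    }
  } else { # l2
    if (spec$masked) {
      if (is.null(mask) || sum(mask) == 0) {
        loss <- 0
        grad <- if (want_grad) array(0, dim(act))
      } else {
        C <- dim(act)[1]
        mrep <- array(rep(as.numeric(mask), each = C), dim(act))
        nfg <- sum(mrep)
        diff <- (act - target) * mrep
        loss <- sum(diff^2) / nfg
        grad <- if (want_grad) 2 * diff / nfg
      }
    } else {
      diff <- act - target
      loss <- mean(diff^2)
      grad <- if (want_grad) 2 * diff / n
    }
    if (want_grad && spec$activation == "sigmoid") grad <- grad * act * (1 - act)
  }
  list(loss = loss, grad = if (want_grad) grad)
}

#' Per-head losses and weighted total
#'
#' Operates on predicted (activated) maps: binary cross-entropy for sigmoid
#' mask heads, mean squared error for offset/boundary/apex heads (offsets
#' averaged over foreground voxels only; an empty foreground contributes 0),
#' multi-class cross-entropy for softmax heads, and cross-entropy for the
#' optional classifier.
#'
#' @param pred named list of predicted maps (each `(C, z, y, x)` or
#'   `(z, y, x)`), plus optionally `logits`.
#' @param target named list of target maps, plus optionally `class`
#'   (integer class index).
#' @param mask optional binary foreground map for masked offset losses.
#' @param heads list of [head_spec()]s describing the heads present.
#' @param cfg a [train_config()] providing loss weights.
#' @return `list(per_head =, total =)`.
#' @export
compute_losses <- function(pred, target, mask = NULL, heads, cfg = train_config()) {
  out <- list()
  total <- 0
  for (spec in heads) {
    nm <- spec$name
    if (is.null(pred[[nm]]) || is.null(target[[nm]])) next
    p <- pred[[nm]]; y <- target[[nm]]
    if (!identical(dim(p), dim(y)))
      stopf("compute_losses(): shape mismatch for head '%s'", nm)
    hl <- head_loss(spec, NULL, p, y, mask, want_grad = FALSE)
    out[[nm]] <- hl$loss
    total <- total + head_weight(cfg, nm) * hl$loss
  }
  if (!is.null(pred$logits) && !is.null(target$class)) {
    pr <- exp(pred$logits - max(pred$logits))
    pr <- pr / sum(pr)
    cl <- -log(pmax(pr[target$class], EPS_P))
    out[["class"]] <- cl
    total <- total + head_weight(cfg, "class") * cl
  }
  list(per_head = out, total = total)
}

# --- Adam over the nested parameter structure ---------------------------

nested_leaves <- function(x, path = character()) {
  if (is.numeric(x)) return(stats::setNames(list(x), paste(path, collapse = "/")))
  if (is.list(x)) {
    out <- list()
    nm <- names(x) %||% as.character(seq_along(x))
    if (is.null(names(x))) nm <- as.character(seq_along(x))
    for (i in seq_along(x)) {
      if (is.null(x[[i]])) next
      out <- c(out, nested_leaves(x[[i]], c(path, nm[i])))
    }
    return(out)
  }
  list()
}

nested_apply2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  if (is.list(a)) {
    for (i in seq_along(a)) if (!is.null(a[[i]])) a[[i]] <- nested_apply2(a[[i]], b[[i]], f)
    return(a)
  }
  a
}

adam_init <- function(params) {
  zero <- function(x, ...) {
    if (is.numeric(x)) return(x * 0)
    if (is.list(x)) return(lapply(x, zero))
    x
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, m = m, v = v))
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
      return(list(p = p, m = m, v = v))
    }
    if (is.list(p)) {
      for (i in seq_along(p)) {
        if (is.null(p[[i]])) next
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

nested_sumsq <- function(g) {
  if (is.null(g)) return(0)
  if (is.numeric(g)) return(sum(g * g))
  if (is.list(g)) return(sum(vapply(g, nested_sumsq, 0)))
  0
}

nested_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (i in seq_along(b)) a[[i]] <- nested_add(a[[i]], b[[i]])
  a
}
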