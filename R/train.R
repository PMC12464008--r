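#' Training configuration
#'
#' Defaults follow the standard recipe for this segmentation task: 50
#' epochs, batch size 4, 8192 input points, 16 neighbours, Adam with
#' learning rate 0.001 and weight decay 1e-4, learning rate multiplied by
#' 0.7 every `lr_step` epochs.
#'
#' @param max_epoch training epochs.
#' @param batch_size samples per optimizer step.
#' @param num_points fixed input size per sample.
#' @param k grouping neighbourhood size.
#' @param learning_rate initial Adam learning rate.
#' @param decay_rate optimizer weight decay.
#' @param lr_decay multiplicative learning-rate factor.
#' @param lr_step epochs between learning-rate decays.
#' @param seed master seed for shuffling, sampling starts and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epoch = 50L, batch_size = 4L,
                         num_points = 8192L, k = 16L, learning_rate = 0.001,
                         decay_rate = 1e-4, lr_decay = 0.7, lr_step = 10L,
                         seed = 1L) {
  if (max_epoch < 1L || batch_size < 1L || num_points < 1L || k < 1L)
    stop("max_epoch, batch_size, num_points and k must be positive")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  if (decay_rate < 0) stop("decay_rate must be >= 0")
  structure(list(max_epoch = as.integer(max_epoch),
                 batch_size = as.integer(batch_size),
                 num_points = as.integer(num_points), k = as.integer(k),
                 learning_rate = learning_rate, decay_rate = decay_rate,
                 lr_decay = lr_decay, lr_step = as.integer(lr_step),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Class-weighted softmax cross-entropy over points.
# Returns the loss and its gradient w.r.t. the logits.
weighted_cross_entropy <- function(logits, labels, class_weights) {
  n <- nrow(logits)
  mx <- apply(logits, 1, max)
  E <- exp(logits - mx)
  P <- E / rowSums(E)
  ij <- cbind(seq_len(n), labels + 1L)
  w <- class_weights[labels + 1L]
  wsum <- sum(w)
  loss <- -sum(w * log(pmax(P[ij], 1e-12))) / wsum
  dL <- P * (w / wsum)
  dL[ij] <- dL[ij] - w / wsum
  list(loss = loss, dLogits = dL)
}

# Inverse-frequency class weights over a training set.
inverse_frequency_weights <- function(dataset, n_classes) {
  counts <- numeric(n_classes)
  for (s in dataset) {
    tab <- tabulate(s$labels + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  total <- sum(counts)
  w <- ifelse(counts > 0, total / (n_classes * counts), 0)
  w
}

#' Train the segmentation network
#'
#' Minimizes per-point cross-entropy with inverse-frequency class weights
#' by Adam, averaging gradients over each mini-batch; the learning rate is
#' multiplied by `lr_decay` every `lr_step` epochs. The entire run is
#' seeded and reproducible.
#'
#' @param model a [segnet_init()] model.
#' @param dataset list of samples, each a list with `coords`
#'   (`num_points x 3`, normalized) and `labels` (integer 0-based classes).
#' @param config a [train_config()].
#' @param stop_at_oa optional early stop: end training once the epoch
#'   training accuracy (percent) reaches this value.
#' @param verbose print per-epoch progress.
#' @return list: `model` (trained), `history` (data.frame with epoch, loss,
#'   training overall accuracy, learning rate), `class_weights`.
#' @export
train_segnet <- function(model, dataset, config = train_config(),
                         stop_at_oa = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "segnet_model"), inherits(config, "train_config"))
  if (length(dataset) == 0L) stop("empty training dataset")
  for (s in dataset) {
    if (nrow(s$coords) != model$config$num_points)
      stop("every sample must have num_points points")
    if (length(s$labels) != nrow(s$coords))
      stop("labels must align with coords")
  }
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(config$seed)
  cw <- inverse_frequency_weights(dataset, model$config$n_classes)
  state <- adam_init(zero_like(model$params))
  ns <- length(dataset)
  hist <- data.frame(epoch = integer(), loss = numeric(), oa = numeric(),
                     lr = numeric())
  for (epoch in seq_len(config$max_epoch)) {
    lr <- config$learning_rate *
      config$lr_decay^((epoch - 1L) %/% config$lr_step)
    ord <- sample.int(ns)
    ep_loss <- 0
    correct <- 0; total <- 0
    for (b0 in seq(1L, ns, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, ns)]
      gsum <- NULL
      bloss <- 0
      for (i in idx) {
        s <- dataset[[i]]
        fw <- segnet_forward(model, s$coords, training = TRUE,
                             keep_cache = TRUE)
        ce <- weighted_cross_entropy(fw$logits, s$labels, cw)
        g <- segnet_backward(model, fw$cache, ce$dLogits / length(idx))
        gsum <- if (is.null(gsum)) g else leaf_map2(`+`, gsum, g)
        bloss <- bloss + ce$loss / length(idx)
        # training accuracy with dropout off: rerun only the output layer on
        # the cached pre-dropout hidden activations (a 2-column matmul)
        eval_logits <- mlp_forward(model$params$head$out,
                                   fw$cache$hid$out)$out
        pred <- max.col(eval_logits, ties.method = "first") - 1L
        correct <- correct + sum(pred == s$labels)
        total <- total + length(s$labels)
      }
      upd <- adam_step(model$params, gsum, state, lr,
                       weight_decay = config$decay_rate)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bloss * length(idx) / ns
    }
    oa <- 100 * correct / total
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss, oa = oa,
                                   lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train OA %.2f%%  lr %.2g",
                      epoch, ep_loss, oa, lr))
    if (!is.null(stop_at_oa) && oa >= stop_at_oa) break
  }
  list(model = model, history = hist, class_weights = cw)
}

# ---- segmentation metrics --------------------------------------------------

#' Confusion matrix
#'
#' `counts[t, p]` is the number of points of true class `t` predicted as
#' class `p` (0-based labels).
#'
#' @param pred_labels,true_labels equal-length integer vectors with values
#'   in `[0, n_classes)`.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` integer matrix of class
#'   `confusion_matrix`.
#' @export
confusion <- function(pred_labels, true_labels, n_classes = 2L) {
  if (length(pred_labels) != length(true_labels))
    stop("pred_labels and true_labels must have equal length")
  labs <- c(pred_labels, true_labels)
  if (any(labs < 0L | labs >= n_classes))
    stop("labels out of range [0, n_classes)")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1L),
                               pred = 0:(n_classes - 1L)))
  tab <- table(factor(true_labels, levels = 0:(n_classes - 1L)),
               factor(pred_labels, levels = 0:(n_classes - 1L)))
  cm[] <- as.integer(tab)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy (percent)
#'
#' Ratio of correctly classified points to the total, times 100.
#'
#' @param cm a [confusion()] matrix.
#' @return percentage in `[0, 100]`.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Per-class intersection over union (percent)
#'
#' For class `i`: `100 * P_ii / (row_i + col_i - P_ii)`. A class absent
#' from both truth and prediction has undefined IoU and is returned as
#' `NA` (and excluded from [mean_iou()]).
#'
#' @param cm a [confusion()] matrix.
#' @return numeric vector of per-class percentages (NA where undefined).
#' @export
iou_per_class <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  di <- diag(cm)
  denom <- rowSums(cm) + colSums(cm) - di
  ifelse(denom > 0, 100 * di / denom, NA_real_)
}

#' Mean intersection over union (percent)
#'
#' Arithmetic mean of the defined per-class IoU values.
#'
#' @param cm a [confusion()] matrix.
#' @return percentage in `[0, 100]`.
#' @export
mean_iou <- function(cm) {
  iou <- iou_per_class(cm)
  if (all(is.na(iou))) stop("no class has a defined IoU")
  mean(iou, na.rm = TRUE)
}

#' Evaluate a model on a labeled dataset
#'
#' Runs the forward pass on every sample, accumulates one confusion matrix
#' and reports OA, per-class IoU and mIoU.
#'
#' @param model a trained [segnet_init()] model.
#' @param dataset list of samples (`coords` normalized at `num_points`,
#'   `labels`).
#' @param seed seed for the per-sample FPS starts.
#' @return list: `cm`, `oa`, `iou` (per class), `miou`.
#' @export
evaluate_segmentation <- function(model, dataset, seed = 1L) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  cm <- NULL
  for (s in dataset) {
    fw <- segnet_forward(model, s$coords)
    pred <- max.col(fw$logits, ties.method = "first") - 1L
    cmi <- confusion(pred, s$labels, model$config$n_classes)
    cm <- if (is.null(cm)) cmi else cm + cmi
  }
  cm <- structure(cm, class = c("confusion_matrix", "matrix"))
  list(cm = cm, oa = overall_accuracy(cm), iou = iou_per_class(cm),
       miou = mean_iou(cm))
}
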