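# The bifocal convolutional classifier: configuration, seeded parameter
# initialisation, SGD-momentum training with cosine learning-rate decay, and
# batched inference. The numerical core (im2col/GEMM convolutions and the
# full backward pass) lives in src/bcnn.cpp.

#' Configuration for the bifocal classifier
#'
#' Defaults: SGD with learning rate
#' 0.0005 decaying gradually (cosine, to a tenth), momentum 0.9, weight decay
#' 0.005, batch size 32, 70 epochs. Each branch runs three 3x3 conv blocks
#' (ReLU, 2x2 max-pool) with the configured channel widths, global average
#' pooling, then concatenation, one hidden layer and a 2-way softmax.
#'
#' @param channels conv channels per block (length 3).
#' @param hidden width of the post-concatenation hidden layer.
#' @param narrowSize,wideSize branch input edges in pixels (32 and 64).
#' @param learningRate initial SGD learning rate.
#' @param lrFinal final learning rate of the cosine schedule.
#' @param momentum SGD momentum.
#' @param weightDecay L2 weight decay (applied to weight matrices).
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param seed seed for parameter initialisation and batch shuffling.
#' @return a named list of class `bcnnConfig`.
#' @export
bcnnConfig <- function(channels = c(16L, 32L, 64L), hidden = 64L,
                       narrowSize = 32L, wideSize = 64L,
                       learningRate = 5e-4, lrFinal = learningRate / 10,
                       momentum = 0.9, weightDecay = 0.005,
                       batchSize = 32L, epochs = 70L, seed = 1L) {
  if (length(channels) != 3L || any(channels < 1L))
    stop("channels must be three positive widths")
  if (wideSize != 2L * narrowSize)
    stop("wideSize must be twice narrowSize (co-centred bifocal crops)")
  if (narrowSize %% 8L != 0L)
    stop("narrowSize must be divisible by 8 (three 2x2 pooling stages)")
  structure(list(channels = as.integer(channels), hidden = as.integer(hidden),
                 narrowSize = as.integer(narrowSize),
                 wideSize = as.integer(wideSize),
                 learningRate = learningRate, lrFinal = lrFinal,
                 momentum = momentum, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize), epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "bcnnConfig")
}

heInit <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

#' Build a bifocal classifier with seed-deterministic initial parameters
#'
#' @param config a [bcnnConfig()] list.
#' @return an untrained [BCNNModel-class].
#' @export
buildModel <- function(config = bcnnConfig()) {
  if (!inherits(config, "bcnnConfig")) stop("config must come from bcnnConfig()")
  ch <- config$channels
  params <- withSeed(config$seed, {
    p <- list()
    for (pre in c("n", "w")) {
      p[[paste0(pre, "W1")]] <- heInit(ch[1], 9 * 3)
      p[[paste0(pre, "b1")]] <- numeric(ch[1])
      p[[paste0(pre, "W2")]] <- heInit(ch[2], 9 * ch[1])
      p[[paste0(pre, "b2")]] <- numeric(ch[2])
      p[[paste0(pre, "W3")]] <- heInit(ch[3], 9 * ch[2])
      p[[paste0(pre, "b3")]] <- numeric(ch[3])
    }
    p$Wh <- heInit(config$hidden, 2 * ch[3])
    p$bh <- numeric(config$hidden)
    p$Wo <- heInit(2L, config$hidden)
    p$bo <- numeric(2L)
    p
  })
  new("BCNNModel", config = unclass(config), params = params,
      trained = FALSE, history = data.frame())
}

checkPairShapes <- function(model, pairs) {
  dn <- dim(pairs@narrow); dw <- dim(pairs@wide)
  if (dn[1] != model@config$narrowSize || dw[1] != model@config$wideSize)
    stop(sprintf("pair sizes (%d / %d) do not match the model (%d / %d)",
                 dn[1], dw[1], model@config$narrowSize, model@config$wideSize))
}

#' Positive-class scores for a set of bifocal pairs
#'
#' @param model a [BCNNModel-class] (trained or freshly built).
#' @param pairs a [BifocalPatchSet-class].
#' @param batchSize pairs per forward batch (results are independent of it).
#' @return numeric vector of positive-class probabilities, one per pair, in
#'   input order.
#' @export
predictPairs <- function(model, pairs, batchSize = 256L) {
  checkPairShapes(model, pairs)
  n <- length(pairs)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batchSize - 1L)
    probs <- bcnn_forward_cpp(model@params,
                              pairs@narrow[, , , i:j, drop = FALSE],
                              pairs@wide[, , , i:j, drop = FALSE])
    out[i:j] <- probs[, 2]
    i <- j + 1L
  }
  out
}

# Class-balanced, shuffled index order for one epoch (oversamples the
# minority class with replacement so each epoch sees both classes equally).
balancedOrder <- function(labels) {
  pos <- which(labels == "positive")
  neg <- which(labels == "negative")
  m <- max(length(pos), length(neg))
  sample(c(sample(pos, m, replace = length(pos) < m),
           sample(neg, m, replace = length(neg) < m)))
}

#' Train the bifocal classifier
#'
#' Stochastic gradient descent with momentum, L2 weight decay and a cosine
#' learning-rate schedule from `learningRate` down to `lrFinal`. Batches are
#' class-balanced. Training is deterministic given the seed (single-threaded
#' BLAS assumed).
#'
#' @param model an untrained or previously trained [BCNNModel-class].
#' @param pairs labelled [BifocalPatchSet-class]; both classes must be
#'   present.
#' @param valPairs optional held-out labelled pairs for per-epoch metrics.
#' @param epochs,batchSize,learningRate,momentum,weightDecay override the
#'   model's configured regime.
#' @param seed seed for shuffling (defaults to the model seed).
#' @param verbose print one line per epoch.
#' @return the trained model, with a per-epoch `history` data.frame
#'   (`epoch`, `lr`, `loss`, and validation accuracy/AUC when `valPairs` is
#'   given).
#' @export
trainModel <- function(model, pairs, valPairs = NULL,
                       epochs = model@config$epochs,
                       batchSize = model@config$batchSize,
                       learningRate = model@config$learningRate,
                       momentum = model@config$momentum,
                       weightDecay = model@config$weightDecay,
                       seed = model@config$seed, verbose = FALSE) {
  checkPairShapes(model, pairs)
  labs <- pairs@labels
  if (length(pairs) == 0L) stop("training set is empty")
  if (length(unique(labs[!is.na(labs)])) < 2L)
    stop("training set must contain both classes")
  lrFinal <- model@config$lrFinal
  params <- model@params
  vel <- lapply(params, function(p) p * 0)
  y <- as.integer(labs == "positive")
  decayed <- names(params)[grepl("^.W", names(params)) |
                             names(params) %in% c("Wh", "Wo")]
  hist <- vector("list", epochs)

  withSeed(seed, {
    totalSteps <- max(1L, epochs)
    for (ep in seq_len(epochs)) {
      lr <- lrFinal + 0.5 * (learningRate - lrFinal) *
        (1 + cos(pi * (ep - 1) / totalSteps))
      ord <- balancedOrder(labs)
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        j <- min(length(ord), i + batchSize - 1L)
        idx <- ord[i:j]
        g <- bcnn_grad_cpp(params,
                           pairs@narrow[, , , idx, drop = FALSE],
                           pairs@wide[, , , idx, drop = FALSE],
                           y[idx])
        losses <- c(losses, g$loss)
        for (nm in names(params)) {
          grad <- g$grads[[nm]]
          if (nm %in% decayed) grad <- grad + weightDecay * params[[nm]]
          vel[[nm]] <- momentum * vel[[nm]] - lr * grad
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        i <- j + 1L
      }
      row <- data.frame(epoch = ep, lr = lr, loss = mean(losses))
      if (!is.null(valPairs)) {
        sc <- predictPairs(new("BCNNModel", config = model@config,
                               params = params, trained = TRUE,
                               history = data.frame()), valPairs)
        rep <- evaluateScores(sc, valPairs@labels)
        row$val_accuracy <- rep@accuracy
        row$val_auc <- rep@auc
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %d/%d: lr %.2g, loss %.4f%s", ep, epochs, lr,
                        row$loss,
                        if (!is.null(valPairs))
                          sprintf(", val acc %.3f, val AUC %.3f",
                                  row$val_accuracy, row$val_auc) else ""))
    }
  })
  new("BCNNModel", config = model@config, params = params, trained = TRUE,
      history = do.call(rbind, hist))
}

#' Save / load a model as an RDS checkpoint with a JSON config sidecar
#'
#' @param model a [BCNNModel-class].
#' @param path checkpoint path (`.rds`); a `.json` sidecar with the config is
#'   written alongside.
#' @return `path` (save) or the model (load).
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model@config, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
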