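#' Inverse-frequency class weights
#'
#' `w_c = N_total / (C * N_c)`, rescaled to mean 1 so the learning rate is
#' invariant to the weight scale. Balanced counts give unit weights, in
#' which case weighted cross-entropy coincides with the unweighted loss.
#'
#' @param class_counts Named positive integer vector of per-class training
#'   counts.
#' @return Named numeric weights with mean 1.
#' @examples
#' compute_class_weights(c(a = 30, b = 10))  # 0.5, 1.5
#' @export
compute_class_weights <- function(class_counts) {
  if (any(class_counts < 1)) stop("every class count must be >= 1")
  w <- sum(class_counts) / (length(class_counts) * class_counts)
  w / mean(w)
}

#' Weighted cross-entropy loss
#'
#' For a single example with true class `t`: `loss = -w_t * log p_t` with
#' `p` the softmax of the logits. The batched loss used in training is the
#' weight-normalized mean `sum_i w_i nll_i / sum_i w_i`.
#'
#' @param logits Numeric vector of class scores.
#' @param true_class Integer index (1-based) of the true class.
#' @param weights Numeric per-class weights (default uniform).
#' @return Nonnegative scalar loss.
#' @export
weighted_cross_entropy <- function(logits, true_class,
                                   weights = rep(1, length(logits))) {
  if (true_class < 1L || true_class > length(logits)) {
    stop("true_class out of range")
  }
  p <- softmax(logits)
  -weights[true_class] * log(max(p[true_class], 1e-300))
}

#' Training configuration
#'
#' @param num_epochs Number of passes over the training split (default 100).
#' @param batch_size Chunks per gradient step (default 16).
#' @param learning_rate AdamW learning rate (default 1e-4), with linear
#'   warmup over `warmup_frac` of the total steps.
#' @param gradient_accumulation_steps Batches accumulated before each
#'   optimizer step (default 1).
#' @param checkpoint_dir Directory for per-epoch checkpoints (NULL disables
#'   checkpointing).
#' @param seed Integer training seed (shuffling, augmentation, dropout).
#' @param augmentation An [augmentation_config()] applied on the fly to
#'   training sequences only.
#' @param weight_decay AdamW decoupled weight decay on weight matrices
#'   (default 0.01; biases and layer-norm parameters are exempt).
#' @param warmup_frac Fraction of total steps under linear warmup
#'   (default 0.05).
#' @return Object of class `train_config`.
#' @export
train_config <- function(num_epochs = 100L, batch_size = 16L,
                         learning_rate = 1e-4,
                         gradient_accumulation_steps = 1L,
                         checkpoint_dir = NULL, seed = 1L,
                         augmentation = augmentation_config(),
                         weight_decay = 0.01, warmup_frac = 0.05) {
  if (num_epochs < 1L) stop("num_epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(num_epochs = as.integer(num_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 gradient_accumulation_steps =
                   as.integer(gradient_accumulation_steps),
                 checkpoint_dir = checkpoint_dir, seed = as.integer(seed),
                 augmentation = augmentation,
                 weight_decay = weight_decay, warmup_frac = warmup_frac),
            class = "train_config")
}

# ---- AdamW ------------------------------------------------------------------

.adamw_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

# decay applies to true weight matrices only
.decay_param <- function(nm) grepl("(_W|^tok_emb|head_W)", nm) &
  !grepl("ln", nm)

.adamw_step <- function(params, grads, state, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && .decay_param(nm)) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# ---- training loop ----------------------------------------------------------

# tokenize every sequence of a split once (no augmentation); returns a list
# of per-sequence chunk lists
.tokenize_split <- function(seqs, vocab, max_embeddings) {
  lapply(seqs$sequence, function(s) tokenize(s, vocab, max_embeddings))
}

# forward every chunk of one sequence (compiled path) and median-aggregate
# the class probabilities
.predict_sequence_chunks <- function(model, chunks) {
  ids_list <- lapply(chunks, function(ch) ch$ids[seq_len(ch$n)])
  probs <- cpp_predict_probs(model$params, model$config, ids_list)
  aggregate_chunks(probs)
}

.evaluate_split <- function(model, seqs, chunk_lists, class_names) {
  preds <- vapply(chunk_lists, function(chs) {
    which.max(.predict_sequence_chunks(model, chs))
  }, integer(1))
  cm <- confusion_matrix(seqs$label, class_names[preds], class_names)
  metrics_report(cm)
}

#' Train the encoder classifier
#'
#' Each epoch: shuffle the training split, augment every sequence on the
#' fly, tokenize, and take batched AdamW steps on the weighted cross-entropy
#' loss (a multi-chunk sequence contributes one training example per chunk,
#' labeled with the source label). After every epoch the un-augmented
#' validation split is evaluated, the metrics are appended to the history,
#' and (if `checkpoint_dir` is set) a checkpoint with weights, optimizer
#' state, epoch and RNG state is written, so training can be resumed
#' deterministically. The checkpoint with the best validation weighted F1 is
#' additionally tagged `checkpoint_best.rds`, and a JSON training log is
#' kept alongside.
#'
#' @param model A `te_encoder` (see [build_model()]).
#' @param splits A `te_splits` with labeled train and validation parts.
#' @param config A [train_config()].
#' @param class_names Character vector fixing the label order; defaults to
#'   the registry-ordered classes present in the training split.
#' @param registry Registry used for the default class order.
#' @param verbose Print one line per epoch.
#' @return List with the trained `model`, a `history` data.frame (epoch,
#'   train_loss, val_accuracy, val_macro_f1, val_weighted_f1), `class_names`
#'   and the checkpoint directory.
#' @export
train_model <- function(model, splits, config, class_names = NULL,
                        registry = default_registry(), verbose = FALSE) {
  stopifnot(inherits(model, "te_encoder"), inherits(splits, "te_splits"),
            inherits(config, "train_config"))
  if (nrow(splits$train) == 0L || nrow(splits$validation) == 0L) {
    stop("train and validation splits must be nonempty")
  }
  if (is.null(class_names)) {
    present <- unique(splits$train$label)
    class_names <- registry$classes[registry$classes %in% present]
    if (length(class_names) == 0L) class_names <- sort(present)
  }
  if (length(class_names) != model$config$num_classes) {
    stop("model num_classes (", model$config$num_classes,
         ") does not match the number of classes (", length(class_names), ")")
  }
  set.seed(config$seed)
  .run_training(model, splits, config, class_names,
                opt_state = .adamw_init(model$params),
                start_epoch = 0L, history = NULL, verbose = verbose)
}

#' Resume training from a checkpoint
#'
#' Restores weights, optimizer state and the RNG state saved at the end of
#' an epoch and continues to `config$num_epochs`. With identical splits and
#' configuration this reproduces the uninterrupted training trajectory
#' exactly.
#'
#' @param checkpoint_path Path to an epoch checkpoint written by
#'   [train_model()].
#' @param splits The same `te_splits` used originally.
#' @param config The same [train_config()] (checked against the checkpoint).
#' @param verbose Print one line per epoch.
#' @return As [train_model()].
#' @export
resume_training <- function(checkpoint_path, splits, config,
                            verbose = FALSE) {
  ck <- readRDS(checkpoint_path)
  stored <- ck$train_config
  for (nm in setdiff(names(stored), c("checkpoint_dir"))) {
    if (!identical(stored[[nm]], config[[nm]])) {
      stop("train_config field '", nm, "' differs from the checkpoint")
    }
  }
  model <- structure(list(config = ck$model_config, params = ck$params),
                     class = "te_encoder")
  assign(".Random.seed", ck$rng_state, envir = globalenv())
  .run_training(model, splits, config, ck$class_names,
                opt_state = ck$opt_state, start_epoch = ck$epoch,
                history = ck$history, verbose = verbose)
}

.run_training <- function(model, splits, config, class_names, opt_state,
                          start_epoch, history, verbose) {
  vocab <- build_vocabulary(model$config$kmer_size)
  max_emb <- model$config$max_embeddings
  weights <- compute_class_weights(table(splits$train$label)[class_names])
  label_idx <- match(splits$train$label, class_names)
  val_chunks <- .tokenize_split(splits$validation, vocab, max_emb)
  n_train <- nrow(splits$train)

  # deterministic warmup horizon from the un-augmented chunk count
  est_chunks <- sum(vapply(splits$train$sequence, function(s) {
    st <- compute_step(max(nchar(s), vocab$k), vocab$k, max_emb)
    ceiling((floor((nchar(s) - vocab$k) / st) + 1) / (max_emb - 1))
  }, numeric(1)))
  total_steps <- max(1, ceiling(est_chunks / config$batch_size) *
                       config$num_epochs /
                       config$gradient_accumulation_steps)
  warmup_steps <- max(1, ceiling(config$warmup_frac * total_steps))

  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (is.null(history)) {
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_accuracy = numeric(), val_macro_f1 = numeric(),
                          val_weighted_f1 = numeric())
  }
  best_f1 <- if (nrow(history) > 0) max(history$val_weighted_f1) else -Inf
  ga <- config$gradient_accumulation_steps

  for (epoch in (start_epoch + 1L):config$num_epochs) {
    order_idx <- sample.int(n_train)
    # build this epoch's chunk-level example list (augment, then tokenize)
    ex_chunks <- list(); ex_labels <- integer(0)
    for (i in order_idx) {
      s <- augment_pipeline(splits$train$sequence[i], config$augmentation)
      if (nchar(s) < vocab$k) s <- splits$train$sequence[i]
      chs <- tokenize(s, vocab, max_emb)
      ex_chunks <- c(ex_chunks, chs)
      ex_labels <- c(ex_labels, rep(label_idx[i], length(chs)))
    }
    n_ex <- length(ex_chunks)
    batch_starts <- seq(1L, n_ex, by = config$batch_size)
    epoch_loss <- 0; n_batches <- 0L
    acc_grads <- list(); acc_count <- 0L
    for (bs in batch_starts) {
      be <- min(bs + config$batch_size - 1L, n_ex)
      idx <- bs:be
      w <- unname(weights[ex_labels[idx]])
      ids_list <- lapply(ex_chunks[idx], function(ch) ch$ids[seq_len(ch$n)])
      bg <- cpp_batch_grad(model$params, model$config, ids_list,
                           ex_labels[idx] - 1L, w)
      batch_grads <- bg$grads
      epoch_loss <- epoch_loss + bg$loss
      n_batches <- n_batches + 1L
      acc_grads <- .grad_add(acc_grads, batch_grads)
      acc_count <- acc_count + 1L
      if (acc_count == ga || bs == batch_starts[length(batch_starts)]) {
        if (acc_count > 1L) {
          acc_grads <- lapply(acc_grads, function(g) g / acc_count)
        }
        lr <- config$learning_rate *
          min(1, (opt_state$t + 1L) / warmup_steps)
        st <- .adamw_step(model$params, acc_grads, opt_state, lr,
                          config$weight_decay)
        model$params <- st$params
        opt_state <- st$state
        acc_grads <- list(); acc_count <- 0L
      }
    }

    rep_val <- .evaluate_split(model, splits$validation, val_chunks,
                               class_names)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / n_batches,
      val_accuracy = rep_val$accuracy,
      val_macro_f1 = unname(rep_val$macro["f1"]),
      val_weighted_f1 = unname(rep_val$weighted["f1"])))
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  val acc %.3f  macro F1 %.3f  weighted F1 %.3f",
        epoch, epoch_loss / n_batches, rep_val$accuracy,
        rep_val$macro["f1"], rep_val$weighted["f1"]))
    }
    if (!is.null(config$checkpoint_dir)) {
      ck <- list(params = model$params, opt_state = opt_state,
                 epoch = epoch, rng_state = get(".Random.seed",
                                                envir = globalenv()),
                 model_config = model$config, train_config = config,
                 class_names = class_names, history = history)
      path <- file.path(config$checkpoint_dir,
                        sprintf("checkpoint_epoch_%03d.rds", epoch))
      saveRDS(ck, path)
      if (rep_val$weighted["f1"] >= best_f1) {
        best_f1 <- rep_val$weighted["f1"]
        file.copy(path, file.path(config$checkpoint_dir,
                                  "checkpoint_best.rds"), overwrite = TRUE)
      }
      jsonlite::write_json(history,
                           file.path(config$checkpoint_dir,
                                     "training_log.json"),
                           dataframe = "rows", digits = NA)
    }
  }
  list(model = model, history = history, class_names = class_names,
       checkpoint_dir = config$checkpoint_dir)
}

#' Save / load a standalone model checkpoint
#'
#' The checkpoint bundles the weights with the model configuration and the
#' class-name order so it round-trips losslessly.
#'
#' @param model A `te_encoder`.
#' @param class_names Class-name order the head was trained with.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, class_names, path) {
  saveRDS(list(params = model$params, model_config = model$config,
               class_names = class_names), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with `model` and
#'   `class_names`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  list(model = structure(list(config = ck$model_config, params = ck$params),
                         class = "te_encoder"),
       class_names = ck$class_names)
}
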