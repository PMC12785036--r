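#' Median aggregation of per-chunk class probabilities
#'
#' Long sequences are processed in chunks; the sequence-level class
#' distribution is the element-wise median of the chunk distributions,
#' renormalized to sum to one (element-wise medians of probability vectors
#' need not be a distribution). Invariant under permutation of the chunks.
#'
#' @param per_chunk_probabilities Numeric matrix, one row per chunk, one
#'   column per class; each row sums to 1. A single vector is accepted.
#' @return Numeric probability vector over classes.
#' @export
aggregate_chunks <- function(per_chunk_probabilities) {
  if (is.null(dim(per_chunk_probabilities))) {
    per_chunk_probabilities <- matrix(per_chunk_probabilities, nrow = 1)
  }
  if (nrow(per_chunk_probabilities) == 0L) stop("no chunk probabilities")
  med <- apply(per_chunk_probabilities, 2, stats::median)
  s <- sum(med)
  if (s <= 0) {
    return(rep(1 / ncol(per_chunk_probabilities),
               ncol(per_chunk_probabilities)))
  }
  med / s
}

#' Classify TE consensus sequences
#'
#' Runs the full inference pipeline: tokenize each sequence with the
#' dilated sliding window, run the encoder on every chunk, median-aggregate
#' the chunk probabilities, take the argmax superfamily (ties broken by
#' registry order), roll it up to its Wicker order, and apply the minimum
#' probability threshold: a sequence whose top probability falls below the
#' threshold is reported `unclassified` (its full probability vector is
#' kept). Sequences shorter than k are flagged `too_short`, never silently
#' dropped. No augmentation is applied at inference time.
#'
#' @param input A labeled-sequence data.frame (labels optional/ignored) or
#'   a path to a FASTA file of unlabeled sequences.
#' @param model A `te_encoder`, or a path to a checkpoint written by
#'   [save_checkpoint()] / [train_model()].
#' @param class_names Class order of the model head; taken from the
#'   checkpoint when `model` is a path.
#' @param threshold Minimum top probability to call a classification
#'   (default 0.7; 0.9 is the strict preset).
#' @param registry A `te_registry` for the superfamily-to-order roll-up;
#'   superfamilies absent from the registry get order NA.
#' @return A data.frame of class `classification_records` with columns id,
#'   predicted_order, predicted_superfamily, max_probability, verdict
#'   (classified / unclassified / too_short), then one probability column
#'   per class (`prob_<class>`), rows in input order.
#' @export
classify_sequences <- function(input, model, class_names = NULL,
                               threshold = 0.7,
                               registry = default_registry()) {
  if (is.character(model)) {
    ck <- load_checkpoint(model)
    if (is.null(class_names)) class_names <- ck$class_names
    model <- ck$model
  }
  if (is.null(class_names)) {
    stop("class_names must be supplied when `model` is not a checkpoint path")
  }
  if (length(class_names) != model$config$num_classes) {
    stop("class_names length does not match the model head")
  }
  seqs <- if (is.character(input)) {
    read_labeled_fasta(input, labeled = FALSE)
  } else input
  vocab <- build_vocabulary(model$config$kmer_size)
  C <- length(class_names)
  n <- nrow(seqs)
  probs <- matrix(NA_real_, n, C)
  verdict <- character(n)
  sf <- rep(NA_character_, n)
  maxp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (nchar(seqs$sequence[i]) < vocab$k) {
      verdict[i] <- "too_short"
      next
    }
    chunks <- tokenize(seqs$sequence[i], vocab, model$config$max_embeddings)
    p <- .predict_sequence_chunks(model, chunks)
    probs[i, ] <- p
    top <- which.max(p)          # first max wins: registry-order tie-break
    sf[i] <- class_names[top]
    maxp[i] <- p[top]
    verdict[i] <- if (p[top] >= threshold) "classified" else "unclassified"
  }
  ord <- ifelse(is.na(sf), NA_character_,
                ifelse(sf %in% registry$classes,
                       unname(registry$orders[sf]), NA_character_))
  out <- data.frame(id = seqs$id, predicted_order = ord,
                    predicted_superfamily = sf, max_probability = maxp,
                    verdict = verdict, stringsAsFactors = FALSE)
  pcols <- as.data.frame(probs)
  names(pcols) <- paste0("prob_", gsub("/", "_", class_names))
  out <- cbind(out, pcols)
  class(out) <- c("classification_records", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "class_names") <- class_names
  out
}

#' Write classification records as TSV
#'
#' Columns: id, predicted_order, predicted_superfamily, max_probability,
#' verdict, then one Softmax probability column per class in registry
#' order.
#'
#' @param records Output of [classify_sequences()].
#' @param path Output TSV path.
#' @export
write_classification_tsv <- function(records, path) {
  out <- as.data.frame(records)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) ifelse(is.na(x), NA,
                                                  sprintf("%.6f", x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
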