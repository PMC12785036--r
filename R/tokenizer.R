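#' Build the k-mer vocabulary over \{A,C,G,T,N\}
#'
#' Enumerates all `5^k` k-mers over the 5-letter DNA alphabet (unknown base N
#' included) in lexicographic order of the alphabet A < C < G < T < N, with
#' dense 0-based ids, and appends the special tokens PAD, CLS and UNK above
#' the k-mer range. For the default k = 5 this yields 3125 k-mer tokens.
#' Ids are computed arithmetically from base-5 digits, so the mapping is
#' stable across runs and needs no stored table.
#'
#' @param k k-mer length, 1..8 (larger values blow up the vocabulary).
#' @return An object of class `kmer_vocab`: list with `k`, `alphabet`,
#'   `n_kmers`, `size`, and the special ids `pad_id`, `cls_id`, `unk_id`.
#' @examples
#' v <- build_vocabulary(5)
#' v$n_kmers  # 3125
#' @export
build_vocabulary <- function(k = 5L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 8L) {
    stop("kmer size k must be an integer in 1..8")
  }
  n <- as.integer(5^k)
  structure(list(k = k,
                 alphabet = c("A", "C", "G", "T", "N"),
                 n_kmers = n,
                 pad_id = n,
                 cls_id = n + 1L,
                 unk_id = n + 2L,
                 size = n + 3L),
            class = "kmer_vocab")
}

# map sequence characters to digits 0..4 (A,C,G,T,N)
.base_digits <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  d <- match(ch, c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(d)) stop("sequence contains characters outside {A,C,G,T,N}; sanitize first")
  d
}

#' Map k-mer strings to token ids and back
#'
#' @param kmers Character vector of k-mers.
#' @param vocab A `kmer_vocab`.
#' @return Integer ids in `[0, 5^k)`.
#' @export
kmer_to_id <- function(kmers, vocab) {
  vapply(kmers, function(s) {
    d <- .base_digits(s)
    if (length(d) != vocab$k) stop("k-mer of wrong length: ", s)
    as.integer(sum(d * 5^((vocab$k - 1L):0L)))
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname kmer_to_id
#' @param ids Integer token ids.
#' @export
id_to_kmer <- function(ids, vocab) {
  vapply(ids, function(id) {
    stopifnot(id >= 0L, id < vocab$n_kmers)
    digs <- integer(vocab$k)
    for (j in vocab$k:1L) {
      digs[j] <- id %% 5L
      id <- id %/% 5L
    }
    paste(vocab$alphabet[digs + 1L], collapse = "")
  }, character(1))
}

#' Full vocabulary table (token, id), including specials
#'
#' @param vocab A `kmer_vocab`.
#' @return data.frame with columns token, id, in id order.
#' @export
vocab_table <- function(vocab) {
  ids <- 0:(vocab$n_kmers - 1L)
  data.frame(
    token = c(id_to_kmer(ids, vocab), "<PAD>", "<CLS>", "<UNK>"),
    id = c(ids, vocab$pad_id, vocab$cls_id, vocab$unk_id),
    stringsAsFactors = FALSE)
}

#' @rdname vocab_table
#' @param path Output TSV path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(vocab_table(vocab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dynamically dilated sliding-window step
#'
#' The step between consecutive k-mer window starts scales with sequence
#' length so that long inputs still fit the embedding budget:
#' `step = clamp(ceil(seq_len / max_embeddings), 2, k - 1)`. The lower bound
#' of two nucleotides maximizes coverage for short inputs; the upper bound
#' `k - 1` guarantees consecutive k-mers still overlap by at least one
#' nucleotide.
#'
#' @param seq_len Sequence length in nucleotides (>= k).
#' @param k k-mer length (must be >= 3 so a valid step window exists).
#' @param max_embeddings Embedding budget per chunk.
#' @return Integer step in `[2, k - 1]`.
#' @examples
#' compute_step(1000, 5, 2048)  # 2
#' compute_step(8192, 5, 2048)  # 4
#' @export
compute_step <- function(seq_len, k = 5L, max_embeddings = 2048L) {
  if (k <= 2L) stop("k must be at least 3: no step in [2, k-1] exists")
  if (max_embeddings < 1L) stop("max_embeddings must be >= 1")
  if (seq_len < k) stop("sequence shorter than k")
  step <- ceiling(seq_len / max_embeddings)
  as.integer(min(max(step, 2L), k - 1L))
}

#' Tokenize a DNA sequence into model-ready chunks
#'
#' Extracts k-mers at window starts 0, step, 2*step, ... while the window
#' fits, giving `floor((len - k)/step) + 1` tokens. If the token count
#' exceeds the embedding budget (one position per chunk is reserved for the
#' CLS classification anchor), the token stream is split into consecutive
#' non-overlapping chunks of at most `max_embeddings - 1` k-mer tokens.
#' Every chunk is prefixed with CLS, and when a call produces several chunks
#' the shorter remainder chunk is padded with PAD to the common length so a
#' batch is rectangular.
#'
#' @param seq Sanitized DNA string (length >= k).
#' @param vocab A `kmer_vocab`.
#' @param max_embeddings Maximum tokens per chunk including CLS
#'   (default 2048).
#' @return List of `token_chunk` objects; each has `ids` (0-based, CLS
#'   first, possibly PAD-padded), `n` (real tokens incl. CLS), `step`,
#'   `starts` (0-based nucleotide start of each k-mer token), `k` and
#'   `seq_len`.
#' @export
tokenize <- function(seq, vocab, max_embeddings = 2048L) {
  k <- vocab$k
  len <- nchar(seq)
  if (len < k) stop("sequence shorter than k")
  step <- compute_step(len, k, max_embeddings)
  d <- .base_digits(seq)
  starts0 <- seq.int(0L, len - k, by = step)   # 0-based
  pow <- 5L^((k - 1L):0L)
  ids <- integer(length(starts0))
  for (j in seq_len(k)) {
    ids <- ids + d[starts0 + j] * pow[j]
  }
  cap <- max_embeddings - 1L
  n_chunks <- ceiling(length(ids) / cap)
  pieces <- unname(split(seq_along(ids), ceiling(seq_along(ids) / cap)))
  width <- length(pieces[[1]])
  lapply(pieces, function(ix) {
    chunk_ids <- c(vocab$cls_id, ids[ix])
    n_real <- length(chunk_ids)
    if (n_chunks > 1L && length(ix) < width) {
      chunk_ids <- c(chunk_ids, rep(vocab$pad_id, width - length(ix)))
    }
    structure(list(ids = as.integer(chunk_ids), n = n_real,
                   step = step, starts = starts0[ix], k = k,
                   seq_len = len),
              class = "token_chunk")
  })
}
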