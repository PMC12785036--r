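#' Augmentation configuration
#'
#' Holds the per-kind application probability and the magnitude parameters of
#' the ten on-the-fly DNA augmentations used during training. The ten kinds,
#' applied in this fixed order by [augment_pipeline()], are: snp, masking,
#' insertion, deletion, repeat, reverse, complement, reverse_complement,
#' add_tail, remove_tail.
#'
#' Magnitudes scale with sequence length: snp/masking counts are drawn
#' uniformly in `[1, max(1, len * snp_frac)]`, inserted/deleted/repeated
#' segment lengths uniformly in `[1, max(1, len * segment_frac)]`, poly-A
#' tails uniformly in `tail_len_range`.
#'
#' @param p_snp,p_masking,p_insertion,p_deletion,p_repeat Probabilities of
#'   the mutating kinds (defaults 0.05 each).
#' @param p_reverse,p_complement,p_reverse_complement Probabilities of the
#'   strand kinds (defaults 0.25 each; each is drawn independently, in order).
#' @param p_add_tail,p_remove_tail Probabilities of the poly-A tail kinds
#'   (defaults 0.05 each).
#' @param snp_frac Fraction of length bounding the SNP/masking count
#'   (default 0.01).
#' @param segment_frac Fraction of length bounding indel/repeat segment
#'   length (default 0.05).
#' @param tail_len_range Integer range of added poly-A tail lengths
#'   (default 5..30).
#' @param min_tail Minimum terminal A-run length recognized as a poly-A tail
#'   by remove_tail (default 5).
#' @return An object of class `aug_config`.
#' @export
augmentation_config <- function(p_snp = 0.05, p_masking = 0.05,
                                p_insertion = 0.05, p_deletion = 0.05,
                                p_repeat = 0.05, p_reverse = 0.25,
                                p_complement = 0.25,
                                p_reverse_complement = 0.25,
                                p_add_tail = 0.05, p_remove_tail = 0.05,
                                snp_frac = 0.01, segment_frac = 0.05,
                                tail_len_range = c(5L, 30L),
                                min_tail = 5L) {
  probs <- c(snp = p_snp, masking = p_masking, insertion = p_insertion,
             deletion = p_deletion, "repeat" = p_repeat, reverse = p_reverse,
             complement = p_complement,
             reverse_complement = p_reverse_complement,
             add_tail = p_add_tail, remove_tail = p_remove_tail)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (snp_frac <= 0 || segment_frac <= 0) stop("magnitude fractions must be positive")
  if (length(tail_len_range) != 2L || any(tail_len_range < 1L)) {
    stop("tail_len_range must be two positive integers")
  }
  structure(list(probs = probs, snp_frac = snp_frac,
                 segment_frac = segment_frac,
                 tail_len_range = as.integer(tail_len_range),
                 min_tail = as.integer(min_tail)),
            class = "aug_config")
}

#' @rdname augmentation_config
#' @details `no_augmentation()` returns the identity configuration (all
#'   probabilities 0), used at validation and inference time.
#' @export
no_augmentation <- function() {
  augmentation_config(p_snp = 0, p_masking = 0, p_insertion = 0,
                      p_deletion = 0, p_repeat = 0, p_reverse = 0,
                      p_complement = 0, p_reverse_complement = 0,
                      p_add_tail = 0, p_remove_tail = 0)
}

AUG_KINDS <- c("snp", "masking", "insertion", "deletion", "repeat",
               "reverse", "complement", "reverse_complement",
               "add_tail", "remove_tail")

COMPLEMENT_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# ---- per-kind edits on character vectors ------------------------------------

.aug_snp <- function(ch, count) {
  n <- length(ch)
  count <- min(count, n)
  pos <- sample.int(n, count)
  for (p in pos) {
    choices <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- choices[sample.int(length(choices), 1L)]
  }
  ch
}

.aug_masking <- function(ch, count) {
  pos <- sample.int(length(ch), min(count, length(ch)))
  ch[pos] <- "N"
  ch
}

.aug_insertion <- function(ch, seg_len) {
  ins <- sample(c("A", "C", "G", "T"), seg_len, replace = TRUE)
  at <- sample.int(length(ch) + 1L, 1L) - 1L  # insert after position `at`
  append(ch, ins, after = at)
}

.aug_deletion <- function(ch, seg_len) {
  n <- length(ch)
  if (seg_len >= n) {
    warning("deletion would empty the sequence; skipped")
    return(ch)
  }
  start <- sample.int(n - seg_len + 1L, 1L)
  ch[-(start:(start + seg_len - 1L))]
}

.aug_repeat <- function(ch, seg_len) {
  n <- length(ch)
  seg_len <- min(seg_len, n)
  start <- sample.int(n - seg_len + 1L, 1L)
  seg <- ch[start:(start + seg_len - 1L)]
  append(ch, seg, after = start + seg_len - 1L)
}

.aug_complement <- function(ch) unname(COMPLEMENT_MAP[ch])

.aug_add_tail <- function(ch, tail_len) c(ch, rep("A", tail_len))

.aug_remove_tail <- function(ch, min_tail) {
  n <- length(ch)
  run <- 0L
  while (run < n && ch[n - run] == "A") run <- run + 1L
  if (run >= min_tail) ch[seq_len(n - run)] else ch
}

#' Apply a single augmentation kind
#'
#' String-level edits of a DNA sequence used for training-time augmentation:
#' point substitutions (snp), N-masking, random insertions/deletions, segment
#' duplication (repeat), strand operations (reverse, complement,
#' reverse_complement), and poly-A tail addition/removal. Randomness is drawn
#' from R's global RNG; seed the session (or use the `seed` argument of
#' [augment_pipeline()]) for reproducibility.
#'
#' @param seq DNA string over \{A,C,G,T,N\}.
#' @param kind One of `"snp"`, `"masking"`, `"insertion"`, `"deletion"`,
#'   `"repeat"`, `"reverse"`, `"complement"`, `"reverse_complement"`,
#'   `"add_tail"`, `"remove_tail"`.
#' @param config An [augmentation_config()] supplying magnitudes.
#' @return The augmented DNA string, still over \{A,C,G,T,N\}.
#' @examples
#' apply_augmentation("AACG", "complement")          # "TTGC"
#' apply_augmentation("AACG", "reverse_complement")  # "CGTT"
#' @export
apply_augmentation <- function(seq, kind = AUG_KINDS,
                               config = augmentation_config()) {
  kind <- match.arg(kind)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0L) stop("cannot augment an empty sequence")
  count_max <- max(1L, floor(n * config$snp_frac))
  seg_max <- max(1L, floor(n * config$segment_frac))
  out <- switch(kind,
    snp = .aug_snp(ch, sample.int(count_max, 1L)),
    masking = .aug_masking(ch, sample.int(count_max, 1L)),
    insertion = .aug_insertion(ch, sample.int(seg_max, 1L)),
    deletion = .aug_deletion(ch, sample.int(seg_max, 1L)),
    "repeat" = .aug_repeat(ch, sample.int(seg_max, 1L)),
    reverse = rev(ch),
    complement = .aug_complement(ch),
    reverse_complement = rev(.aug_complement(ch)),
    add_tail = .aug_add_tail(
      ch, config$tail_len_range[1] +
        sample.int(diff(config$tail_len_range) + 1L, 1L) - 1L),
    remove_tail = .aug_remove_tail(ch, config$min_tail)
  )
  paste(out, collapse = "")
}

#' Stochastic augmentation pipeline
#'
#' Applies each of the ten augmentation kinds independently with its
#' configured probability, in the fixed order snp, masking, insertion,
#' deletion, repeat, reverse, complement, reverse_complement, add_tail,
#' remove_tail. With all probabilities 0 the input is returned unchanged;
#' identical (sequence, config, seed) gives identical output.
#'
#' @param seq DNA string over \{A,C,G,T,N\}.
#' @param config An [augmentation_config()].
#' @param seed Optional integer; if given, the pipeline runs under a local
#'   RNG seeded with it (the caller's RNG stream is untouched).
#' @return Augmented DNA string of length >= 1.
#' @export
augment_pipeline <- function(seq, config = augmentation_config(),
                             seed = NULL) {
  run <- function() {
    s <- seq
    for (kind in AUG_KINDS) {
      p <- config$probs[[kind]]
      if (p > 0 && stats::runif(1) < p) {
        s <- apply_augmentation(s, kind, config)
      }
    }
    s
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
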