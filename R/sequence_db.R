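#' Sanitize a raw DNA sequence
#'
#' Uppercases the sequence, strips whitespace, and maps every character that
#' is not A, C, G or T to N (so IUPAC ambiguity codes, softmasked leftovers
#' after case folding, and stray characters all become the unknown base).
#' Sanitization is idempotent.
#'
#' @param raw Character scalar, the raw sequence.
#' @param id Optional record identifier used in error messages.
#' @return Character scalar over the alphabet \{A,C,G,T,N\}.
#' @examples
#' sanitize_sequence("acgt")   # "ACGT"
#' sanitize_sequence("ACRGT")  # "ACNGT"
#' @export
sanitize_sequence <- function(raw, id = NULL) {
  if (length(raw) != 1L || is.na(raw)) {
    stop("sanitize_sequence() expects a single non-NA string")
  }
  s <- toupper(gsub("\\s", "", raw))
  if (nchar(s) == 0L) {
    stop("empty sequence",
         if (!is.null(id)) paste0(" for record '", id, "'") else "")
  }
  gsub("[^ACGT]", "N", s)
}

#' Construct a labeled sequence table
#'
#' The canonical in-memory container for TE consensus sequences: a
#' data.frame with columns `id`, `label` (NA when unlabeled) and `sequence`
#' (sanitized). Row order is preserved everywhere in the package.
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of DNA sequences (sanitized on entry).
#' @param label Optional character vector of class labels (NA allowed).
#' @return A data.frame with columns id, label, sequence.
#' @export
labeled_sequences <- function(id, sequence, label = NA_character_) {
  stopifnot(length(id) == length(sequence))
  sequence <- vapply(seq_along(sequence),
                     function(i) sanitize_sequence(sequence[i], id[i]),
                     character(1))
  data.frame(id = as.character(id),
             label = rep_len(as.character(label), length(id)),
             sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Read a (labeled) FASTA file of TE consensus sequences
#'
#' Headers follow the RepeatMasker/Dfam convention `<id><separator><class>`
#' (default separator `#`); the class part may itself contain further
#' characters such as `/` (e.g. `L1/L2`). Sequences are sanitized to the
#' \{A,C,G,T,N\} alphabet; file order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param label_separator Separator between id and class in the header.
#' @param registry A `te_registry` used to validate labels.
#' @param strict_labels If TRUE (default) an unknown class name is an error;
#'   if FALSE the offending records are dropped with a warning.
#' @param labeled If FALSE, headers are taken verbatim as ids and no label is
#'   parsed (inference input).
#' @return A labeled-sequence data.frame (see [labeled_sequences()]).
#' @export
read_labeled_fasta <- function(path, label_separator = "#",
                               registry = default_registry(),
                               strict_labels = TRUE, labeled = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), label = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  seqs <- as.character(set)
  if (!labeled) {
    ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
    return(labeled_sequences(ids, seqs))
  }
  # take the header token before any whitespace, then split at the first
  # separator: the id may not contain it, the class may (e.g. "L1/L2")
  tok <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  sep_pos <- regexpr(label_separator, tok, fixed = TRUE)
  bad <- sep_pos < 0L
  if (any(bad)) {
    stop("malformed FASTA header(s), no '", label_separator, "' separator: ",
         paste(utils::head(headers[bad], 5), collapse = "; "))
  }
  ids <- substr(tok, 1L, sep_pos - 1L)
  labels <- substr(tok, sep_pos + nchar(label_separator), nchar(tok))
  unknown <- !(labels %in% registry$classes)
  if (any(unknown)) {
    msg <- paste0("unknown class label(s): ",
                  paste(unique(labels[unknown]), collapse = ", "))
    if (strict_labels) stop(msg)
    warning(msg, "; ", sum(unknown), " record(s) skipped")
    ids <- ids[!unknown]; labels <- labels[!unknown]; seqs <- seqs[!unknown]
  }
  labeled_sequences(ids, seqs, labels)
}

#' Write a labeled sequence table as FASTA
#'
#' @param seqs A labeled-sequence data.frame.
#' @param path Output path.
#' @param label_separator Separator placed between id and label in headers;
#'   records with NA labels get a bare id header.
#' @export
write_labeled_fasta <- function(seqs, path, label_separator = "#") {
  headers <- ifelse(is.na(seqs$label), seqs$id,
                    paste0(seqs$id, label_separator, seqs$label))
  set <- Biostrings::DNAStringSet(seqs$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# round-half-up, unlike base round() which rounds half to even
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

#' Deterministic stratified train/validation/test split
#'
#' Splits labeled sequences per class into train/validation/test parts with
#' fractions 0.75/0.15/0.10 by default. Within each class of size `N`, the
#' training part gets `floor(0.75 N)` members, validation
#' `round-half-up(0.15 N)`, and test the remainder; assignment within a class
#' is a seeded random permutation, so identical input and seed reproduce the
#' split exactly.
#'
#' @param seqs Labeled-sequence data.frame; every record must carry a label.
#' @param fractions Numeric length-3 vector (train, validation, test)
#'   summing to 1.
#' @param seed Integer master seed.
#' @return An object of class `te_splits`: list with data.frames `train`,
#'   `validation`, `test` plus the `fractions` and `seed` used.
#' @examples
#' seqs <- labeled_sequences(paste0("s", 1:10), rep("ACGTACGTAC", 10), "Copia")
#' sp <- split_dataset(seqs, seed = 1)
#' vapply(sp[c("train", "validation", "test")], nrow, 1L)  # 7 2 1
#' @export
split_dataset <- function(seqs, fractions = c(0.75, 0.15, 0.10), seed = 1L) {
  if (nrow(seqs) == 0L) stop("no sequences to split")
  if (anyNA(seqs$label)) stop("every record must be labeled for splitting")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three numbers summing to 1")
  }
  classes <- sort(unique(seqs$label))
  small <- classes[table(seqs$label)[classes] < 3L]
  if (length(small) > 0) {
    warning("class(es) with fewer than 3 members: ",
            paste(small, collapse = ", "), " (some parts may be empty)")
  }
  part <- character(nrow(seqs))
  with_local_seed(seed, {
    for (cl in classes) {
      idx <- which(seqs$label == cl)
      n <- length(idx)
      n_tr <- floor(fractions[1] * n)
      n_va <- round_half_up(fractions[2] * n)
      n_te <- n - n_tr - n_va
      if (n_te < 0L) { n_va <- n_va + n_te; n_te <- 0L }
      perm <- sample(idx, n)
      part[perm] <- rep(c("train", "validation", "test"),
                        times = c(n_tr, n_va, n_te))
    }
  })
  structure(
    list(train = seqs[part == "train", , drop = FALSE],
         validation = seqs[part == "validation", , drop = FALSE],
         test = seqs[part == "test", , drop = FALSE],
         fractions = fractions, seed = as.integer(seed)),
    class = "te_splits"
  )
}

#' Split manifest (id, class, partition)
#'
#' @param splits A `te_splits` object.
#' @return A data.frame with columns id, class, partition, ordered
#'   train/validation/test.
#' @export
split_manifest <- function(splits) {
  stopifnot(inherits(splits, "te_splits"))
  do.call(rbind, lapply(c("train", "validation", "test"), function(p) {
    d <- splits[[p]]
    if (nrow(d) == 0L) {
      return(data.frame(id = character(), class = character(),
                        partition = character(), stringsAsFactors = FALSE))
    }
    data.frame(id = d$id, class = d$label, partition = p,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname split_manifest
#' @param path Output TSV path.
#' @export
write_split_manifest <- function(splits, path) {
  utils::write.table(split_manifest(splits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run expr with a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
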