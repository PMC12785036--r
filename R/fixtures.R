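#' Specification of a synthetic TE family
#'
#' A family is defined by a consensus drawn from a base-composition bias
#' with planted signature motifs, from which noisy copies are generated by
#' per-base substitution and occasional short indels. Placement rules:
#' `internal` plants the motif at a random interior position,
#' `terminal_repeat` at both ends in the same orientation (LTR-like),
#' `inverted_terminal_repeat` at the 5' end plus its reverse complement at
#' the 3' end (TIR-like), and `polyA_suffix` appends an A-run (non-LTR-like
#' tail).
#'
#' @param name Family (class) name.
#' @param n_copies Number of copies to generate.
#' @param length_range Integer min/max consensus length in nucleotides.
#' @param base_probs Length-4 composition bias over A,C,G,T (normalized).
#' @param motifs List of `list(seq=, placement=)` entries; motif sequences
#'   are over \{A,C,G,T\}; placement is one of the rules above
#'   (`polyA_suffix` needs no `seq`).
#' @param sub_rate Per-base substitution probability per copy, in [0, 0.5).
#' @param indel_rate Per-base probability that an indel event (length 1-10,
#'   insertion or deletion) starts at a position, in [0, 0.5).
#' @param seed Integer seed owned by the spec: identical specs generate
#'   identical families.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(name, n_copies, length_range,
                        base_probs = c(0.25, 0.25, 0.25, 0.25),
                        motifs = list(), sub_rate = 0.05,
                        indel_rate = 0.001, seed = 1L) {
  if (sub_rate < 0 || sub_rate >= 0.5) stop("sub_rate must be in [0, 0.5)")
  if (indel_rate < 0 || indel_rate >= 0.5) stop("indel_rate must be in [0, 0.5)")
  if (length(length_range) != 2L || any(length_range < 1L)) {
    stop("length_range must be two positive integers")
  }
  for (m in motifs) {
    if (!identical(m$placement, "polyA_suffix")) {
      if (is.null(m$seq) || grepl("[^ACGT]", m$seq)) {
        stop("motif sequences must be over {A,C,G,T}")
      }
      if (nchar(m$seq) > length_range[1]) {
        stop("motif '", m$seq, "' longer than the minimum family length")
      }
    }
  }
  structure(list(name = name, n_copies = as.integer(n_copies),
                 length_range = as.integer(length_range),
                 base_probs = base_probs / sum(base_probs),
                 motifs = motifs, sub_rate = sub_rate,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "family_spec")
}

.revcomp_chars <- function(ch) rev(unname(COMPLEMENT_MAP[ch]))

.plant_motifs <- function(ch, motifs) {
  n <- length(ch)
  for (m in motifs) {
    if (identical(m$placement, "polyA_suffix")) {
      ch <- c(ch, rep("A", 15L))
      n <- length(ch)
      next
    }
    ms <- strsplit(m$seq, "", fixed = TRUE)[[1]]
    w <- length(ms)
    switch(m$placement,
      internal = {
        at <- sample.int(n - w + 1L, 1L)
        ch[at:(at + w - 1L)] <- ms
      },
      terminal_repeat = {
        ch[1:w] <- ms
        ch[(n - w + 1L):n] <- ms
      },
      inverted_terminal_repeat = {
        ch[1:w] <- ms
        ch[(n - w + 1L):n] <- .revcomp_chars(ms)
      },
      stop("unknown motif placement: ", m$placement))
  }
  ch
}

.mutate_copy <- function(ch, sub_rate, indel_rate) {
  n <- length(ch)
  if (sub_rate > 0) {
    hit <- which(stats::runif(n) < sub_rate)
    for (p in hit) {
      choices <- setdiff(c("A", "C", "G", "T"), ch[p])
      ch[p] <- choices[sample.int(3L, 1L)]
    }
  }
  if (indel_rate > 0) {
    n_events <- stats::rbinom(1L, n, indel_rate)
    for (e in seq_len(n_events)) {
      len <- sample.int(10L, 1L)
      if (stats::runif(1) < 0.5 && length(ch) > len) {
        start <- sample.int(length(ch) - len, 1L)
        ch <- ch[-(start:(start + len - 1L))]
      } else {
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        at <- sample.int(length(ch) + 1L, 1L) - 1L
        ch <- append(ch, ins, after = at)
      }
    }
  }
  ch
}

#' Generate one synthetic TE family
#'
#' Draws the family consensus (composition bias, planted motifs) and
#' `n_copies` perturbed copies. Fully deterministic given the spec (the
#' spec owns its seed).
#'
#' @param spec A [family_spec()].
#' @return Labeled-sequence data.frame with ids `<name>_<i>` and
#'   label `name`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_local_seed(spec$seed, {
    rng <- spec$length_range
    len <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    cons <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = spec$base_probs)
    cons <- .plant_motifs(cons, spec$motifs)
    copies <- vapply(seq_len(spec$n_copies), function(i) {
      paste(.mutate_copy(cons, spec$sub_rate, spec$indel_rate),
            collapse = "")
    }, character(1))
    out <- labeled_sequences(
      paste0(gsub("[^A-Za-z0-9]", "", spec$name), "_", seq_len(spec$n_copies)),
      copies, spec$name)
    attr(out, "consensus") <- paste(cons, collapse = "")
    out
  })
}

#' The four-family benchmark preset
#'
#' Toy counterpart of a real TE library: an LTR-like family (Copia label;
#' direct terminal repeats, GC-rich), a LINE-like family (L1/L2 label;
#' long, internal motif, poly-A tail, AT-rich), a SINE-like family (SINE
#' label; short, poly-A tail) and a TIR-like family (TcMar label; inverted
#' terminal repeats). Distinct 12-mer signature motifs and composition
#' biases give well-separated families at the default 5% substitution
#' rate.
#'
#' @param n_copies Copies per family (default 200).
#' @param sub_rate Per-copy substitution rate (default 0.05).
#' @param seed Master seed; each family spec gets a derived seed.
#' @return List of four [family_spec()] objects.
#' @export
four_family_preset <- function(n_copies = 200L, sub_rate = 0.05,
                               seed = 1L) {
  list(
    family_spec("Copia", n_copies, c(800L, 1500L),
                base_probs = c(0.2, 0.3, 0.3, 0.2),
                motifs = list(list(seq = "TGTCAGGCACTA",
                                   placement = "terminal_repeat"),
                              list(seq = "GGGCCATTACGG",
                                   placement = "internal")),
                sub_rate = sub_rate, seed = seed * 1000L + 1L),
    family_spec("L1/L2", n_copies, c(900L, 1500L),
                base_probs = c(0.35, 0.15, 0.15, 0.35),
                motifs = list(list(seq = "ACTGGCATTCAA",
                                   placement = "internal"),
                              list(placement = "polyA_suffix")),
                sub_rate = sub_rate, seed = seed * 1000L + 2L),
    family_spec("SINE", n_copies, c(300L, 500L),
                base_probs = c(0.25, 0.25, 0.25, 0.25),
                motifs = list(list(seq = "CCGTAGTTAGCA",
                                   placement = "internal"),
                              list(placement = "polyA_suffix")),
                sub_rate = sub_rate, seed = seed * 1000L + 3L),
    family_spec("TcMar", n_copies, c(300L, 700L),
                base_probs = c(0.3, 0.2, 0.2, 0.3),
                motifs = list(list(seq = "CAGTGGTGAACC",
                                   placement = "inverted_terminal_repeat")),
                sub_rate = sub_rate, seed = seed * 1000L + 4L)
  )
}

#' Generate a labeled benchmark with stratified splits
#'
#' Generates every family, pools the copies, and produces the stratified
#' 75/15/10 split. Optionally writes the labeled FASTA, the split manifest
#' TSV and a JSON record of the specs to `dir`.
#'
#' @param family_specs List of [family_spec()]s with distinct names.
#' @param split_fractions Train/validation/test fractions.
#' @param seed Seed for the split assignment.
#' @param dir Optional output directory.
#' @return List with `seqs` (all copies), `splits` (a `te_splits`) and, if
#'   `dir` was given, the written `paths`.
#' @export
generate_benchmark <- function(family_specs,
                               split_fractions = c(0.75, 0.15, 0.10),
                               seed = 1L, dir = NULL) {
  if (length(family_specs) < 2L) stop("need at least 2 families")
  nm <- vapply(family_specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate family names")
  seqs <- do.call(rbind, lapply(family_specs, generate_family))
  splits <- split_dataset(seqs, split_fractions, seed)
  out <- list(seqs = seqs, splits = splits)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "benchmark.fasta"),
                  manifest = file.path(dir, "split_manifest.tsv"),
                  specs = file.path(dir, "family_specs.json"))
    write_labeled_fasta(seqs, paths$fasta)
    write_split_manifest(splits, paths$manifest)
    jsonlite::write_json(
      lapply(family_specs, function(s) s[setdiff(names(s), "motifs")]),
      paths$specs, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Negative-control pair: one family under two names
#'
#' Builds two specs identical in every field (including the seed) except
#' the name, so both families contain byte-identical copies. Any classifier
#' is then at chance; used as the separability negative control.
#'
#' @param n_copies Copies per family.
#' @param seed Shared spec seed.
#' @return List of two [family_spec()]s.
#' @export
negative_control_pair <- function(n_copies = 100L, seed = 1L) {
  base <- function(name) {
    family_spec(name, n_copies, c(300L, 600L),
                motifs = list(list(seq = "GATTACAGATTA",
                                   placement = "internal")),
                sub_rate = 0.05, seed = seed)
  }
  list(base("Copia"), base("Gypsy"))
}
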