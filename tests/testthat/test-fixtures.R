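test_that("family generation is deterministic and noise-free at zero rates", {
  spec <- family_spec("Copia", 8, c(100L, 150L), sub_rate = 0, indel_rate = 0,
                      seed = 5)
  fam <- generate_family(spec)
  expect_equal(nrow(fam), 8)
  expect_true(all(fam$label == "Copia"))
  expect_equal(length(unique(fam$sequence)), 1L)       # all copies = consensus
  expect_identical(fam$sequence[1], attr(fam, "consensus"))
  # same spec, same output; different seed, different copies
  expect_identical(generate_family(spec)$sequence, fam$sequence)
  spec2 <- family_spec("Copia", 8, c(100L, 150L), sub_rate = 0.05,
                       indel_rate = 0, seed = 5)
  spec3 <- family_spec("Copia", 8, c(100L, 150L), sub_rate = 0.05,
                       indel_rate = 0, seed = 6)
  f2 <- generate_family(spec2); f3 <- generate_family(spec3)
  expect_false(identical(f2$sequence, f3$sequence))
})

test_that("substitution noise matches the binomial expectation", {
  spec <- family_spec("RTE", 50, c(1000L, 1000L), sub_rate = 0.05,
                      indel_rate = 0, seed = 11)
  fam <- generate_family(spec)
  cons <- strsplit(attr(fam, "consensus"), "")[[1]]
  hd <- vapply(fam$sequence, function(s) {
    sum(strsplit(s, "")[[1]] != cons)
  }, numeric(1))
  mean_expect <- 1000 * 0.05
  se <- sqrt(1000 * 0.05 * 0.95 / 50)
  expect_lt(abs(mean(hd) - mean_expect), 3 * se)
})

test_that("motif placement rules plant signatures where promised", {
  tr <- generate_family(family_spec(
    "Copia", 2, c(100L, 100L), sub_rate = 0, indel_rate = 0,
    motifs = list(list(seq = "TGTCAGGCACTA", placement = "terminal_repeat")),
    seed = 3))
  s <- tr$sequence[1]
  expect_equal(substr(s, 1, 12), "TGTCAGGCACTA")
  expect_equal(substr(s, nchar(s) - 11, nchar(s)), "TGTCAGGCACTA")
  itr <- generate_family(family_spec(
    "TcMar", 1, c(100L, 100L), sub_rate = 0, indel_rate = 0,
    motifs = list(list(seq = "CAGTGG", placement = "inverted_terminal_repeat")),
    seed = 3))
  s2 <- itr$sequence[1]
  expect_equal(substr(s2, 1, 6), "CAGTGG")
  expect_equal(substr(s2, nchar(s2) - 5, nchar(s2)), "CCACTG")
  pa <- generate_family(family_spec(
    "SINE", 1, c(100L, 100L), sub_rate = 0, indel_rate = 0,
    motifs = list(list(placement = "polyA_suffix")), seed = 3))
  expect_match(pa$sequence[1], "A{15}$")
  expect_error(family_spec("P", 3, c(10L, 20L),
                           motifs = list(list(seq = paste(rep("A", 30),
                                                          collapse = ""),
                                              placement = "internal"))),
               "longer")
})

test_that("benchmark generation writes FASTA + manifest with stratified counts", {
  specs <- four_family_preset(n_copies = 200, seed = 2)
  dir <- withr::local_tempdir()
  bm <- generate_benchmark(specs, seed = 2, dir = dir)
  expect_equal(nrow(bm$seqs), 800)
  man <- split_manifest(bm$splits)
  tab <- table(man$class, man$partition)
  expect_true(all(tab[, "train"] == 150))
  expect_true(all(tab[, "validation"] == 30))
  expect_true(all(tab[, "test"] == 20))
  # round trip through the written FASTA is lossless
  back <- read_labeled_fasta(bm$paths$fasta)
  expect_equal(back$sequence, bm$seqs$sequence)
  expect_equal(back$label, bm$seqs$label)
  expect_true(file.exists(bm$paths$manifest))
  expect_true(file.exists(bm$paths$specs))
  # duplicate family names are refused
  expect_error(generate_benchmark(list(specs[[1]], specs[[1]])), "duplicate")
})

test_that("default four-family preset is well separated between families", {
  specs <- four_family_preset(n_copies = 5, seed = 7)
  fams <- lapply(specs, generate_family)
  # mean pairwise inter-family identity below 60%, via alignment as oracle
  idents <- c()
  for (i in 1:3) {
    for (j in (i + 1):4) {
      a <- Biostrings::DNAString(fams[[i]]$sequence[1])
      b <- Biostrings::DNAString(fams[[j]]$sequence[1])
      al <- Biostrings::pairwiseAlignment(a, b, type = "global")
      idents <- c(idents, Biostrings::pid(al))
    }
  }
  expect_lt(mean(idents), 60)
})

test_that("higher substitution rates degrade a k-mer composition classifier", {
  kmer_profile <- function(s) {
    v <- build_vocabulary(3)
    ch <- tokenize(s, v, 10000)[[1]]
    tabulate(ch$ids[2:ch$n] + 1L, nbins = v$n_kmers) / (ch$n - 1)
  }
  nearest_centroid_acc <- function(sub_rate) {
    # identical composition; only planted motifs and mild length cues differ,
    # so accuracy cannot saturate at both noise levels
    motifs <- c("GGATCCGGATCC", "TTAACGCGTTAA", "CACACATGTGTG", "GCGCAATTGCGC")
    specs <- lapply(1:4, function(i) {
      family_spec(paste0("fam", i), 20, c(300L, 360L),
                  motifs = list(list(seq = motifs[i], placement = "internal"),
                                list(seq = motifs[i], placement = "terminal_repeat")),
                  sub_rate = sub_rate, seed = 50 + i)
    })
    seqs <- do.call(rbind, lapply(specs, generate_family))
    X <- t(vapply(seqs$sequence, kmer_profile, numeric(125)))
    train <- seq_len(nrow(X)) %% 2 == 0
    cents <- sapply(unique(seqs$label), function(cl) {
      colMeans(X[train & seqs$label == cl, , drop = FALSE])
    })
    pred <- colnames(cents)[apply(X[!train, ], 1, function(r) {
      which.min(colSums((cents - r)^2))
    })]
    mean(pred == seqs$label[!train])
  }
  expect_gt(nearest_centroid_acc(0.02), nearest_centroid_acc(0.35))
})

test_that("the negative-control pair is two identically generated families", {
  pair <- negative_control_pair(n_copies = 6, seed = 9)
  f1 <- generate_family(pair[[1]])
  f2 <- generate_family(pair[[2]])
  expect_identical(f1$sequence, f2$sequence)
  expect_false(identical(f1$label, f2$label))
})
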