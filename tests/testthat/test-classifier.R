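test_that("chunk aggregation is the renormalized element-wise median", {
  expect_equal(aggregate_chunks(c(0.3, 0.7)), c(0.3, 0.7))
  m <- rbind(c(0.8, 0.2), c(0.8, 0.2), c(0.2, 0.8))
  expect_equal(aggregate_chunks(m), c(0.8, 0.2))
  two <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(aggregate_chunks(two), c(0.7, 0.3) / 1)
  # permuting chunks never changes the aggregate
  set.seed(2)
  probs <- t(apply(matrix(runif(15), 5, 3), 1, function(r) r / sum(r)))
  base <- aggregate_chunks(probs)
  for (i in 1:5) {
    expect_equal(aggregate_chunks(probs[sample(5), , drop = FALSE]), base)
  }
  expect_equal(sum(base), 1)
  expect_error(aggregate_chunks(matrix(numeric(0), 0, 3)), "no chunk")
})

# a deterministic "model" whose head makes class probabilities predictable:
# zero everything, then bias the head so probabilities are fixed by class
biased_model <- function(class_logits, seed = 1) {
  m <- tiny_model(num_classes = length(class_logits), dim = 8, layers = 1,
                  heads = 2, window = 64, seed = seed)
  m$params$head_W[] <- 0
  m$params$head_b <- class_logits
  m
}

test_that("classification applies the probability threshold rule", {
  classes <- c("Copia", "Gypsy", "SINE")
  # softmax(c(1.2, 0, 0)) top prob ~ 0.624: below 0.7, above 0.5
  m <- biased_model(c(1.2, 0, 0))
  seqs <- labeled_sequences(c("s1", "s2"),
                            c(random_dna(60), random_dna(80)))
  rec <- classify_sequences(seqs, m, class_names = classes, threshold = 0.7)
  expect_equal(rec$verdict, c("unclassified", "unclassified"))
  expect_equal(rec$predicted_superfamily, c("Copia", "Copia"))
  # unclassified records keep their full probability vector
  expect_equal(rowSums(as.matrix(rec[, grep("^prob_", names(rec))])),
               c(1, 1), tolerance = 1e-6, ignore_attr = TRUE)
  rec2 <- classify_sequences(seqs, m, class_names = classes, threshold = 0.5)
  expect_equal(rec2$verdict, c("classified", "classified"))
  # threshold 0 classifies everything
  rec0 <- classify_sequences(seqs, m, class_names = classes, threshold = 0)
  expect_true(all(rec0$verdict == "classified"))
  # verdict is exactly max_probability >= threshold
  expect_true(all((rec$max_probability >= 0.7) ==
                    (rec$verdict == "classified")))
})

test_that("raising the threshold never classifies more sequences", {
  set.seed(31)
  m <- tiny_model(num_classes = 4, dim = 16, layers = 1, heads = 2,
                  window = 64, seed = 3)
  seqs <- labeled_sequences(paste0("s", 1:12),
                            replicate(12, random_dna(sample(50:200, 1))))
  classes <- c("Copia", "Gypsy", "SINE", "hAT")
  counts <- vapply(c(0, 0.25, 0.3, 0.5, 0.9, 1.0000001), function(th) {
    rec <- classify_sequences(seqs, m, class_names = classes, threshold = th)
    sum(rec$verdict == "classified")
  }, numeric(1))
  expect_equal(counts[1], 12)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)
})

test_that("argmax ties break toward the first class in registry order", {
  classes <- c("Copia", "Gypsy", "SINE")
  m <- biased_model(c(0, 0, 0))        # exactly uniform probabilities
  seqs <- labeled_sequences("s1", random_dna(40))
  rec <- classify_sequences(seqs, m, class_names = classes, threshold = 0)
  expect_equal(rec$predicted_superfamily, "Copia")
  expect_equal(rec$max_probability, 1 / 3, tolerance = 1e-9)
})

test_that("predicted superfamilies roll up to Wicker orders", {
  classes <- c("Gypsy", "Helitron")
  m <- biased_model(c(5, 0))
  seqs <- labeled_sequences("s1", random_dna(40))
  rec <- classify_sequences(seqs, m, class_names = classes, threshold = 0.7)
  expect_equal(rec$predicted_superfamily, "Gypsy")
  expect_equal(rec$predicted_order, "LTR")
  m2 <- biased_model(c(0, 5))
  rec2 <- classify_sequences(seqs, m2, class_names = classes)
  expect_equal(rec2$predicted_order, "Helitron")
})

test_that("short sequences are flagged, never dropped; order is preserved", {
  classes <- c("Copia", "Gypsy", "SINE")
  m <- biased_model(c(3, 0, 0))
  seqs <- labeled_sequences(c("long1", "tiny", "long2"),
                            c(random_dna(50), "ACG", random_dna(60)))
  rec <- classify_sequences(seqs, m, class_names = classes)
  expect_equal(rec$id, c("long1", "tiny", "long2"))
  expect_equal(rec$verdict, c("classified", "too_short", "classified"))
  expect_true(is.na(rec$max_probability[2]))
})

test_that("classification TSV output is byte-identical across runs", {
  classes <- c("Copia", "Gypsy", "SINE", "hAT")
  m <- tiny_model(num_classes = 4, dim = 16, layers = 1, heads = 2,
                  window = 64, seed = 17)
  set.seed(5)
  seqs <- labeled_sequences(paste0("s", 1:6),
                            replicate(6, random_dna(150)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_labeled_fasta(seqs, f)
  rec1 <- classify_sequences(f, m, class_names = classes)
  rec2 <- classify_sequences(f, m, class_names = classes)
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_classification_tsv(rec1, t1)
  write_classification_tsv(rec2, t2)
  expect_identical(readLines(t1), readLines(t2))
  hdr <- strsplit(readLines(t1)[1], "\t")[[1]]
  expect_equal(hdr[1:5], c("id", "predicted_order", "predicted_superfamily",
                           "max_probability", "verdict"))
  expect_equal(hdr[6:9], paste0("prob_", classes))
})

test_that("a trained checkpoint classifies from its stored class order", {
  specs <- list(
    family_spec("Copia", 10, c(60L, 90L), base_probs = c(0.4, 0.1, 0.1, 0.4),
                sub_rate = 0.02, seed = 1),
    family_spec("SINE", 10, c(60L, 90L), base_probs = c(0.1, 0.4, 0.4, 0.1),
                sub_rate = 0.02, seed = 2))
  bm <- generate_benchmark(specs, seed = 3)
  m <- build_model(model_config(num_classes = 2, embedding_dim = 16,
                                num_hidden_layers = 1,
                                num_attention_heads = 2,
                                intermediate_size = 32, max_embeddings = 64,
                                local_attention_window = 16,
                                global_att_tokens = 0L, dropout = 0,
                                seed = 4))
  res <- train_model(m, bm$splits,
                     train_config(num_epochs = 2, batch_size = 8,
                                  learning_rate = 1e-3, seed = 6,
                                  augmentation = no_augmentation()))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(res$model, res$class_names, f)
  rec <- classify_sequences(bm$splits$test, f)
  expect_equal(nrow(rec), nrow(bm$splits$test))
  expect_true(all(rec$predicted_superfamily %in% c("Copia", "SINE")))
})
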