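test_that("k-mer extraction returns ordered stride-one windows", {
  km <- extract_kmers("AGCCC", 3)
  expect_equal(as.character(km), c("AGC", "GCC", "CCC"))
  expect_false(any(attr(km, "null")))
  expect_equal(as.character(extract_kmers("ACGT", 4)), "ACGT")
  km2 <- extract_kmers("ANG", 3)
  expect_equal(as.character(km2), "ANG")
  expect_true(attr(km2, "null"))
  expect_error(extract_kmers("AC", 3), "shorter")
})

test_that("vocabulary enumeration matches the k-mer index map", {
  for (k in 1:3) {
    vocab <- kmer_vocabulary(k)
    expect_length(vocab, 4^k)
    expect_false(anyDuplicated(vocab) > 0)
    ids <- lncloc:::kmer_ids(vocab, k)
    expect_equal(ids, seq_len(4^k))
  }
  expect_true(is.na(lncloc:::kmer_ids("ANG", 3)))
})

test_that("skip-gram training is seeded-deterministic with correct shapes", {
  set.seed(3)
  corpus <- lapply(1:6, function(i) random_record(paste0("r", i), 120))
  t1 <- train_kmer_embeddings(corpus, k = 3, d = 16, epochs = 2, seed = 9)
  t2 <- train_kmer_embeddings(corpus, k = 3, d = 16, epochs = 2, seed = 9)
  expect_identical(t1$vectors, t2$vectors)
  expect_equal(dim(t1$vectors), c(64L, 16L))
  expect_equal(t1$null_vector, numeric(16))
  t3 <- train_kmer_embeddings(corpus, k = 3, d = 16, epochs = 2, seed = 10)
  expect_false(identical(t1$vectors, t3$vectors))
})

test_that("unseen k-mers get seeded fallback vectors", {
  one <- list(lncloc:::new_record("a", "AAAA"))
  tab <- train_kmer_embeddings(one, k = 3, d = 8, epochs = 1, seed = 4)
  expect_equal(dim(tab$vectors), c(64L, 8L))
  expect_true(all(is.finite(tab$vectors)))
  # every k-mer other than AAA was never observed yet has a vector
  expect_true(all(rowSums(abs(tab$vectors)) > 0))
  expect_error(train_kmer_embeddings(list()), "empty corpus")
})

synthetic_table <- function(k = 1, d = 2) {
  vocab <- kmer_vocabulary(k)
  vec <- matrix(0, length(vocab), d, dimnames = list(vocab, NULL))
  structure(list(k = k, d = d, vocabulary = vocab, vectors = vec,
                 null_vector = numeric(d)), class = "lncloc_embeddings")
}

test_that("subsequence rows average the k-mer vectors in each bin", {
  # k = 1, d = 2: A -> (1, 0), C -> (0, 1), G -> (-1, 0), T -> (0, -1)
  tab <- synthetic_table()
  tab$vectors <- matrix(c(1, 0, 0, 1, -1, 0, 0, -1), 4, 2, byrow = TRUE,
                        dimnames = list(kmer_vocabulary(1), NULL))
  rec <- lncloc:::new_record("x", "AACCGGTT")
  lay <- split_subsequences(rec, n_max = 4, k = 1)
  st <- embed_sequence(rec, lay, tab)
  expect_equal(st$values[1, ], c(1, 0))       # mean of two A vectors
  expect_equal(st$values[3, ], c(-1, 0))
  # A and G cancel
  rec2 <- lncloc:::new_record("y", "AG")
  lay2 <- split_subsequences(rec2, n_max = 1, k = 1)
  expect_equal(embed_sequence(rec2, lay2, tab)$values[1, ], c(0, 0))
  # all-null bin is exactly zero, and counted nulls dilute the mean
  rec3 <- lncloc:::new_record("z", "NNN")
  lay3 <- split_subsequences(rec3, n_max = 1, k = 1)
  expect_equal(embed_sequence(rec3, lay3, tab)$values[1, ], c(0, 0))
  rec4 <- lncloc:::new_record("w", "AN")
  lay4 <- split_subsequences(rec4, n_max = 1, k = 1)
  expect_equal(embed_sequence(rec4, lay4, tab)$values[1, ], c(0.5, 0))
})

test_that("masked rows are zero and rows obey the convex-hull bound", {
  set.seed(11)
  tab <- train_kmer_embeddings(list(random_record("a", 200)), k = 2, d = 8,
                               epochs = 1, seed = 2)
  rec <- random_record("b", 61)
  lay <- split_subsequences(rec, n_max = 40, k = 2)
  st <- embed_sequence(rec, lay, tab)
  expect_true(all(st$values[!st$mask, ] == 0))
  bound <- max(abs(tab$vectors))
  expect_true(all(abs(st$values) <= bound + 1e-12))
})

test_that("reversing sequence and bins reverses the embedding rows", {
  # reversal-symmetric k = 1 table: each base maps to the same vector as
  # its reverse (identity for 1-mers), so row equivariance is exact
  tab <- synthetic_table()
  set.seed(5)
  tab$vectors <- matrix(rnorm(8), 4, 2,
                        dimnames = list(kmer_vocabulary(1), NULL))
  s <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
  rec <- lncloc:::new_record("f", s)
  rev_rec <- lncloc:::new_record("r",
    paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  lay <- split_subsequences(rec, n_max = 4, k = 1)
  a <- embed_sequence(rec, lay, tab)$values
  b <- embed_sequence(rev_rec, lay, tab)$values
  expect_equal(a[lay$n_eff:1, ], b[1:lay$n_eff, ])
})

test_that("embedding tables serialize and reload faithfully", {
  corpus <- list(random_record("a", 150, seed = 1))
  tab <- train_kmer_embeddings(corpus, k = 2, d = 6, epochs = 1, seed = 8)
  f <- withr::local_tempfile(fileext = ".vec")
  write_embeddings(tab, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- read_embeddings(f)
  expect_equal(back$vectors, tab$vectors, tolerance = 1e-12)
  expect_equal(back$k, tab$k)
  expect_equal(back$d, tab$d)
  expect_equal(back$seed, tab$seed)
})
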