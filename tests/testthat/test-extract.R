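sig <- default_signatures()
fl <- default_flanks()

make_read <- function(barcode, dish = 1, qual = NULL) {
  bases <- paste0(sig[dish], fl[["left"]], barcode, fl[["right"]])
  if (is.null(qual)) qual <- strrep("?", nchar(bases))
  data.frame(id = "r", bases = bases, quals = qual)
}

test_that("reads demultiplex by signature within the mismatch budget", {
  r_exact <- make_read(strrep("A", 30), dish = 2)
  s2_mut <- sig[2]
  substr(s2_mut, 4, 4) <- if (substr(s2_mut, 4, 4) == "A") "C" else "A"
  r_onemm <- r_exact
  r_onemm$bases <- paste0(s2_mut, substring(r_exact$bases, 11))
  r_none <- r_exact
  r_none$bases <- paste0(strrep("N", 10), substring(r_exact$bases, 11))
  dm <- demultiplex(rbind(r_exact, r_onemm, r_none), sig,
                    max_mismatches = 1)
  expect_equal(dm$dish, c(2L, 2L, NA))
})

test_that("ambiguous signature sets are rejected at configuration time", {
  bad <- c("ACGTACGTAC", "ACGTACGTAT", sig[3:4])  # Hamming distance 1
  expect_error(demultiplex(make_read(strrep("A", 30)), bad,
                           max_mismatches = 1), "ambiguous")
})

test_that("trimming applies the length window at its printed boundaries", {
  r25 <- make_read(strrep("A", 25))
  r26 <- make_read(strrep("A", 26))
  r34 <- make_read(strrep("A", 34))
  r35 <- make_read(strrep("A", 35))
  dm <- demultiplex(rbind(r25, r26, r34, r35), sig)
  tf <- trim_and_filter(dm)
  expect_equal(unname(tf$discards["length_filtered"]), 2L)
  expect_setequal(nchar(tf$candidates$barcode), c(26, 34))
})

test_that("quality rule discards only reads with >20% bases under Q20", {
  # 31-base barcode makes the read 65 bases, so 13 bases are exactly 20%
  bc <- strrep("A", 31)
  full_len <- 10 + nchar(fl[["left"]]) + 31 + nchar(fl[["right"]])
  stopifnot(full_len %% 5 == 0)
  mk_qual <- function(n_low) {
    q <- rep("?", full_len)                 # Q30
    if (n_low > 0) q[seq_len(n_low)] <- "0" # Q15 < Q20
    paste(q, collapse = "")
  }
  n20 <- full_len / 5                      # exactly 20%: retained
  n21 <- n20 + 1                           # >20%: discarded
  reads <- rbind(make_read(bc, qual = mk_qual(0)),
                 make_read(bc, qual = mk_qual(n20)),
                 make_read(bc, qual = mk_qual(n21)))
  tf <- trim_and_filter(demultiplex(reads, sig))
  expect_equal(unname(tf$discards["low_quality"]), 1L)
  expect_equal(sum(tf$candidates$reads), 2L)
})

test_that("reads with unlocatable flanks land in counted discard bins", {
  good <- make_read(strrep("G", 30))
  noleft <- good
  noleft$bases <- paste0(sig[1], strrep("T", nchar(fl[["left"]])),
                         strrep("G", 30), fl[["right"]])
  noright <- good
  noright$bases <- paste0(sig[1], fl[["left"]], strrep("G", 30),
                          strrep("T", nchar(fl[["right"]])))
  noright$quals <- strrep("?", nchar(noright$bases))
  noleft$quals <- strrep("?", nchar(noleft$bases))
  tf <- trim_and_filter(demultiplex(rbind(good, noleft, noright), sig))
  expect_equal(unname(tf$discards["no_left_flank"]), 1L)
  expect_equal(unname(tf$discards["no_right_flank"]), 1L)
  expect_equal(nrow(tf$candidates), 1L)
})

test_that("clustering collapses identical and near-identical variants", {
  s <- strrep("ACGT", 7) # 28-mer, within the length window
  v <- s
  substr(v, 5, 5) <- "T"
  cl <- cluster_barcodes(c(s, s), threshold = 0.8)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$total_reads, 2)
  cl2 <- cluster_barcodes(c(s, s, v), threshold = 0.8)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$centroid, s) # abundance-ordered centroid
  expect_equal(cl2$n_variants, 2L)
  # empty input
  expect_equal(nrow(cluster_barcodes(character(0))), 0L)
})

test_that("greedy clustering equals a brute-force oracle on 200 candidates", {
  set.seed(303)
  true_bc <- random_barcodes(40)
  variants <- unlist(lapply(true_bc, function(s) {
    v <- vapply(1:8, function(i) {
      z <- s
      pos <- sample(30, sample(1:3, 1))
      for (p in pos) substr(z, p, p) <- sample(c("A", "C", "G", "T"), 1)
      z
    }, "")
    c(s, v)
  }))
  variants <- unique(variants)
  stopifnot(length(variants) >= 200)
  cand <- data.frame(barcode = variants[1:200])
  cand$reads <- sample(1:50, nrow(cand), replace = TRUE)
  cand$dish <- 1L
  oracle <- brute_force_cluster(cand$barcode, cand$reads, 0.8)
  got <- cluster_barcodes(cand, threshold = 0.8)
  # same centroid set and same membership sizes
  expect_setequal(got$centroid, oracle$centroids)
  oracle_sizes <- sort(as.integer(table(oracle$assign)))
  expect_equal(sort(got$n_variants), oracle_sizes)
  # identical per-centroid read totals
  oracle_reads <- tapply(cand$reads[oracle$order], oracle$assign, sum)
  names(oracle_reads) <- oracle$centroids
  expect_equal(got$total_reads[order(got$centroid)],
               as.numeric(oracle_reads[order(names(oracle_reads))]))
})

test_that("threshold sweep is monotone with the expected endpoints", {
  set.seed(11)
  seqs <- random_barcodes(150)
  sw <- threshold_sweep(seqs, thresholds = c(0.05, 0.4, 0.6, 0.8, 1.0))
  expect_true(all(diff(sw$n_clusters) >= 0))
  expect_equal(sw$n_clusters[sw$threshold == 1.0], length(unique(seqs)))
  expect_equal(sw$n_clusters[sw$threshold == 0.05], 1L)
})

test_that("single-read clusters are eliminated without touching others", {
  cand <- candidates_from_sets(list(c("AAACCCGGGTTTAAACCCGGGTTTAAACCC")),
                               reads = 5L)
  lone <- data.frame(barcode = "TTTGGGCCCAAATTTGGGCCCAAATTTGGG",
                     dish = 2L, reads = 1L)
  cl <- cluster_barcodes(rbind(as.data.frame(cand), lone))
  expect_equal(nrow(cl), 2L)
  kept <- drop_singletons(cl)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$total_reads, 5)
})

test_that("cross-dish presence uses 0.1% of a quarter of total reads", {
  s <- far_apart_seqs(2)
  # barcode 1: 10,000 reads total, 2 in dish 4 -> threshold 2.5, absent
  # barcode 2: 400 reads total, 1 in dish 2  -> threshold 0.1, present
  cand <- rbind(
    data.frame(barcode = s[1], dish = 1:4, reads = c(5000, 2998, 2000, 2)),
    data.frame(barcode = s[2], dish = 1:2, reads = c(399, 1))
  )
  cl <- cluster_barcodes(cand)
  pres <- dish_presence(cl)
  row1 <- which(cl$centroid == s[1])
  row2 <- which(cl$centroid == s[2])
  expect_equal(unname(pres[row1, ]), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(pres[row2, ]), c(TRUE, TRUE, FALSE, FALSE))
  # zero reads in a dish is never presence, whatever the threshold
  expect_false(any(pres[, 3][row2]))
})

test_that("overlap table enumerates dish-membership patterns", {
  s <- far_apart_seqs(4)
  A <- s[1]; B <- s[2]; C <- s[3]; D <- s[4]
  cand <- candidates_from_sets(list(c(A, B), c(A, C), c(A, D), A))
  cl <- cluster_barcodes(cand)
  ot <- build_overlap_table(cl, spike_ins = NULL)
  expect_equal(unname(ot$exactly), c(3L, 0L, 0L, 1L))
  expect_equal(ot$shared, 1L)
  expect_equal(unname(ot$per_dish), c(2, 2, 2, 1))
  # {A},{A},{},{} -> exactly-2 = 1
  cand2 <- candidates_from_sets(list(A, A, character(0), character(0)))
  ot2 <- build_overlap_table(cluster_barcodes(cand2), spike_ins = NULL)
  expect_equal(unname(ot2$exactly), c(0L, 1L, 0L, 0L))
  expect_equal(ot2$shared, 1L)
})

test_that("every retained barcode falls in exactly one overlap bucket", {
  set.seed(77)
  lib <- generate_library(2000, 30, seed = 19)
  p <- sim_params(400, 0.6, diversity = 2000, heritability = 0.3,
                  mu = 30, si = 4)
  tr <- generate_ground_truth(p, lib, seed = 23)
  fq <- generate_fastq(tr, read_model(error_rate = 0.003, mean_reads = 20),
                       dir = tempfile(), seed = 29)
  res <- extract_barcodes(fq$fastq)
  expect_equal(sum(res$overlap$exactly), nrow(res$overlap$patterns))
  expect_true(all(table(res$overlap$patterns$centroid) == 1))
  # count(>= k) non-increasing in k
  ge <- rev(cumsum(rev(res$overlap$exactly)))
  expect_true(all(diff(ge) <= 0))
})
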