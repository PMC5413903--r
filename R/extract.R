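#' Read a FASTQ file into a read table
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a
#' data.table with one row per read.
#'
#' @param path FASTQ file path(s).
#' @return data.table with columns `id`, `bases`, `quals`.
#' @export
read_fastq <- function(path) {
  parts <- lapply(path, function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq",
                                      with.qualities = TRUE)
    data.table(id = names(x), bases = as.character(x),
               quals = as.character(S4Vectors::mcols(x)$qualities))
  })
  rbindlist(parts)
}

check_signatures <- function(signatures, max_mismatches) {
  if (length(signatures) < 2) return(invisible(signatures))
  mm <- prefix_mismatches(signatures, signatures)
  off <- mm[upper.tri(mm)]
  if (any(is.na(off)) || any(off <= max_mismatches)) {
    stop(sprintf(
      "ambiguous signature set: pairwise distances must exceed %d",
      max_mismatches), call. = FALSE)
  }
  invisible(signatures)
}

#' Demultiplex reads by dish signature
#'
#' Assigns each read to the dish whose 10-base signature matches the read
#' prefix within `max_mismatches` substitutions. Reads matching no
#' signature -- or, defensively, more than one -- are left unassigned.
#'
#' @param reads A [read_fastq()] table (or character vector of sequences).
#' @param signatures Dish signature sequences (pairwise Hamming distance
#'   must exceed `max_mismatches`; checked).
#' @param max_mismatches Substitutions tolerated in the signature
#'   (default 1).
#' @return The read table with an integer `dish` column (`NA` =
#'   unassigned).
#' @export
demultiplex <- function(reads, signatures = default_signatures(),
                        max_mismatches = 1) {
  if (is.character(reads)) reads <- data.table(bases = reads)
  reads <- as.data.table(reads)
  check_signatures(signatures, max_mismatches)
  mm <- prefix_mismatches(reads$bases, signatures)
  mm[is.na(mm)] <- nchar(signatures)[col(mm)][is.na(mm)]
  hits <- mm <= max_mismatches
  n_hit <- rowSums(hits)
  dish <- max.col(-mm, ties.method = "first")
  dish[n_hit != 1L] <- NA_integer_
  reads$dish <- dish
  reads
}

#' Trim flanks and filter candidate barcodes
#'
#' Removes the known flanking sequences around the barcode (exact match
#' first, then a one-mismatch fallback), discards low-quality reads
#' (strictly more than 20% of bases below Q20 by default) and barcodes
#' outside the 26-34 bp length window. Reads whose flanks cannot be
#' located are routed to counted discard bins, not errors.
#'
#' @param reads A demultiplexed read table (columns `bases`, `quals`,
#'   `dish`); unassigned reads (`dish` NA) are dropped into the
#'   `unassigned` bin.
#' @param left_flank,right_flank Flank sequences (non-empty).
#' @param min_len,max_len Retained barcode length window (default 26-34).
#' @param quality_min Phred threshold defining a low-quality base
#'   (default 20).
#' @param max_low_fraction A read is discarded when its fraction of bases
#'   below `quality_min` strictly exceeds this (default 0.20; exactly 20%
#'   is retained).
#' @param max_flank_mm Mismatches tolerated in each flank (default 1).
#' @return List with `candidates` (data.table `barcode`, `dish`, `reads` =
#'   read count) and `discards` (named counts per bin).
#' @export
trim_and_filter <- function(reads, left_flank = default_flanks()[["left"]],
                            right_flank = default_flanks()[["right"]],
                            min_len = 26, max_len = 34,
                            quality_min = 20, max_low_fraction = 0.20,
                            max_flank_mm = 1) {
  stopifnot(nzchar(left_flank), nzchar(right_flank))
  reads <- as.data.table(reads)
  if (is.null(reads$dish)) reads$dish <- 1L
  discards <- c(unassigned = 0L, low_quality = 0L, no_left_flank = 0L,
                no_right_flank = 0L, length_filtered = 0L)

  keep <- !is.na(reads$dish)
  discards["unassigned"] <- sum(!keep)
  reads <- reads[keep, ]

  if (!is.null(reads$quals)) {
    lowfrac <- low_quality_fraction(reads$quals, quality_min)
    ok <- lowfrac <= max_low_fraction + 1e-12
    discards["low_quality"] <- sum(!ok)
    reads <- reads[ok, ]
  }

  lpos <- find_flank(reads$bases, left_flank, max_flank_mm, 1L)
  ok <- lpos > 0L
  discards["no_left_flank"] <- sum(!ok)
  reads <- reads[ok, ]
  lpos <- lpos[ok]

  bc_start <- lpos + nchar(left_flank)
  rpos <- find_flank(reads$bases, right_flank, max_flank_mm, bc_start)
  ok <- rpos > 0L
  discards["no_right_flank"] <- sum(!ok)
  reads <- reads[ok, ]
  bc_start <- bc_start[ok]
  rpos <- rpos[ok]

  barcode <- substr(reads$bases, bc_start, rpos - 1L)
  len <- nchar(barcode)
  ok <- len >= min_len & len <= max_len
  discards["length_filtered"] <- sum(!ok)

  cand <- data.table(barcode = barcode[ok], dish = reads$dish[ok])
  candidates <- cand[, list(reads = .N), by = c("barcode", "dish")]
  list(candidates = candidates, discards = discards)
}

#' Cluster candidate barcodes by sequence identity
#'
#' Greedy abundance-ordered centroid clustering: candidates are sorted by
#' total read count (ties broken lexicographically); each joins the first
#' centroid whose normalized identity, `1 - editdist / max(length)`, is at
#' least `threshold`, otherwise it founds a new cluster.
#'
#' @param candidates data.table with columns `barcode` and `reads`
#'   (optionally `dish` for per-dish read sums; a character vector is
#'   taken as one read each).
#' @param threshold Identity threshold in `(0, 1]` (default 0.8).
#' @param n_dishes Number of dish columns to report (default 4).
#' @return A `barcode_clusters` data.table: `centroid`, per-dish read
#'   counts `reads_d1..`, `total_reads`, `n_variants` (distinct member
#'   sequences).
#' @export
cluster_barcodes <- function(candidates, threshold = 0.8, n_dishes = 4) {
  if (is.character(candidates)) {
    candidates <- data.table(barcode = candidates, dish = 1L, reads = 1L)
  }
  candidates <- as.data.table(candidates)
  if (is.null(candidates$dish)) candidates$dish <- 1L
  if (is.null(candidates$reads)) candidates$reads <- 1L
  if (!nrow(candidates)) {
    return(empty_clusters(n_dishes))
  }
  totals <- candidates[, list(total = sum(reads)), by = "barcode"]
  setorder(totals, -total, barcode)
  assign <- greedy_cluster_cpp(totals$barcode, threshold)
  totals$cluster <- assign
  centroids <- totals$barcode[!duplicated(assign)]
  centroid_of <- character(max(assign))
  centroid_of[totals$cluster[!duplicated(assign)]] <- centroids

  candidates$cluster <- totals$cluster[match(candidates$barcode,
                                             totals$barcode)]
  per_dish <- candidates[, list(reads = sum(reads)),
                         by = c("cluster", "dish")]
  out <- data.table(cluster = seq_len(max(assign)),
                    centroid = centroid_of[seq_len(max(assign))])
  for (d in seq_len(n_dishes)) {
    col <- per_dish[per_dish$dish == d, ]
    v <- integer(nrow(out))
    v[col$cluster] <- col$reads
    out[[paste0("reads_d", d)]] <- v
  }
  out$total_reads <- rowSums(as.matrix(
    out[, paste0("reads_d", seq_len(n_dishes)), with = FALSE]))
  nv <- totals[, .N, by = "cluster"]
  out$n_variants <- 0L
  out$n_variants[nv$cluster] <- nv$N
  out$cluster <- NULL
  setattr(out, "threshold", threshold)
  setattr(out, "class", c("barcode_clusters", class(out)))
  out[]
}

empty_clusters <- function(n_dishes) {
  out <- data.table(centroid = character(0))
  for (d in seq_len(n_dishes)) out[[paste0("reads_d", d)]] <- integer(0)
  out$total_reads <- numeric(0)
  out$n_variants <- integer(0)
  setattr(out, "class", c("barcode_clusters", class(out)))
  out
}

#' Sweep the clustering identity threshold
#'
#' Recomputes the cluster count over a grid of identity thresholds. On
#' error-free data the count plateaus once the threshold exceeds the
#' typical identity between unrelated barcodes; with sequencing errors a
#' further rise past ~0.9 signals noise being split off as spurious
#' barcodes.
#'
#' @param candidates As in [cluster_barcodes()].
#' @param thresholds Ascending vector of identity thresholds.
#' @return data.frame with `threshold` and `n_clusters`.
#' @export
threshold_sweep <- function(candidates,
                            thresholds = seq(0.5, 1, by = 0.1)) {
  stopifnot(!is.unsorted(thresholds))
  n <- vapply(thresholds, function(t) {
    nrow(cluster_barcodes(candidates, threshold = t))
  }, integer(1))
  data.frame(threshold = thresholds, n_clusters = n)
}

#' Remove single-read clusters
#'
#' Barcodes supported by only one read in total are eliminated as noise.
#'
#' @param clusters A [cluster_barcodes()] table.
#' @return The filtered table.
#' @export
drop_singletons <- function(clusters) {
  clusters[clusters$total_reads > 1L, ]
}

#' Per-dish presence calls for clustered barcodes
#'
#' A barcode counts as present in a dish only if that dish's read count is
#' at least 0.1% of the expected count under even representation (the
#' expected count being a quarter of all reads carrying the barcode).
#' This suppresses low-level index hopping / carry-over.
#'
#' @param clusters A [cluster_barcodes()] table.
#' @param n_dishes Number of dishes.
#' @param min_fraction Presence threshold as a fraction of the expected
#'   per-dish reads (default 0.001).
#' @return Logical matrix, rows = clusters, columns = dishes.
#' @export
dish_presence <- function(clusters, n_dishes = 4, min_fraction = 0.001) {
  m <- as.matrix(clusters[, paste0("reads_d", seq_len(n_dishes)),
                          with = FALSE])
  expected <- clusters$total_reads / n_dishes
  present <- m >= pmax(min_fraction * expected, .Machine$double.eps) &
    m > 0
  colnames(present) <- seq_len(n_dishes)
  present
}

#' Overlap table of barcodes across dishes
#'
#' Counts distinct barcodes present in exactly 1, 2, 3 and 4 dishes
#' (presence per [dish_presence()]); barcodes in two or more dishes are
#' "shared". Spike-in control barcodes are excluded from the overlap
#' counts and reported separately with their per-dish read counts and
#' ranks.
#'
#' @param clusters A filtered [cluster_barcodes()] table.
#' @param spike_ins Character vector of control barcode sequences to set
#'   aside (matched at `spike_identity` to tolerate centroid errors), or
#'   `NULL`.
#' @param n_dishes Number of dishes.
#' @param min_fraction Passed to [dish_presence()].
#' @param spike_identity Identity for recognizing spike-in centroids
#'   (default 0.9).
#' @return An `overlap_table`: `exactly` (counts for 1..4 dishes),
#'   `shared`, `per_dish` (distinct barcodes per dish), `patterns`
#'   (per-barcode dish membership), `spike_ins` (per control and dish:
#'   reads and within-dish rank among controls).
#' @export
build_overlap_table <- function(clusters, spike_ins = control_barcodes(),
                                n_dishes = 4, min_fraction = 0.001,
                                spike_identity = 0.9) {
  spike_report <- NULL
  if (!is.null(spike_ins) && nrow(clusters)) {
    is_spike <- rep(FALSE, nrow(clusters))
    spike_of <- rep(NA_character_, nrow(clusters))
    for (s in spike_ins) {
      k <- floor((1 - spike_identity) *
                   pmax(nchar(clusters$centroid), nchar(s)))
      d <- edit_distance_bounded(clusters$centroid,
                                 rep(s, nrow(clusters)), max(k, 0))
      hit <- !is.na(d) & d <= k
      spike_of[hit & !is_spike] <- s
      is_spike <- is_spike | hit
    }
    if (any(is_spike)) {
      sp <- clusters[is_spike, ]
      sp$spike_seq <- spike_of[is_spike]
      long <- rbindlist(lapply(seq_len(n_dishes), function(d) {
        data.table(spike_seq = sp$spike_seq, dish = d,
                   reads = sp[[paste0("reads_d", d)]])
      }))
      long <- long[, list(reads = sum(reads)), by = c("spike_seq", "dish")]
      long[, rank := rank(-reads, ties.method = "min"), by = "dish"]
      spike_report <- long
    }
    clusters <- clusters[!is_spike, ]
  }
  if (!nrow(clusters)) {
    exactly <- setNames(integer(n_dishes), seq_len(n_dishes))
    return(structure(list(exactly = exactly, shared = 0L,
                          per_dish = integer(n_dishes),
                          patterns = data.table(centroid = character(0),
                                                pattern = character(0)),
                          spike_ins = spike_report),
                     class = "overlap_table"))
  }
  present <- dish_presence(clusters, n_dishes, min_fraction)
  ndish <- rowSums(present)
  keep <- ndish > 0
  exactly <- tabulate(ndish[keep], nbins = n_dishes)
  names(exactly) <- seq_len(n_dishes)
  patterns <- data.table(
    centroid = clusters$centroid[keep],
    pattern = apply(present[keep, , drop = FALSE], 1, function(z) {
      paste(which(z), collapse = ",")
    }),
    n_dishes = ndish[keep]
  )
  structure(list(
    exactly = exactly,
    shared = sum(exactly[-1L]),
    per_dish = colSums(present),
    patterns = patterns,
    spike_ins = spike_report
  ), class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("overlap_table\n")
  cat("  barcodes in exactly k dishes:",
      paste(sprintf("k=%s: %d", names(x$exactly), x$exactly),
            collapse = ", "), "\n")
  cat("  shared (>= 2 dishes):", x$shared, "\n")
  cat("  distinct barcodes per dish:", paste(x$per_dish, collapse = ", "),
      "\n")
  if (!is.null(x$spike_ins)) {
    cat("  spike-in controls detected:",
        length(unique(x$spike_ins$spike_seq)), "\n")
  }
  invisible(x)
}

#' Full barcode-recovery pipeline
#'
#' FASTQ to overlap table: demultiplex by dish signature, trim flanks,
#' apply quality/length filters, cluster at the identity threshold, drop
#' single-read clusters, apply the cross-dish presence filter and build
#' the overlap table.
#'
#' @param fastq FASTQ path(s).
#' @param signatures,max_mismatches Passed to [demultiplex()].
#' @param left_flank,right_flank Passed to [trim_and_filter()].
#' @param threshold Clustering identity threshold (default 0.8).
#' @param spike_ins Control barcodes to set aside (default the two known
#'   controls).
#' @param n_dishes Number of dishes.
#' @return List with `clusters` (post-singleton-filter), `overlap`
#'   (the [build_overlap_table()]), and `discards`.
#' @export
extract_barcodes <- function(fastq, signatures = default_signatures(),
                             max_mismatches = 1,
                             left_flank = default_flanks()[["left"]],
                             right_flank = default_flanks()[["right"]],
                             threshold = 0.8,
                             spike_ins = control_barcodes(),
                             n_dishes = 4) {
  reads <- read_fastq(fastq)
  reads <- demultiplex(reads, signatures, max_mismatches)
  tf <- trim_and_filter(reads, left_flank, right_flank)
  clusters <- cluster_barcodes(tf$candidates, threshold, n_dishes)
  clusters <- drop_singletons(clusters)
  overlap <- build_overlap_table(clusters, spike_ins, n_dishes)
  list(clusters = clusters, overlap = overlap, discards = tf$discards)
}
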