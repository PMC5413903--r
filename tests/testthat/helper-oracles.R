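# Independent re-implementations used as oracles; deliberately naive.

random_barcodes <- function(n, len = 30) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# brute-force greedy centroid clustering via utils::adist
brute_force_cluster <- function(barcodes, counts, threshold) {
  ord <- order(-counts, barcodes)
  seqs <- barcodes[ord]
  centroids <- character(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (c in seq_along(centroids)) {
      ml <- max(nchar(seqs[i]), nchar(centroids[c]))
      idy <- 1 - utils::adist(seqs[i], centroids[c])[1, 1] / ml
      if (idy >= threshold - 1e-12) { hit <- c; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, seqs[i])
      hit <- length(centroids)
    }
    assign[i] <- hit
  }
  list(order = ord, assign = assign, centroids = centroids)
}

# Kruskal-Wallis H via stats::kruskal.test as the reference
reference_kw <- function(groups) {
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

# hand-built two-cell clone population for targeted reprogramming tests
two_sister_population <- function(dishes = c(1L, 2L)) {
  structure(list(
    clone = c(1L, 1L),
    class = c(2L, 2L),
    dish = dishes,
    reprog = c(FALSE, FALSE),
    stage1 = c(FALSE, FALSE),
    n_clones = 1L,
    clone_barcodes = list(clone = 1L, barcode = 7L)
  ), class = "cell_population")
}

# candidates table from explicit per-dish barcode sets (>= 2 reads each so
# the singleton filter keeps everything)
candidates_from_sets <- function(dish_sets, reads = 10L) {
  rows <- lapply(seq_along(dish_sets), function(d) {
    if (!length(dish_sets[[d]])) return(NULL)
    data.frame(barcode = dish_sets[[d]], dish = d, reads = reads)
  })
  data.table::rbindlist(rows)
}

# well-separated sequences for overlap-table enumeration tests
far_apart_seqs <- function(n, len = 30, seed = 404) {
  set.seed(seed)
  repeat {
    s <- random_barcodes(n, len)
    if (length(unique(s)) == n &&
        all(utils::adist(s)[upper.tri(diag(n))] > (1 - 0.8) * len)) {
      return(s)
    }
  }
}

# per-dish reprogrammed barcode-sequence sets from a ground truth
truth_dish_sets <- function(truth) {
  cells <- truth$cells[truth$cells$reprogrammed, ]
  merged <- merge(cells[, c("clone_id", "dish")], truth$integrations,
                  by = "clone_id", allow.cartesian = TRUE)
  lapply(1:4, function(d) {
    sort(unique(merged$barcode_seq[merged$dish == d]))
  })
}
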