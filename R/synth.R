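#' The two spike-in control barcode sequences
#'
#' Barcodes of the two clonal control cell lines added in known cell
#' numbers to every dish to monitor PCR amplification and sequencing
#' fidelity.
#'
#' @return Character vector of two 30-base barcodes.
#' @export
control_barcodes <- function() {
  c("TGCTGACCGCAGGTACGACGCCGAAGGATG",
    "GGACGCGCCTACTACTTCGCGAGCATCCTG")
}

#' Default dish signature sequences
#'
#' Four 10-base signatures prepended to reads during amplification so all
#' four dish libraries can be pooled in one sequencing run. Pairwise
#' Hamming distances are >= 7, far above the default one-mismatch
#' demultiplexing tolerance.
#'
#' @return Character vector of four 10-mers.
#' @export
default_signatures <- function() {
  c("ACGTACGTAC", "CATGCATGCA", "GTACTGCAGT", "TGCAATACTG")
}

#' Default barcode flanking sequences
#'
#' Constant vector context on either side of the 30-base random barcode,
#' taken from the barcode linker design (M13/universal-primer region on
#' the left, linker on the right).
#'
#' @return Named character vector with elements `left` and `right`.
#' @export
default_flanks <- function() {
  c(left = "ACGACGGCCAGT", right = "GGTCATAGCTGT")
}

int_to_seq <- function(idx, length) {
  # map 1-based integers to base-4 DNA words of the given length
  bases <- c("A", "C", "G", "T")
  idx <- idx - 1
  out <- matrix("", length(idx), length)
  for (p in length:1) {
    out[, p] <- bases[idx %% 4 + 1]
    idx <- idx %/% 4
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

#' Generate a random barcode library
#'
#' Draws `diversity` unique uniform-random DNA sequences of the given
#' length.
#'
#' @param diversity Number of unique barcodes D (must not exceed
#'   `4^barcode_length`).
#' @param barcode_length Barcode length in bases (default 30).
#' @param seed Optional seed; fixed seed reproduces the same library.
#' @return A `barcode_library`: list with `sequences`, `diversity`,
#'   `barcode_length`.
#' @export
generate_library <- function(diversity, barcode_length = 30, seed = NULL) {
  stopifnot(diversity >= 1, barcode_length >= 1)
  space <- 4^barcode_length
  if (diversity > space) {
    stop(sprintf(
      "diversity %s exceeds the 4^%d = %s possible sequences",
      format(diversity, big.mark = ","), barcode_length,
      format(space, big.mark = ",")), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (space <= 2^31 - 1 && diversity > space / 16) {
    # dense request: sample indices without replacement and decode
    seqs <- int_to_seq(sample.int(space, diversity), barcode_length)
  } else {
    seqs <- character(0)
    need <- diversity
    while (need > 0) {
      m <- matrix(sample(c("A", "C", "G", "T"), need * barcode_length,
                         replace = TRUE), nrow = need)
      cand <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
      seqs <- unique(c(seqs, cand))
      need <- diversity - length(seqs)
    }
  }
  structure(list(sequences = seqs, diversity = diversity,
                 barcode_length = barcode_length),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("barcode_library: %s sequences of %d bp\n",
              format(x$diversity, big.mark = ","), x$barcode_length))
  invisible(x)
}

#' Ground truth for a synthetic split-dish experiment
#'
#' Runs the generative model (infection, division, plating, loss,
#' reprogramming with heritable sister fate) once and keeps the full
#' per-cell record, with barcode ids mapped to sequences from a library,
#' plus spike-in control records. This is the manifest against which the
#' extraction pipeline can be validated read-for-read.
#'
#' @param params A [sim_params()] object; its `diversity` is overridden by
#'   the library size.
#' @param library A [generate_library()] object.
#' @param spike_in_cells Cells per dish for each control barcode (same in
#'   every dish); default 100 for the first control and 400 for the
#'   second. Use `NULL` for no spike-ins.
#' @param seed Optional seed.
#' @return A `ground_truth` list: `cells` (one row per surviving cell:
#'   clone_id, progeny_class, dish, reprogrammed, stage1), `integrations`
#'   (clone_id, barcode_id, barcode_seq), `spike_ins`
#'   (barcode_seq, dish, cells), `overlaps` (the true
#'   [count_overlaps()]), and the parameters.
#' @export
generate_ground_truth <- function(params, library,
                                  spike_in_cells = c(100, 400),
                                  seed = NULL) {
  stopifnot(inherits(params, "sim_params"),
            inherits(library, "barcode_library"))
  if (!is.null(seed)) set.seed(seed)
  pop <- init_population(params$n_seeded, params$moi, library$diversity,
                         integration_model = params$integration_model)
  pop <- divide_cells(pop, params$progeny_prob)
  pop <- plate_cells(pop, params$n_dishes)
  pop <- cull_cells(pop, params$loss)
  pop <- reprogram_cells(pop, dish_targets = params$dish_targets,
                         mu = params$mu, si = params$si,
                         heritability = params$heritability,
                         n_dishes = params$n_dishes,
                         quota = params$quota,
                         on_infeasible = params$on_infeasible)
  cells <- data.table(
    cell_id = seq_along(pop$clone),
    clone_id = pop$clone,
    progeny_class = pop$class,
    dish = pop$dish,
    reprogrammed = pop$reprog,
    stage1 = pop$stage1
  )
  used <- sort(unique(pop$clone_barcodes$clone[
    pop$clone_barcodes$clone %in% pop$clone]))
  integrations <- data.table(
    clone_id = pop$clone_barcodes$clone,
    barcode_id = pop$clone_barcodes$barcode
  )
  integrations <- integrations[integrations$clone_id %in% used, ]
  integrations$barcode_seq <- library$sequences[integrations$barcode_id]
  spike_ins <- NULL
  if (!is.null(spike_in_cells)) {
    ctrl <- control_barcodes()
    if (length(spike_in_cells) > length(ctrl)) {
      stop("at most ", length(ctrl), " spike-in controls are available",
           call. = FALSE)
    }
    spike_ins <- data.table(
      barcode_seq = rep(ctrl[seq_along(spike_in_cells)],
                        each = params$n_dishes),
      dish = rep(seq_len(params$n_dishes), length(spike_in_cells)),
      cells = rep(spike_in_cells, each = params$n_dishes)
    )
  }
  structure(list(cells = cells, integrations = integrations,
                 spike_ins = spike_ins,
                 overlaps = attr(pop, "overlaps"),
                 params = params),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d cells (%d reprogrammed) in %d dishes, %d clones\n",
    nrow(x$cells), sum(x$cells$reprogrammed), x$params$n_dishes,
    length(unique(x$cells$clone_id))))
  if (!is.null(x$spike_ins)) {
    cat(sprintf("  spike-ins: %d controls per dish\n",
                length(unique(x$spike_ins$barcode_seq))))
  }
  invisible(x)
}

#' Read-generation model
#'
#' Parameters of the PCR + sequencing noise applied when turning a ground
#' truth into FASTQ reads.
#'
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param pcr_sigma Log-normal dispersion (sdlog) of the per-(barcode,
#'   dish) amplification factor; 0 disables PCR bias. The factor is
#'   mean-1 (`exp(sigma*Z - sigma^2/2)`).
#' @param mean_reads Mean reads per contributing cell (>= 1).
#' @param indel_rate Per-base probability of an indel (half deletions,
#'   half single-base insertions); default 0 (substitution-only).
#' @param low_quality_fraction Fraction of reads given degraded quality
#'   strings (30% of bases at Q2) to exercise the quality filter.
#' @return A `read_model` list.
#' @export
read_model <- function(error_rate = 0, pcr_sigma = 0, mean_reads = 50,
                       indel_rate = 0, low_quality_fraction = 0) {
  stopifnot(error_rate >= 0, error_rate < 1, pcr_sigma >= 0,
            mean_reads >= 1, indel_rate >= 0, indel_rate < 1,
            low_quality_fraction >= 0, low_quality_fraction <= 1)
  structure(list(error_rate = error_rate, pcr_sigma = pcr_sigma,
                 mean_reads = mean_reads, indel_rate = indel_rate,
                 low_quality_fraction = low_quality_fraction),
            class = "read_model")
}

mutate_substitutions <- function(seqs, rate) {
  if (rate == 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  m <- strsplit(seqs, "", fixed = TRUE)
  flat <- unlist(m, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit)) {
    # substitute with a uniformly chosen *different* base
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- ceiling(runif(length(hit)) * 3)
    flat[hit] <- mapply(function(b, p) alt[[b]][p], flat[hit], pick,
                        USE.NAMES = FALSE)
  }
  grp <- factor(rep.int(seq_along(seqs), lens), levels = seq_along(seqs))
  unname(vapply(split(flat, grp), paste, "", collapse = ""))
}

mutate_indels <- function(seqs, rate) {
  if (rate == 0 || !length(seqs)) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    u <- runif(length(v))
    del <- u < rate / 2
    ins <- u >= rate / 2 & u < rate
    if (any(ins)) {
      v[ins] <- paste0(sample(bases, sum(ins), replace = TRUE), v[ins])
    }
    paste(v[!del | ins], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Write synthetic FASTQ reads for a ground-truth experiment
#'
#' Each read is `signature + left flank + barcode (with substitution and
#' optional indel errors) + right flank`. Read multiplicity per (barcode,
#' dish) is `max(1, round(n_cells * mean_reads * PCR factor))`. Spike-in
#' controls contribute reads in proportion to their cell numbers. A
#' ground-truth manifest TSV is written alongside.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param model A [read_model()].
#' @param dir Output directory (created if missing).
#' @param signatures Four distinct 10-base dish signatures.
#' @param flanks Named character vector with `left` and `right` flanks.
#' @param split_by_dish Write one FASTQ per dish instead of a single
#'   multiplexed file.
#' @param seed Optional seed.
#' @return List with `fastq` (file path(s)), `manifest` (path of the TSV:
#'   clone_id, barcode_seq, dish, n_reads, reprogrammed, progeny_class,
#'   spikein_flag), and the manifest `table`.
#' @export
generate_fastq <- function(truth, model = read_model(), dir = tempfile(),
                           signatures = default_signatures(),
                           flanks = default_flanks(),
                           split_by_dish = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(model, "read_model"))
  if (anyDuplicated(signatures)) {
    stop("dish signatures must be pairwise distinct", call. = FALSE)
  }
  if (!all(nzchar(flanks[c("left", "right")]))) {
    stop("flanks must be non-empty", call. = FALSE)
  }
  if (length(signatures) < truth$params$n_dishes) {
    stop("need one signature per dish", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # contributing cell counts per (barcode sequence, dish)
  cells <- truth$cells[truth$cells$reprogrammed, ]
  tab <- merge(cells[, c("clone_id", "dish")], truth$integrations,
               by = "clone_id", allow.cartesian = TRUE)
  counts <- tab[, list(n_cells = .N), by = c("barcode_seq", "dish")]
  counts$clone_id <- tab$clone_id[match(
    paste(counts$barcode_seq, counts$dish),
    paste(tab$barcode_seq, tab$dish))]
  counts$progeny_class <- cells$progeny_class[match(
    paste(counts$clone_id, counts$dish),
    paste(cells$clone_id, cells$dish))]
  counts$spikein_flag <- FALSE
  if (!is.null(truth$spike_ins)) {
    sp <- data.table(barcode_seq = truth$spike_ins$barcode_seq,
                     dish = truth$spike_ins$dish,
                     n_cells = truth$spike_ins$cells,
                     clone_id = NA_integer_,
                     progeny_class = NA_integer_,
                     spikein_flag = TRUE)
    counts <- rbindlist(list(counts, sp), use.names = TRUE)
  }
  pcr <- if (model$pcr_sigma > 0) {
    exp(rnorm(nrow(counts), 0, model$pcr_sigma) - model$pcr_sigma^2 / 2)
  } else rep(1, nrow(counts))
  counts$n_reads <- pmax(1L, as.integer(round(
    counts$n_cells * model$mean_reads * pcr)))
  setorder(counts, dish, barcode_seq)

  # expand to reads and apply sequencing noise to the barcode segment
  bc <- rep.int(counts$barcode_seq, counts$n_reads)
  dish <- rep.int(counts$dish, counts$n_reads)
  bc <- mutate_substitutions(bc, model$error_rate)
  bc <- mutate_indels(bc, model$indel_rate)
  reads <- paste0(signatures[dish], flanks[["left"]], bc,
                  flanks[["right"]])
  quals <- strrep("?", nchar(reads)) # constant Q30
  if (model$low_quality_fraction > 0 && length(reads)) {
    n_low <- round(model$low_quality_fraction * length(reads))
    if (n_low > 0) {
      low_idx <- sample(length(reads), n_low)
      quals[low_idx] <- vapply(nchar(reads[low_idx]), function(l) {
        q <- rep("?", l)
        q[sample(l, ceiling(0.3 * l))] <- "#" # Q2
        paste(q, collapse = "")
      }, "")
    }
  }
  ids <- sprintf("read%07d dish=%d", seq_along(reads), dish)

  write_one <- function(path, sel) {
    x <- Biostrings::DNAStringSet(reads[sel])
    names(x) <- ids[sel]
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals[sel]))
    path
  }
  if (split_by_dish) {
    fastq <- vapply(seq_len(truth$params$n_dishes), function(d) {
      write_one(file.path(dir, sprintf("dish%d.fastq", d)), dish == d)
    }, "")
  } else {
    fastq <- write_one(file.path(dir, "reads.fastq"),
                       seq_along(reads))
  }
  manifest <- counts[, c("clone_id", "barcode_seq", "dish", "n_reads",
                         "progeny_class", "spikein_flag")]
  manifest$reprogrammed <- !manifest$spikein_flag
  manifest <- manifest[, c("clone_id", "barcode_seq", "dish", "n_reads",
                           "reprogrammed", "progeny_class",
                           "spikein_flag")]
  manifest_path <- file.path(dir, "manifest.tsv")
  fwrite(manifest, manifest_path, sep = "\t")
  list(fastq = fastq, manifest = manifest_path, table = manifest)
}
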