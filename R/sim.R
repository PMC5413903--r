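#' Default progeny-count distribution
#'
#' Probability that a starting fibroblast produces k = 0..8 progeny during
#' the pre-splitting culture window (roughly one population doubling).
#' Chosen as a realistic time-lapse-style distribution: most cells divide
#' once, a minority dies or does not divide, a tail divides twice or more;
#' cells with more than four progeny make up 10% of the population.
#' Replace with experiment-specific frequencies when available.
#'
#' @return Named numeric vector of probabilities for k = 0..8, summing
#'   to 1.
#' @export
default_progeny_prob <- function() {
  p <- c(0.05, 0.15, 0.40, 0.15, 0.15, 0.05, 0.03, 0.01, 0.01)
  names(p) <- 0:8
  p
}

check_progeny_prob <- function(p) {
  if (length(p) != 9 || any(p < 0)) {
    stop("progeny_prob must be 9 non-negative probabilities for k = 0..8",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("progeny_prob must sum to 1 (within 1e-9)", call. = FALSE)
  }
  p
}

#' Parameters of the split-dish lineage simulation
#'
#' Bundles every input of the stochastic model: seeding and infection,
#' library diversity, the progeny-count distribution, loss of material,
#' the per-dish reprogrammed-barcode targets and the heritability level.
#'
#' @param n_seeded Number of cells plated before transduction.
#' @param moi Multiplicity of infection of the barcoded virus (> 0).
#' @param diversity Number of distinct barcodes in the viral library
#'   (default 8e6).
#' @param progeny_prob Probabilities of producing 0..8 progeny
#'   (length 9, sums to 1).
#' @param loss Loss-of-material fraction `d` in `[0, 1)`: each dish loses
#'   `round(d * n)` cells before reprogramming.
#' @param heritability Either a single probability `h` in `[0, 1]` that a
#'   sibling of a reprogrammed cell is itself reprogrammed, or a numeric
#'   vector named by progeny class (`"0"`..`"8"`) for
#'   proliferation-dependent heritability; unnamed classes default to the
#'   entry named `"default"` (or 0).
#' @param dish_targets Optional integer vector of length `n_dishes`: the
#'   exact number of distinct barcodes to reprogramme per dish
#'   (`BA_1..BA_4`). When `NULL`, targets are drawn per replicate from a
#'   Gaussian with mean `mu` and sd `si`, rounded and clamped at 0.
#' @param mu,si Gaussian parameters for the per-dish targets (used when
#'   `dish_targets` is `NULL`); typically the mean and sd of the observed
#'   per-dish distinct-barcode counts.
#' @param n_dishes Number of dishes cells are split into (default 4).
#' @param integration_model `"ztpois"` draws the number of barcode
#'   integrations per infected cell from a zero-truncated Poisson(moi);
#'   `"single"` forces exactly one integration per cell (the reference
#'   mode for analytic checks).
#' @param correct_multi If `TRUE`, additionally report shared counts
#'   divided by the mean integrations per infected cell,
#'   `moi / (1 - exp(-moi))` -- an approximate post-hoc correction for
#'   multi-integration inflation.
#' @param on_infeasible What to do when a dish target exceeds the distinct
#'   barcodes available in that dish: `"clamp"` (default; the target is
#'   clamped and the replicate flagged infeasible) or `"error"`.
#' @param quota Quota semantics for [reprogram_cells()]: `"final"`
#'   (default) or `"stage1"`.
#' @return A list of validated parameters, class `sim_params`.
#' @export
sim_params <- function(n_seeded, moi, diversity = 8e6,
                       progeny_prob = default_progeny_prob(),
                       loss = 0, heritability = 0,
                       dish_targets = NULL, mu = NULL, si = NULL,
                       n_dishes = 4,
                       integration_model = c("ztpois", "single"),
                       correct_multi = FALSE,
                       quota = c("final", "stage1"),
                       on_infeasible = c("clamp", "error")) {
  stopifnot(n_seeded >= 1, moi > 0, diversity >= 1,
            diversity <= .Machine$integer.max,
            loss >= 0, loss < 1, n_dishes >= 1)
  progeny_prob <- check_progeny_prob(progeny_prob)
  if (any(heritability < 0) || any(heritability > 1)) {
    stop("heritability levels must be in [0, 1]", call. = FALSE)
  }
  # mu/si may stay NULL here (e.g. grid_fit fills them in from the
  # observed per-dish counts); reprogram_cells validates at run time
  if (is.null(dish_targets)) {
    if (!is.null(mu)) stopifnot(mu >= 0)
    if (!is.null(si)) stopifnot(si >= 0)
  } else {
    stopifnot(length(dish_targets) == n_dishes, all(dish_targets >= 0))
  }
  structure(
    list(n_seeded = n_seeded, moi = moi, diversity = as.integer(diversity),
         progeny_prob = progeny_prob, loss = loss,
         heritability = heritability,
         dish_targets = dish_targets, mu = mu, si = si,
         n_dishes = as.integer(n_dishes),
         integration_model = match.arg(integration_model),
         correct_multi = isTRUE(correct_multi),
         quota = match.arg(quota),
         on_infeasible = match.arg(on_infeasible)),
    class = "sim_params"
  )
}

#' Initial barcoded cell population
#'
#' Computes the effective number of barcoded cells
#' `N0 = round(n_seeded * (1 - exp(-moi)))` (only infected cells carry a
#' barcode and can be tracked), draws each cell's number of integrations,
#' and assigns each integration a barcode uniformly from the library.
#'
#' @param n_seeded Cells plated before transduction.
#' @param moi MOI of the barcoded virus (> 0).
#' @param diversity Library diversity (number of distinct barcodes).
#' @param seed Optional integer seed.
#' @param integration_model `"ztpois"` or `"single"` (see [sim_params()]).
#' @return A `cell_population`: parallel vectors `clone`, `class`
#'   (progeny class, NA before division), `dish` (NA before plating),
#'   `reprog`, `stage1`, plus a `clone_barcodes` table with one row per
#'   integration.
#' @export
init_population <- function(n_seeded, moi, diversity = 8e6, seed = NULL,
                            integration_model = c("ztpois", "single")) {
  integration_model <- match.arg(integration_model)
  stopifnot(moi > 0, diversity >= 1)
  if (!is.null(seed)) set.seed(seed)
  n0 <- round(n_seeded * infected_fraction(moi))
  if (n0 < 1) {
    stop("no effective cells: n_seeded * (1 - exp(-moi)) rounds to 0",
         call. = FALSE)
  }
  k_int <- if (integration_model == "single") {
    rep(1L, n0)
  } else {
    # zero-truncated Poisson(moi) by inverse-CDF on (P(X=0), 1]
    as.integer(qpois(runif(n0, ppois(0, moi), 1), moi))
  }
  barcodes <- sample.int(diversity, sum(k_int), replace = TRUE)
  structure(
    list(clone = seq_len(n0),
         class = rep(NA_integer_, n0),
         dish = rep(NA_integer_, n0),
         reprog = rep(FALSE, n0),
         stage1 = rep(FALSE, n0),
         n_clones = n0,
         clone_barcodes = list(clone = rep(seq_len(n0), k_int),
                               barcode = barcodes)),
    class = "cell_population"
  )
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf(
    "cell_population: %d cells, %d clones, %d integrations%s%s\n",
    length(x$clone), x$n_clones, length(x$clone_barcodes$barcode),
    if (all(is.na(x$dish))) "" else ", plated",
    if (any(x$reprog)) sprintf(", %d reprogrammed", sum(x$reprog)) else ""
  ))
  invisible(x)
}

#' One round of clonal division
#'
#' Each current cell is replaced by k progeny, k drawn i.i.d. from
#' `progeny_prob`; progeny inherit the parental barcode set and record
#' their progeny class k.
#'
#' @param pop A `cell_population`.
#' @param progeny_prob Probabilities for k = 0..8.
#' @param seed Optional seed.
#' @return The progeny `cell_population`.
#' @export
divide_cells <- function(pop, progeny_prob = default_progeny_prob(),
                         seed = NULL) {
  progeny_prob <- check_progeny_prob(progeny_prob)
  if (!is.null(seed)) set.seed(seed)
  n <- length(pop$clone)
  k <- sample.int(9L, n, replace = TRUE, prob = progeny_prob) - 1L
  idx <- rep.int(seq_len(n), k)
  pop$clone <- pop$clone[idx]
  pop$class <- rep.int(k, k)
  pop$dish <- rep(NA_integer_, length(idx))
  pop$reprog <- rep(FALSE, length(idx))
  pop$stage1 <- rep(FALSE, length(idx))
  pop
}

#' Random plating onto dishes
#'
#' Assigns each cell an i.i.d. uniform dish label in `1..n_dishes`.
#'
#' @inheritParams divide_cells
#' @param n_dishes Number of dishes.
#' @return The population with dish labels.
#' @export
plate_cells <- function(pop, n_dishes = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop$dish <- if (length(pop$clone)) {
    sample.int(n_dishes, length(pop$clone), replace = TRUE)
  } else integer(0)
  pop
}

#' Loss of material
#'
#' Removes `round(loss * n_d)` uniformly chosen cells from each dish,
#' modelling cell death, uneven splitting and downstream dropout.
#'
#' @inheritParams divide_cells
#' @param loss Loss fraction `d` in `[0, 1)`.
#' @return The culled population.
#' @export
cull_cells <- function(pop, loss, seed = NULL) {
  stopifnot(loss >= 0, loss < 1)
  if (!is.null(seed)) set.seed(seed)
  if (loss == 0 || !length(pop$clone)) return(pop)
  drop <- logical(length(pop$clone))
  for (d in unique(pop$dish)) {
    in_d <- which(pop$dish == d)
    n_drop <- round(loss * length(in_d))
    if (n_drop > 0) drop[sample(in_d, n_drop)] <- TRUE
  }
  keep <- !drop
  pop$clone <- pop$clone[keep]
  pop$class <- pop$class[keep]
  pop$dish <- pop$dish[keep]
  pop$reprog <- pop$reprog[keep]
  pop$stage1 <- pop$stage1[keep]
  pop
}

# heritability per cell, from a scalar or a progeny-class-named map
h_for_class <- function(heritability, class) {
  if (length(heritability) == 1 && is.null(names(heritability))) {
    return(rep(as.numeric(heritability), length(class)))
  }
  default <- if ("default" %in% names(heritability)) {
    heritability[["default"]]
  } else 0
  h <- heritability[as.character(class)]
  h[is.na(h)] <- default
  as.numeric(h)
}

#' Quota-driven reprogramming with heritable sister fate
#'
#' Reprogramming is simulated so that the cells reprogrammed in dish i
#' represent `BA_i` distinct barcodes (`BA_i` either given as
#' `dish_targets` or drawn from `Normal(mu, si)`, rounded and clamped at
#' 0). Directly selected cells are recorded as `stage1`; every
#' not-yet-reprogrammed sibling (same progenitor clone, in any dish) of a
#' selected cell is itself reprogrammed with probability `heritability`
#' (possibly progeny-class specific). Overlaps are counted on the union
#' of flags at the barcode level, so multi-integration inflation is
#' represented mechanically.
#'
#' Two quota semantics are available:
#' \describe{
#'   \item{`"final"` (default)}{Cells are drawn uniformly without
#'     replacement, round-robin across the dishes still under quota, and
#'     reprogrammed -- their siblings inheriting the fate with
#'     probability `heritability` as each is drawn -- until every dish's
#'     reprogrammed cells (including cells flagged as siblings of other
#'     dishes' selections) represent `BA_i` distinct barcodes. Final
#'     per-dish counts can exceed a target only through sisters flagged
#'     after that dish met its quota. This semantics makes the grid fit
#'     self-consistent when the targets are derived from observed
#'     per-dish counts.}
#'   \item{`"stage1"`}{The quota counts only directly drawn cells; all
#'     sibling flags are applied in a single pass afterwards and may push
#'     a dish's barcode count beyond `BA_i`.}
#' }
#' At `heritability = 0` the two modes are equivalent.
#'
#' @inheritParams divide_cells
#' @param dish_targets,mu,si,heritability,on_infeasible See [sim_params()].
#' @param n_dishes Number of dishes.
#' @param quota Quota semantics, `"final"` or `"stage1"` (see Details).
#' @return The population with `reprog`/`stage1` flags set and an
#'   `overlap_counts` object in attribute `"overlaps"` (also returned by
#'   [count_overlaps()]).
#' @export
reprogram_cells <- function(pop, dish_targets = NULL, mu = NULL, si = NULL,
                            heritability = 0, n_dishes = 4, seed = NULL,
                            quota = c("final", "stage1"),
                            on_infeasible = c("clamp", "error")) {
  on_infeasible <- match.arg(on_infeasible)
  quota <- match.arg(quota)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dish_targets)) {
    if (is.null(mu) || is.null(si)) {
      stop("supply either dish_targets or (mu, si)", call. = FALSE)
    }
    dish_targets <- pmax(0L, as.integer(round(rnorm(n_dishes, mu, si))))
  }
  stopifnot(length(dish_targets) == n_dishes)

  # barcode sets per clone, indexable by clone id (dense re-labelling so
  # per-dish presence fits in memory whatever the library diversity)
  cb <- pop$clone_barcodes
  dense <- as.integer(factor(cb$barcode))
  bc_by_clone <- split(dense, factor(cb$clone,
                                     levels = seq_len(pop$n_clones)))
  n_cells <- length(pop$clone)
  # at h = 0 the two quota modes coincide; use the vectorized path
  if (quota == "final" && all(heritability == 0)) quota <- "stage1"
  res <- if (quota == "final") {
    reprogram_final(pop, bc_by_clone, dish_targets, heritability,
                    n_dishes, on_infeasible)
  } else {
    reprogram_stage1(pop, bc_by_clone, dish_targets, heritability,
                     n_dishes, on_infeasible)
  }
  pop$stage1 <- res$stage1
  pop$reprog <- res$reprog
  attr(pop, "overlaps") <- count_overlaps(pop, n_dishes = n_dishes,
                                          ba = res$ba,
                                          clamped = res$clamped)
  pop
}

# distinct barcodes available among the cells of each dish
dish_available <- function(pop, bc_by_clone, n_dishes) {
  vapply(seq_len(n_dishes), function(d) {
    cl <- unique(pop$clone[pop$dish == d])
    length(unique(unlist(bc_by_clone[cl], use.names = FALSE)))
  }, integer(1))
}

reprogram_final <- function(pop, bc_by_clone, dish_targets, heritability,
                            n_dishes, on_infeasible) {
  n <- length(pop$clone)
  n_dense <- max(unlist(bc_by_clone, use.names = FALSE), 0L)
  present <- matrix(FALSE, n_dense, n_dishes)
  count <- integer(n_dishes)
  reprog <- logical(n)
  stage1 <- logical(n)
  ba <- integer(n_dishes)
  clamped <- logical(n_dishes)
  cells_by_clone <- split(seq_len(n),
                          factor(pop$clone, levels = seq_len(pop$n_clones)))
  avail <- dish_available(pop, bc_by_clone, n_dishes)
  h_scalar <- length(heritability) == 1 && is.null(names(heritability))

  mark <- function(cell) {
    # flag a cell and credit its barcodes to its dish
    reprog[cell] <<- TRUE
    bs <- bc_by_clone[[pop$clone[cell]]]
    dd <- pop$dish[cell]
    new <- bs[!present[bs, dd]]
    if (length(new)) {
      present[new, dd] <<- TRUE
      count[dd] <<- count[dd] + length(new)
    }
  }

  for (d in seq_len(n_dishes)) {
    target <- dish_targets[d]
    if (target > avail[d]) {
      if (on_infeasible == "error") {
        stop(sprintf(
          "dish %d: target of %d distinct barcodes exceeds the %d available",
          d, target, avail[d]), call. = FALSE)
      }
      clamped[d] <- TRUE
      target <- avail[d]
    }
    ba[d] <- target
  }
  ords <- lapply(seq_len(n_dishes), function(d) {
    in_d <- which(pop$dish == d)
    if (length(in_d) > 1) sample(in_d) else in_d
  })
  ptrs <- rep(1L, n_dishes)
  # round-robin over under-quota dishes so sister spillover between
  # dishes is absorbed symmetrically instead of inflating early dishes
  repeat {
    under <- which(count < ba &
                     vapply(seq_len(n_dishes),
                            function(d) ptrs[d] <= length(ords[[d]]),
                            logical(1)))
    if (!length(under)) break
    d <- if (length(under) > 1) sample(under, 1) else under
    ord <- ords[[d]]
    ptr <- ptrs[d]
    while (ptr <= length(ord) && reprog[ord[ptr]]) ptr <- ptr + 1L
    ptrs[d] <- ptr + 1L
    if (ptr > length(ord)) next # dish exhausted
    cell <- ord[ptr]
    mark(cell)
    stage1[cell] <- TRUE
    sibs <- cells_by_clone[[pop$clone[cell]]]
    sibs <- sibs[!reprog[sibs]]
    if (length(sibs)) {
      h <- if (h_scalar) heritability else {
        h_for_class(heritability, pop$class[sibs])
      }
      hit <- sibs[runif(length(sibs)) < h]
      for (s in hit) mark(s)
    }
  }
  list(stage1 = stage1, reprog = reprog, ba = ba, clamped = clamped)
}

reprogram_stage1 <- function(pop, bc_by_clone, dish_targets, heritability,
                             n_dishes, on_infeasible) {
  n <- length(pop$clone)
  ba <- integer(n_dishes)
  clamped <- logical(n_dishes)
  stage1 <- logical(n)
  for (d in seq_len(n_dishes)) {
    in_d <- which(pop$dish == d)
    target <- dish_targets[d]
    if (target == 0 || !length(in_d)) {
      ba[d] <- 0L
      clamped[d] <- target > 0 && !length(in_d)
      next
    }
    perm <- if (length(in_d) > 1) sample(in_d) else in_d
    bcs <- bc_by_clone[pop$clone[perm]]
    lens <- lengths(bcs)
    flat <- unlist(bcs, use.names = FALSE)
    distinct_after <- cumsum(!duplicated(flat))[cumsum(lens)]
    avail <- distinct_after[length(distinct_after)]
    if (target > avail) {
      if (on_infeasible == "error") {
        stop(sprintf(
          "dish %d: target of %d distinct barcodes exceeds the %d available",
          d, target, avail), call. = FALSE)
      }
      clamped[d] <- TRUE
      target <- avail
    }
    n_sel <- which(distinct_after >= target)[1]
    stage1[perm[seq_len(n_sel)]] <- TRUE
    ba[d] <- target
  }
  # single sibling pass afterwards
  hit_clones <- unique(pop$clone[stage1])
  sibs <- which(!stage1 & pop$clone %in% hit_clones)
  flagged <- logical(n)
  if (length(sibs)) {
    h <- h_for_class(heritability, pop$class[sibs])
    flagged[sibs] <- runif(length(sibs)) < h
  }
  list(stage1 = stage1, reprog = stage1 | flagged, ba = ba,
       clamped = clamped)
}

#' Barcode overlap counts of a reprogrammed population
#'
#' Counts, at the barcode level, in how many dishes each barcode carried
#' by a reprogrammed cell appears, plus per-dish distinct-barcode counts,
#' stage-1 cell counts and the progeny-class decomposition of the
#' exactly-2-dish overlaps.
#'
#' @param pop A `cell_population` after [reprogram_cells()].
#' @param n_dishes Number of dishes.
#' @param ba,clamped Internal: realized dish targets and clamp flags.
#' @return An `overlap_counts` list: `exactly` (named counts for 1..4
#'   dishes), `shared` (>= 2 dishes), `per_dish` distinct barcodes,
#'   `n_stage1`, `ba`, `clamped`, `contribution` (exactly-2 counts
#'   attributed to progeny classes 0..8).
#' @export
count_overlaps <- function(pop, n_dishes = 4, ba = NULL, clamped = NULL) {
  rp <- which(pop$reprog)
  cb <- pop$clone_barcodes
  empty <- setNames(numeric(9), 0:8)
  if (!length(rp)) {
    return(structure(list(
      exactly = setNames(integer(n_dishes), seq_len(n_dishes)),
      shared = 0L, per_dish = integer(n_dishes),
      n_stage1 = integer(n_dishes), ba = ba, clamped = clamped,
      contribution = empty), class = "overlap_counts"))
  }
  bc_by_clone <- split(cb$barcode,
                       factor(cb$clone, levels = seq_len(pop$n_clones)))
  bcs <- bc_by_clone[pop$clone[rp]]
  lens <- lengths(bcs)
  cell_dt <- data.table(
    barcode = unlist(bcs, use.names = FALSE),
    dish = rep.int(pop$dish[rp], lens),
    class = rep.int(pop$class[rp], lens)
  )
  bd <- unique(cell_dt[, c("barcode", "dish")])
  ndish <- bd[, .N, by = "barcode"]
  exactly <- tabulate(ndish$N, nbins = n_dishes)
  names(exactly) <- seq_len(n_dishes)
  per_dish <- tabulate(bd$dish, nbins = n_dishes)
  n_stage1 <- tabulate(pop$dish[pop$stage1], nbins = n_dishes)

  # attribute each exactly-2 barcode to the progeny classes of its
  # reprogrammed carriers (split equally when classes mix)
  contribution <- empty
  two <- ndish$barcode[ndish$N == 2L]
  if (length(two)) {
    cls <- unique(cell_dt[cell_dt$barcode %in% two, c("barcode", "class")])
    cls <- cls[!is.na(cls$class)]
    if (nrow(cls)) {
      w <- cls[, list(wt = 1 / .N, class = class), by = "barcode"]
      agg <- tapply(w$wt, factor(w$class, levels = 0:8), sum)
      agg[is.na(agg)] <- 0
      contribution <- setNames(as.numeric(agg), 0:8)
    }
  }
  structure(list(
    exactly = exactly,
    shared = sum(exactly[-1L]),
    per_dish = per_dish,
    n_stage1 = n_stage1,
    ba = ba, clamped = clamped,
    contribution = contribution
  ), class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat("overlap_counts\n")
  cat("  barcodes in exactly k dishes:",
      paste(sprintf("k=%s: %d", names(x$exactly), x$exactly),
            collapse = ", "), "\n")
  cat("  shared (>= 2 dishes):", x$shared, "\n")
  cat("  distinct barcodes per dish:", paste(x$per_dish, collapse = ", "),
      "\n")
  invisible(x)
}

#' Run replicated split-dish simulations
#'
#' Executes the full model (seeding and infection, division, plating,
#' loss, quota reprogramming with heritable sister fate) `replicates`
#' times with independent sub-seeds and collects per-replicate overlap
#' counts.
#'
#' @param params A [sim_params()] object.
#' @param replicates Number of independent executions (>= 1).
#' @param seed Optional master seed; sub-seeds are derived from it.
#' @return A `clone_sim` data.frame with one row per replicate: `shared`,
#'   `exactly2/3/4`, per-dish distinct-barcode counts `dish1..`, stage-1
#'   cell counts, a `feasible` flag (no dish target was clamped), and
#'   `shared_corrected` when `correct_multi` is set. The progeny-class
#'   contribution matrix is in attribute `"contribution"`.
#' @export
run_simulation <- function(params, replicates = 100, seed = NULL) {
  stopifnot(inherits(params, "sim_params"), replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  rows <- vector("list", replicates)
  contrib <- matrix(0, replicates, 9, dimnames = list(NULL, 0:8))
  for (r in seq_len(replicates)) {
    set.seed(sub_seeds[r])
    pop <- init_population(params$n_seeded, params$moi, params$diversity,
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
    ov <- attr(pop, "overlaps")
    contrib[r, ] <- ov$contribution
    row <- data.frame(
      replicate = r,
      shared = ov$shared,
      exactly2 = unname(ov$exactly["2"]),
      exactly3 = if (params$n_dishes >= 3) unname(ov$exactly["3"]) else 0L,
      exactly4 = if (params$n_dishes >= 4) unname(ov$exactly["4"]) else 0L,
      feasible = !any(ov$clamped)
    )
    for (d in seq_len(params$n_dishes)) {
      row[[paste0("dish", d)]] <- ov$per_dish[d]
      row[[paste0("stage1_d", d)]] <- ov$n_stage1[d]
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  if (params$correct_multi) {
    kbar <- params$moi / infected_fraction(params$moi)
    out$shared_corrected <- out$shared / kbar
  }
  attr(out, "contribution") <- contrib
  attr(out, "params") <- params
  class(out) <- c("clone_sim", "data.frame")
  out
}

#' @export
print.clone_sim <- function(x, ...) {
  cat(sprintf("clone_sim: %d replicates\n", nrow(x)))
  cat(sprintf("  shared barcodes: median %.1f, mean %.2f (range %d-%d)\n",
              median(x$shared), mean(x$shared), min(x$shared),
              max(x$shared)))
  cat(sprintf("  feasible replicates: %d/%d\n", sum(x$feasible), nrow(x)))
  invisible(x)
}
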