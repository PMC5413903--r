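kw_statistic <- function(values, group_sizes) {
  n <- length(values)
  r <- rank(values)
  ends <- cumsum(group_sizes)
  starts <- c(1, head(ends, -1) + 1)
  rsum <- vapply(seq_along(group_sizes), function(g) {
    sum(r[starts[g]:ends[g]])
  }, numeric(1))
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / group_sizes) - 3 * (n + 1)
  # tie correction
  t <- table(values)
  cf <- 1 - sum(t^3 - t) / (n^3 - n)
  if (cf > 0) h <- h / cf else h <- 0
  h
}

#' Kruskal-Wallis rank test
#'
#' One-way nonparametric ANOVA: the rank-based H statistic with tie
#' correction, and a p value from the chi-square approximation with
#' `groups - 1` degrees of freedom. When exactly two groups are compared
#' and one of them is a single value -- the situation when testing one
#' observed shared-barcode count against a set of simulated replicates,
#' where the chi-square approximation is unreliable -- the p value is
#' computed by exact permutation over which pooled value forms the
#' singleton group.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @param exact `NULL` (auto: exact when two groups and the smaller has a
#'   single element), or `TRUE`/`FALSE`.
#' @return List with `statistic` (H), `p.value`, `method`.
#' @export
#' @examples
#' kw_test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic # 7.2
kw_test <- function(groups, exact = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("all groups must be non-empty", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  if (n < 3) stop("need at least 3 values in total", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p.value = 1,
                method = "Kruskal-Wallis (degenerate: all values tied)"))
  }
  h <- kw_statistic(values, sizes)
  use_exact <- if (is.null(exact)) {
    length(groups) == 2 && min(sizes) == 1
  } else isTRUE(exact)
  if (use_exact && length(groups) == 2 && min(sizes) == 1) {
    # permute which value is the singleton; group sizes stay fixed
    single_first <- sizes[1] == 1
    hs <- vapply(seq_len(n), function(i) {
      v <- c(values[i], values[-i])
      kw_statistic(v, if (single_first) sizes else rev(sizes))
    }, numeric(1))
    p <- mean(hs >= h - 1e-12)
    method <- "Kruskal-Wallis, exact permutation (singleton group)"
  } else {
    p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
    method <- "Kruskal-Wallis chi-square approximation"
  }
  list(statistic = h, p.value = p, method = method)
}

#' Observed overlap counts
#'
#' Packages the measurements the grid fit needs: the shared-barcode count
#' (one value per experiment) and the per-dish distinct-barcode counts
#' that set the simulator's reprogramming quotas.
#'
#' @param shared Observed number(s) of barcodes present in >= 2 dishes.
#' @param per_dish Observed distinct-barcode counts per dish.
#' @param exactly Optional named counts for barcodes in exactly 2, 3, 4
#'   dishes.
#' @return An `observed_overlaps` list. An [build_overlap_table()] result
#'   can be converted with [as_observed()].
#' @export
observed_overlaps <- function(shared, per_dish, exactly = NULL) {
  stopifnot(all(shared >= 0), all(per_dish >= 0))
  structure(list(shared = shared, per_dish = per_dish, exactly = exactly),
            class = "observed_overlaps")
}

#' @rdname observed_overlaps
#' @param x An `overlap_table` (from [build_overlap_table()]) or
#'   `overlap_counts` (from [count_overlaps()]).
#' @export
as_observed <- function(x) {
  stopifnot(inherits(x, c("overlap_table", "overlap_counts")))
  observed_overlaps(shared = x$shared, per_dish = x$per_dish,
                    exactly = x$exactly[-1L])
}

#' Grid fit of the heritability level
#'
#' For every combination of loss-of-material `d` and heritability `h` on
#' the grids, runs `replicates` simulations and tests whether the
#' simulated shared-barcode counts are statistically compatible with the
#' observed count (Kruskal-Wallis; compatibility = failure to reject at
#' `alpha`). Per `d`, reports the accepted set of `h` and the best-fit
#' `h` (median simulated shared count closest to the observed mean; ties
#' go to the smaller `h`). When the test rejects every `h` -- which
#' happens at roughly rate `alpha` even on data the model generated --
#' the closest-median point estimate over the feasible grid is still
#' reported, flagged via `best_accepted = FALSE`, and the accepted set
#' stays empty. Parameter combinations whose dish quotas
#' cannot be met in most replicates are flagged infeasible rather than
#' silently skipped; if no `h` is accepted anywhere, the result records
#' an explicit no-fit.
#'
#' @param observed An [observed_overlaps()] (or an object [as_observed()]
#'   accepts). Its `per_dish` counts supply `mu` and `si` for the
#'   simulator unless `params` carries explicit `dish_targets`.
#' @param params A [sim_params()] template; `loss` and `heritability` are
#'   overridden by the grid values.
#' @param d_grid Loss-of-material grid (default 0.1..0.9 by 0.1).
#' @param h_grid Heritability grid (default 0..1 by 0.1).
#' @param replicates Simulations per grid point (default 100).
#' @param alpha Significance level (default 0.05).
#' @param accept_if One of `"p_ge_alpha"` (default: a point is compatible
#'   when the test fails to reject, p >= alpha) or `"p_lt_alpha"` (the
#'   inverted reading).
#' @param mode `"shared"` compares the shared-count replicates against
#'   the observed value; `"classes"` additionally requires compatibility
#'   of the exactly-2/3/4 counts (each at `alpha`).
#' @param min_feasible Minimum fraction of feasible replicates for a grid
#'   point to be fit at all (default 0.5).
#' @param seed Optional master seed.
#' @return A `heritability_fit`: `grid` (per (d, h): median/mean shared,
#'   p, accepted, feasible), `per_d` (accepted set and best-fit per d),
#'   `best` (global best-fit per d as named vector), `min_accepted_h`,
#'   `no_fit` flag.
#' @export
grid_fit <- function(observed, params,
                     d_grid = seq(0.1, 0.9, by = 0.1),
                     h_grid = seq(0, 1, by = 0.1),
                     replicates = 100, alpha = 0.05,
                     accept_if = c("p_ge_alpha", "p_lt_alpha"),
                     mode = c("shared", "classes"),
                     min_feasible = 0.5, seed = NULL) {
  if (!inherits(observed, "observed_overlaps")) {
    observed <- as_observed(observed)
  }
  stopifnot(inherits(params, "sim_params"))
  accept_if <- match.arg(accept_if)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params$dish_targets)) {
    params$mu <- mean(observed$per_dish)
    params$si <- if (length(observed$per_dish) > 1) {
      sd(observed$per_dish)
    } else 0
  }
  obs_mean <- mean(observed$shared)
  grid <- expand.grid(d = d_grid, h = h_grid)
  grid <- grid[order(grid$d, grid$h), ]
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p_i <- params
    p_i$loss <- grid$d[i]
    p_i$heritability <- grid$h[i]
    sims <- run_simulation(p_i, replicates = replicates)
    feas_frac <- mean(sims$feasible)
    feasible <- feas_frac >= min_feasible
    if (feasible) {
      kw <- kw_test(list(sims$shared, observed$shared))
      pval <- kw$p.value
      if (mode == "classes" && !is.null(observed$exactly)) {
        p_cls <- vapply(c("2", "3", "4"), function(k) {
          kw_test(list(sims[[paste0("exactly", k)]],
                       observed$exactly[[k]]))$p.value
        }, numeric(1))
        pval <- min(pval, p_cls)
      }
      accepted <- if (accept_if == "p_ge_alpha") pval >= alpha
                  else pval < alpha
    } else {
      pval <- NA_real_
      accepted <- FALSE
    }
    rows[[i]] <- data.frame(
      d = grid$d[i], h = grid$h[i],
      median_shared = median(sims$shared),
      mean_shared = mean(sims$shared),
      p_value = pval, accepted = accepted,
      feasible = feasible, feasible_fraction = feas_frac
    )
  }
  res <- do.call(rbind, rows)
  per_d <- lapply(d_grid, function(d) {
    sub <- res[res$d == d, ]
    acc <- sub$h[sub$accepted]
    # point estimate: closest median among the accepted set, or -- when
    # the compatibility test rejects everywhere (it has a ~alpha false-
    # rejection rate even on data the model generated) -- among all
    # feasible h, flagged as outside the accepted set
    cand <- if (length(acc)) sub[sub$accepted, ] else sub[sub$feasible, ]
    best <- if (nrow(cand)) {
      cand$h[order(abs(cand$median_shared - obs_mean), cand$h)][1]
    } else NA_real_
    list(d = d, accepted_h = acc, best_h = best,
         best_accepted = length(acc) > 0,
         infeasible_h = sub$h[!sub$feasible])
  })
  best <- vapply(per_d, `[[`, numeric(1), "best_h")
  names(best) <- format(d_grid)
  acc_any <- unlist(lapply(per_d, `[[`, "accepted_h"))
  structure(list(
    grid = res, per_d = per_d, best = best,
    min_accepted_h = if (length(acc_any)) min(acc_any) else NA_real_,
    no_fit = length(acc_any) == 0,
    observed = observed, alpha = alpha, mode = mode,
    replicates = replicates
  ), class = "heritability_fit")
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf("heritability_fit (%d replicates per grid point, alpha = %g)\n",
              x$replicates, x$alpha))
  if (x$no_fit) {
    cat("  NO FIT: no heritability level is compatible with the",
        "observation at any loss value\n")
  } else {
    cat(sprintf("  minimal accepted heritability: %.2f\n",
                x$min_accepted_h))
  }
  for (pd in x$per_d) {
    cat(sprintf(
      "  d = %.1f: best-fit h = %s%s, accepted {%s}%s\n", pd$d,
      ifelse(is.na(pd$best_h), "none", sprintf("%.2f", pd$best_h)),
      if (!pd$best_accepted && !is.na(pd$best_h)) "*" else "",
      paste(sprintf("%.1f", pd$accepted_h), collapse = ", "),
      if (length(pd$infeasible_h)) {
        sprintf(" (infeasible at h = %s)",
                paste(sprintf("%.1f", pd$infeasible_h), collapse = ", "))
      } else ""))
  }
  if (any(!vapply(x$per_d, `[[`, logical(1), "best_accepted"))) {
    cat("  * closest-median point estimate outside the accepted set\n")
  }
  invisible(x)
}

#' Progeny-class contribution to double overlaps
#'
#' Decomposes the simulated exactly-2-dish overlaps by the progeny class
#' of the clones that generated them, answering whether fast-cycling
#' cells contribute disproportionately to observed sharing.
#'
#' @param sims A [run_simulation()] result.
#' @return data.frame with `class` (0..8), `share` (mean share of
#'   exactly-2 overlaps across replicates with at least one double
#'   overlap; shares sum to 1), and `population_fraction` (the progeny
#'   distribution's cell-count fraction per class, for comparison).
#' @export
contribution_report <- function(sims) {
  contrib <- attr(sims, "contribution")
  params <- attr(sims, "params")
  if (is.null(contrib)) stop("no contribution attribution in input",
                             call. = FALSE)
  tot <- rowSums(contrib)
  use <- tot > 0
  if (!any(use)) {
    share <- rep(NA_real_, 9)
  } else {
    share <- colMeans(contrib[use, , drop = FALSE] / tot[use])
  }
  # fraction of *cells* in each class: k cells are produced per class-k
  # progenitor
  pf <- params$progeny_prob * 0:8
  pf <- pf / sum(pf)
  data.frame(class = 0:8, share = as.numeric(share),
             population_fraction = as.numeric(pf))
}
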