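#' Multiplicity of infection from the infected fraction
#'
#' Under the Poisson model of lentiviral transduction the number of viral
#' integrations per cell is Poisson(m), so the fraction of cells with at
#' least one integration (e.g. the GFP-positive fraction of a parallel
#' reporter infection) is `1 - exp(-m)`. Inverting gives the MOI.
#'
#' @param f_gfp Fraction of cells infected with at least one particle,
#'   in `[0, 1)`.
#' @return The MOI `m = -log(1 - f_gfp)`.
#' @seealso [infected_fraction()] for the inverse.
#' @export
#' @examples
#' moi_from_gfp(0.591) # ~0.89
moi_from_gfp <- function(f_gfp) {
  stopifnot(is.numeric(f_gfp), f_gfp >= 0)
  if (any(f_gfp >= 1)) {
    stop("f_gfp = 1 gives an undefined (infinite) MOI", call. = FALSE)
  }
  -log1p(-f_gfp)
}

#' Fraction of cells infected at a given MOI
#'
#' @param m Multiplicity of infection, `m >= 0`.
#' @return `1 - exp(-m)`, the Poisson probability of at least one
#'   integration.
#' @export
infected_fraction <- function(m) {
  stopifnot(is.numeric(m), m >= 0)
  -expm1(-m)
}

#' Theoretical diversity of a random barcode
#'
#' Number of distinct sequences of a given length over a fixed alphabet.
#' Returned as a double: 4^30 is ~1.15e18 and exceeds the integer range,
#' but is exactly representable (< 2^53).
#'
#' @param length Barcode length in bases (>= 1).
#' @param alphabet_size Alphabet cardinality, 4 for DNA.
#' @return `alphabet_size ^ length` as a double.
#' @export
theoretical_diversity <- function(length, alphabet_size = 4) {
  stopifnot(length >= 1, alphabet_size >= 2)
  alphabet_size^length
}

#' Library complexity from a plating dilution
#'
#' Scales a colony count from plating a known fraction of a transformation
#' mix up to the whole mix.
#'
#' @param colonies Number of colonies counted.
#' @param plated_fraction Fraction of the mix plated, in `(0, 1]`.
#' @return Estimated total number of independent transformants.
#' @export
#' @examples
#' plating_complexity(727, 0.000015) # ~48.5e6
plating_complexity <- function(colonies, plated_fraction) {
  stopifnot(colonies >= 0)
  if (!is.numeric(plated_fraction) || plated_fraction <= 0 ||
      plated_fraction > 1) {
    stop("plated_fraction must be in (0, 1]", call. = FALSE)
  }
  colonies / plated_fraction
}

#' Mark-recapture estimate of barcode library diversity
#'
#' Two independent transductions from the same viral batch sample barcodes
#' from the same pool; barcodes shared between the two recovered sets
#' reflect re-use of library members. The Lincoln-Petersen estimator
#' treats the first sample as "marked": `D = n1 * n2 / s`.
#'
#' @param n1,n2 Numbers of distinct barcodes recovered in the two runs.
#' @param s_shared Number of barcodes present in both.
#' @return A list with `estimate`, the inputs, and `lower_bound_only`
#'   (`TRUE` when `s_shared == 0`, in which case `estimate = n1 * n2` is
#'   only a lower bound).
#' @export
estimate_diversity <- function(n1, n2, s_shared) {
  stopifnot(n1 >= 1, n2 >= 1, s_shared >= 0)
  lower <- s_shared == 0
  est <- if (lower) n1 * n2 else n1 * n2 / s_shared
  structure(
    list(estimate = est, n1 = n1, n2 = n2, s_shared = s_shared,
         lower_bound_only = lower),
    class = "diversity_estimate"
  )
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("Library diversity estimate: %s%s\n",
              format(x$estimate, big.mark = ","),
              if (x$lower_bound_only) " (lower bound: no shared barcodes)"
              else ""))
  cat(sprintf("  from n1 = %d, n2 = %d, shared = %d\n",
              x$n1, x$n2, x$s_shared))
  invisible(x)
}

#' Reprogramming efficiency from recovered barcodes
#'
#' Each distinct recovered barcode marks at least one lineage that yielded
#' a pluripotent colony. Efficiency is the recovered-barcode count divided
#' by the number of cells that carried a barcoded provirus (the "effective"
#' cells, `N_seeded * (1 - exp(-m))`).
#'
#' @param n_barcodes Total distinct barcodes recovered across dishes.
#' @param n_seeded Cells plated before transduction.
#' @param m MOI of the barcoded virus (> 0).
#' @return Efficiency `E` in `[0, 1]` (can exceed 1 only if multiple
#'   integrations inflate the barcode count).
#' @export
reprogramming_efficiency <- function(n_barcodes, n_seeded, m) {
  stopifnot(n_barcodes >= 0, n_seeded > 0)
  if (!is.numeric(m) || m <= 0) {
    stop("m must be > 0: with no infection there are no barcoded cells",
         call. = FALSE)
  }
  eff_cells <- n_seeded * infected_fraction(m)
  if (eff_cells < 1) stop("fewer than one effective cell", call. = FALSE)
  n_barcodes / eff_cells
}

#' Expected shared barcodes under stochastic (non-heritable) reprogramming
#'
#' If reprogramming strikes cells independently, a barcode appears in two
#' dishes only when both sisters of a split clone reprogramme by
#' coincidence: `T = N * C * E^2`, with `N` transduced cells, `C` the
#' chance that two sisters land in different dishes, and `E` the
#' reprogramming efficiency.
#'
#' @param n Number of transduced cells.
#' @param c_split Probability two sisters are split to different dishes.
#' @param efficiency Reprogramming efficiency `E`.
#' @param round Round the result to the nearest integer for reporting
#'   (default `FALSE`).
#' @return Expected number of shared barcodes.
#' @export
#' @examples
#' expected_shared(170000, 0.75, 0.0167)               # 35.56...
#' expected_shared(170000, 0.75, 0.0167, round = TRUE) # 36
expected_shared <- function(n, c_split, efficiency, round = FALSE) {
  stopifnot(n >= 0, c_split >= 0, c_split <= 1,
            efficiency >= 0, efficiency <= 1)
  t_expected <- n * c_split * efficiency^2
  if (round) round(t_expected) else t_expected
}

#' Probability that sisters are split into different dishes
#'
#' Under independent uniform plating of `n_sisters` cells onto `n_dishes`
#' dishes, the probability that they all land on distinct dishes. For two
#' sisters this is `1 - 1/n_dishes` (0.75 for four dishes).
#'
#' @param n_dishes Number of dishes (>= 1).
#' @param n_sisters Number of sister cells (default 2).
#' @return The split probability; 0 when `n_sisters > n_dishes`.
#' @export
sister_split_probability <- function(n_dishes, n_sisters = 2) {
  stopifnot(n_dishes >= 1, n_sisters >= 1)
  if (n_sisters > n_dishes) return(0)
  # n_dishes * (n_dishes-1) * ... / n_dishes^n_sisters
  prod(seq(n_dishes, by = -1, length.out = n_sisters)) / n_dishes^n_sisters
}
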