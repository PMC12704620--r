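## Isotopologue mathematics. An MID is a bare numeric vector of length
## n_carbons + 1 indexed by mass level m = 0..n: the fraction of molecules
## carrying exactly m heavy carbons. All operations return vectors on the
## probability simplex.

#' Validate an MID vector
#'
#' @param x numeric vector over mass levels 0..n.
#' @param tol tolerance on the sum-to-one constraint.
#' @return `TRUE` if all entries are non-negative and sum to 1 within `tol`.
#' @export
validMid <- function(x, tol = 1e-9) {
  is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
    all(x >= -tol) && abs(sum(x) - 1) <= tol
}

#' Normalize a non-negative vector onto the probability simplex
#'
#' @param raw non-negative numeric vector with positive sum.
#' @return the vector divided by its sum; order preserved.
#' @examples
#' normalizeMid(c(2, 2, 0))  # 0.5 0.5 0.0
#' @export
normalizeMid <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw)) || any(raw < 0))
    stop("MID normalization requires a finite non-negative vector")
  s <- sum(raw)
  if (s <= 0) stop("cannot normalize an all-zero vector")
  raw / s
}

#' Convolve two MIDs (condensation of two carbon skeletons)
#'
#' The mass distribution of a molecule formed by joining fragments with
#' `n_a` and `n_b` carbons is the discrete convolution of the fragment
#' MIDs: `out[m] = sum_k a[k] * b[m - k]`. Used to evaluate the precursor
#' MID of condensation reactions (e.g. citrate synthase joining acetyl-CoA
#' and oxaloacetate).
#'
#' @param a,b MID vectors.
#' @return MID over `n_a + n_b` carbons.
#' @examples
#' convolveMids(c(0.5, 0.5), c(0.5, 0.5))  # 0.25 0.50 0.25
#' @export
convolveMids <- function(a, b) {
  stopifnot(validMid(a, tol = 1e-6), validMid(b, tol = 1e-6))
  out <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(a))
    out[k:(k + length(b) - 1L)] <- out[k:(k + length(b) - 1L)] + a[k] * b
  out
}

#' Hypergeometric carbon-loss marginalization
#'
#' Projects an MID over `n` carbons onto a retained subset of `n_keep`
#' carbons under the assumption that labeled carbons are exchangeable
#' (positional information is not tracked at MID resolution): the number of
#' labels retained when `n_keep` of `n` carbons are kept follows a
#' hypergeometric law,
#' `out[j] = sum_m x[m] * C(m, j) * C(n - m, n_keep - j) / C(n, n_keep)`.
#' Used for carbon-losing reactions such as decarboxylations. Mean
#' enrichment is preserved exactly.
#'
#' @param x MID over `n` carbons.
#' @param n_keep number of carbons retained, `0 < n_keep < n`.
#' @return MID over `n_keep` carbons.
#' @examples
#' marginalizeCarbons(c(0, 0, 1, 0), 2)  # 0 2/3 1/3
#' @export
marginalizeCarbons <- function(x, n_keep) {
  n <- length(x) - 1L
  if (n_keep <= 0 || n_keep >= n)
    stop("n_keep must satisfy 0 < n_keep < n_carbons")
  as.numeric(.margMatrix(n, n_keep) %*% x)
}

## (n_keep+1) x (n+1) hypergeometric redistribution matrix; columns are
## probability vectors, so the operator maps the simplex to the simplex.
.margMatrix <- function(n, n_keep) {
  m <- outer(0:n_keep, 0:n, function(j, mm)
    choose(mm, j) * choose(n - mm, n_keep - j) / choose(n, n_keep))
  m[is.na(m)] <- 0
  m
}

#' Forward natural-abundance smearing matrix
#'
#' Column `j` is the observed mass-level distribution of a molecule whose
#' tracer-derived mass level is `j`, when each of the remaining `n - j`
#' carbons is independently 13C with probability `p_nat`:
#' `C[i, j] = choose(n - j, i - j) * p_nat^(i - j) * (1 - p_nat)^(n - i)`
#' for `i >= j`. Multiplying a clean MID by this matrix reproduces the raw
#' pattern an instrument would report (carbon skeleton only).
#'
#' @param n number of carbons.
#' @param p_nat natural 13C abundance (default 0.0107).
#' @return `(n + 1) x (n + 1)` lower-triangular matrix.
#' @export
naturalAbundanceMatrix <- function(n, p_nat = 0.0107) {
  stopifnot(n >= 1, p_nat >= 0, p_nat < 0.5)
  outer(0:n, 0:n, function(i, j) {
    v <- choose(n - j, i - j) * p_nat^(i - j) * (1 - p_nat)^(n - i)
    ifelse(i >= j, v, 0)
  })
}

#' Correct a raw isotope pattern for natural 13C abundance
#'
#' Solves `C x = raw` for the tracer-only MID `x >= 0`, where `C` is the
#' binomial smearing matrix of [naturalAbundanceMatrix()], then normalizes.
#' The system is solved as a non-negative least-squares problem rather than
#' by plain inversion, which avoids small negative fractions caused by
#' measurement noise. Only the carbon skeleton is corrected; at unit-mass
#' resolution carbon dominates the isotope envelope and H/N/O natural
#' isotopes are ignored.
#'
#' @param raw non-negative intensity (or fraction) vector over mass levels
#'   `0..n_carbons`, uncorrected for natural abundance.
#' @param n_carbons number of tracked carbons (`length(raw) - 1`).
#' @param p_nat natural 13C abundance, `0 <= p_nat < 0.5`
#'   (default 0.0107). With `p_nat = 0` this reduces to normalization.
#' @return corrected MID (sums to 1).
#' @examples
#' p <- 0.0107
#' raw <- c((1 - p)^2, 2 * p * (1 - p), p^2)  # unlabeled 2-carbon compound
#' correctNaturalAbundance(raw, 2)            # ~ (1, 0, 0)
#' @export
correctNaturalAbundance <- function(raw, n_carbons, p_nat = 0.0107) {
  if (length(raw) != n_carbons + 1L)
    stop("intensity vector must have n_carbons + 1 entries")
  if (any(raw < 0) || all(raw == 0))
    stop("raw pattern must be non-negative with at least one positive entry")
  if (p_nat >= 0.5) stop("p_nat must be < 0.5")
  if (p_nat == 0) return(normalizeMid(raw))
  C <- naturalAbundanceMatrix(n_carbons, p_nat)
  x <- pracma::lsqnonneg(C, as.numeric(raw))$x
  normalizeMid(x)
}

#' Mean labeling enrichment of an MID
#'
#' The fraction of a metabolite's carbon atoms that carry label,
#' `sum_m (m/n) * x[m]` (the "relative labeling enrichment" reported for
#' glycolysis/TCA-cycle metabolites in tracing studies). The alternative
#' convention, the labeled-molecule fraction `1 - x[0]`, is available via
#' `method = "labeled_fraction"`.
#'
#' @param x MID over `n >= 1` carbons.
#' @param method `"atom_fraction"` (default) or `"labeled_fraction"`.
#' @return a scalar in \[0, 1\].
#' @examples
#' meanEnrichment(c(0.25, 0.5, 0.25))  # 0.5
#' @export
meanEnrichment <- function(x, method = c("atom_fraction", "labeled_fraction")) {
  method <- match.arg(method)
  n <- length(x) - 1L
  if (n < 1) stop("enrichment is undefined for a 0-carbon pool")
  stopifnot(validMid(x, tol = 1e-6))
  if (method == "atom_fraction") sum((0:n) / n * x) else 1 - x[1]
}
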