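# Goldman-Yang style codon substitution model: single-nucleotide codon steps,
# transition/transversion ratio kappa, nonsynonymous/synonymous ratio omega,
# stationary codon frequencies pi. One independent omega per branch class.

#' Branch classes of the sextuplet design
#'
#' The five dN/dS regimes fitted on the sextuplet topology: preduplication
#' (`preD`), the two initial postduplication internal branches (`ipostD1`,
#' `ipostD2`), and the two recent postduplication terminal branch pairs
#' (`rpostD1`, `rpostD2`).
#'
#' @return Character vector of the five class labels, in canonical order.
#' @export
omega_classes <- function() c("preD", "ipostD1", "ipostD2", "rpostD1", "rpostD2")

#' Construct codon model parameters
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega_by_class Named numeric vector mapping omega-class labels to
#'   dN/dS values (all >= 0). Any subset of classes may be supplied; a single
#'   unnamed value is recycled to all five classes of [omega_classes()].
#' @param codon_freqs Stationary frequencies of the 61 sense codons
#'   (non-negative, summing to 1). Defaults to uniform.
#' @return An object of class `codon_model_params`.
#' @examples
#' p <- codon_model_params(kappa = 2, omega_by_class = c(preD = 0.1, rpostD1 = 0.3))
#' @export
codon_model_params <- function(kappa = 2,
                               omega_by_class = c(preD = 0.2),
                               codon_freqs = rep(1 / 61, 61)) {
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) || kappa <= 0)
    stop("kappa must be a single finite positive number")
  if (is.null(names(omega_by_class))) {
    if (length(omega_by_class) != 1)
      stop("omega_by_class must be named, or a single value applied to all classes")
    omega_by_class <- stats::setNames(rep(omega_by_class, 5), omega_classes())
  }
  if (!all(names(omega_by_class) %in% omega_classes()))
    stop("unknown omega class label(s): ",
         paste(setdiff(names(omega_by_class), omega_classes()), collapse = ", "))
  if (any(!is.finite(omega_by_class)) || any(omega_by_class < 0))
    stop("all omega values must be finite and >= 0")
  codon_freqs <- as.numeric(codon_freqs)
  if (length(codon_freqs) != 61 || any(!is.finite(codon_freqs)) ||
      any(codon_freqs < 0))
    stop("codon_freqs must be 61 finite non-negative values")
  if (abs(sum(codon_freqs) - 1) > 1e-12)
    stop("codon_freqs must sum to 1 (within 1e-12)")
  structure(list(kappa = kappa,
                 omega_by_class = omega_by_class,
                 codon_freqs = codon_freqs,
                 genetic_code = "standard"),
            class = "codon_model_params")
}

#' @export
print.codon_model_params <- function(x, ...) {
  cat("Codon model parameters (GY-style, standard code)\n")
  cat(sprintf("  kappa = %.4g\n", x$kappa))
  cat("  omega by class:\n")
  for (cl in names(x$omega_by_class))
    cat(sprintf("    %-8s %.4g\n", cl, x$omega_by_class[[cl]]))
  cat(sprintf("  codon frequencies: range [%.4g, %.4g]\n",
              min(x$codon_freqs), max(x$codon_freqs)))
  invisible(x)
}

#' Instantaneous rate matrix of the codon model
#'
#' Builds the 61 x 61 generator for a given dN/dS value. Off-diagonal entry
#' (i, j) is zero unless codons i and j differ at exactly one nucleotide;
#' single-step entries are `pi_j * kappa^[transition] * omega^[nonsynonymous]`.
#' The matrix is rescaled so that the expected number of substitutions per
#' codon per unit time at stationarity equals 1 under this omega, so branch
#' lengths are in expected substitutions per codon.
#'
#' @param params A [codon_model_params()] object.
#' @param omega dN/dS rate ratio (>= 0) for this matrix.
#' @return 61 x 61 matrix with zero row sums, with the scaling factor as
#'   attribute `"scale"` (expected substitutions per codon of the unscaled
#'   matrix).
#' @export
build_rate_matrix <- function(params, omega) {
  stopifnot(inherits(params, "codon_model_params"))
  if (!is.numeric(omega) || length(omega) != 1 || !is.finite(omega) || omega < 0)
    stop("omega must be a single finite non-negative number")
  pi <- params$codon_freqs
  single <- .code("single_step")
  ts <- .code("is_transition")
  syn <- .code("is_synonymous")
  Q <- single * rep(pi, each = 61)           # pi_j along columns
  Q[ts] <- Q[ts] * params$kappa
  Q[single & !syn] <- Q[single & !syn] * omega
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  attr(Q, "scale") <- scale
  dimnames(Q) <- list(sense_codons(), sense_codons())
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computes the matrix exponential through the eigendecomposition of the
#' symmetrised reversible generator, which is numerically stable and exact to
#' machine precision for these matrices.
#'
#' @param Q Rate matrix from [build_rate_matrix()].
#' @param t Branch length (>= 0) in expected substitutions per codon.
#' @param pi Stationary frequencies of `Q`; recovered from detailed balance if
#'   omitted and `Q` carries no `"pi"` attribute.
#' @return 61 x 61 stochastic matrix.
#' @export
transition_probabilities <- function(Q, t, pi = NULL) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("branch length t must be a single finite value >= 0")
  n <- nrow(Q)
  if (t == 0) return(diag(n))
  if (is.null(pi)) pi <- stationary_frequencies(Q)
  sq <- sqrt(pmax(pi, 1e-300))
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  P <- (1 / sq) * (e$vectors %*% (exp(e$values * t) * t(e$vectors))) * rep(sq, each = n)
  P <- pmax(P, 0)
  P / rowSums(P)
}

# Stationary distribution of a reversible generator via its left null space;
# cheap closed form from detailed balance is not available without pi, so
# solve pi Q = 0 directly.
stationary_frequencies <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0] <- 0
  pi / sum(pi)
}

# Stationary substitution fluxes partitioned into synonymous and
# nonsynonymous, for the scaled generator (total flux 1).
substitution_fluxes <- function(params, omega) {
  Q <- build_rate_matrix(params, omega)
  pi <- params$codon_freqs
  syn <- .code("is_synonymous")
  flux <- pi * Q          # pi_i * q_ij elementwise along rows
  diag(flux) <- 0
  s <- sum(flux[syn])
  n <- sum(flux) - s
  c(synonymous = s, nonsynonymous = n)
}

#' Per-branch dN and dS from the fitted branch length and omega
#'
#' Decomposes a branch of length `t` (expected substitutions per codon) into
#' dN (nonsynonymous substitutions per nonsynonymous site) and dS (synonymous
#' substitutions per synonymous site). With `rho_N`, `rho_S` the stationary
#' fractions of substitutions that are nonsynonymous/synonymous under `omega`,
#' and `rho*_N`, `rho*_S` the same fractions at omega = 1 (mutational
#' opportunity), `dn = t * rho_N / (3 * rho*_N)` and
#' `ds = t * rho_S / (3 * rho*_S)`; consequently `dn/ds = omega` exactly.
#'
#' @param t Branch length >= 0, in substitutions per codon.
#' @param omega dN/dS ratio of the branch's class.
#' @param params A [codon_model_params()] object (kappa and pi are used).
#' @return Named numeric vector `c(dn = , ds = )`.
#' @export
dn_ds_from_branch <- function(t, omega, params) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("branch length t must be >= 0")
  fl <- substitution_fluxes(params, omega)
  fl0 <- substitution_fluxes(params, 1)
  rho <- fl / sum(fl)
  rho0 <- fl0 / sum(fl0)
  c(dn = t * rho[["nonsynonymous"]] / (3 * rho0[["nonsynonymous"]]),
    ds = t * rho[["synonymous"]] / (3 * rho0[["synonymous"]]))
}

# Inverse of the ds component of dn_ds_from_branch: branch length giving a
# target per-branch ds under a class omega. Used by the scenario builders so
# simulations can be specified in synonymous-divergence units.
branch_length_for_ds <- function(ds, omega, params) {
  stopifnot(ds >= 0)
  unit <- dn_ds_from_branch(1, omega, params)[["ds"]]
  ds / unit
}

#' Empirical F3x4 codon frequencies of an alignment
#'
#' Position-specific nucleotide frequencies are estimated from all codons of
#' all sequences (gap codons excluded); codon frequencies are the product over
#' the three positions, with stop codons removed and the rest renormalised.
#' Frequencies are floored at `1e-8` before renormalisation so that the
#' generator stays irreducible for alignments missing a nucleotide at some
#' position.
#'
#' @param aln A [codon_alignment()].
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  idx <- aln$index        # n_seq x n_col matrix of codon indices, NA = gap
  cm <- .code("codon_nt")
  freq <- matrix(0, 3, 4, dimnames = list(NULL, .nt))
  obs <- idx[!is.na(idx)]
  for (p in 1:3) {
    tab <- table(factor(cm[obs, p], levels = .nt))
    freq[p, ] <- as.numeric(tab)
  }
  freq <- freq / rowSums(freq)
  pi <- freq[1, cm[, 1]] * freq[2, cm[, 2]] * freq[3, cm[, 3]]
  pi <- pmax(pi, 1e-8)
  pi / sum(pi)
}
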