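#' Define a panel of biallelic variants
#'
#' A variant panel records the minor-allele frequency (MAF) of each variant
#' in the region under study. Variants are treated as independent (no linkage
#' disequilibrium) and genotypes are coded as minor-allele counts in
#' `{0, 1, 2}`.
#'
#' @param maf Numeric vector of minor-allele frequencies, each in `(0, 0.5]`.
#'   A scalar is recycled to `m` variants when `m` is given.
#' @param m Number of variants (optional when `maf` already has full length).
#' @param labels Optional unique variant identifiers; defaults to `v1..vm`.
#' @return A tibble of class `variant_panel` with columns `variant` and `maf`.
#' @examples
#' variant_panel(0.005, m = 10)
#' @export
variant_panel <- function(maf, m = NULL, labels = NULL) {
  if (!is.null(m) && length(maf) == 1L) maf <- rep(maf, m)
  m <- length(maf)
  if (m < 1L) stop("a panel needs at least one variant")
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    stop("all MAFs must lie in (0, 0.5]")
  }
  if (is.null(labels)) labels <- paste0("v", seq_len(m))
  if (length(labels) != m || anyDuplicated(labels)) {
    stop("labels must be unique and of length m")
  }
  out <- tibble::tibble(variant = as.character(labels), maf = as.numeric(maf))
  class(out) <- c("variant_panel", class(out))
  out
}

#' Logistic penetrance model for disease affection
#'
#' The probability that a subject with multi-variant genotype `g` is affected
#' is `expit(logit(c) + sum_i beta_i * g_i)`, where `c` is the background
#' chance of affection for a subject carrying no minor alleles and `beta_i`
#' is the per-allele log odds ratio of variant `i`. `beta_i = 0` encodes a
#' non-causal variant.
#'
#' @param c Background affection probability, in `(0, 1)`.
#' @param beta Per-variant log odds ratios (finite). Alternatively supply
#'   `or` (per-variant odds ratios) and omit `beta`.
#' @param or Per-variant odds ratios; used when `beta` is missing.
#' @return An object of class `disease_model` with fields `c`, `beta`, `or`.
#' @examples
#' disease_model(c = 0.01, or = c(2, 2, 2, 2, rep(1, 6)))
#' @export
disease_model <- function(c, beta = NULL, or = NULL) {
  if (length(c) != 1L || !is.finite(c) || c <= 0 || c >= 1) {
    stop("background risk c must be a single probability in (0, 1)")
  }
  if (is.null(beta)) {
    if (is.null(or)) stop("supply beta or or")
    if (any(or <= 0)) stop("odds ratios must be positive")
    beta <- log(or)
  }
  if (any(!is.finite(beta))) stop("beta must be finite")
  structure(list(c = c, beta = as.numeric(beta), or = exp(beta)),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Logistic disease model: background risk c =", x$c, "\n")
  cat("  per-variant OR:", paste(signif(x$or, 4), collapse = " "), "\n")
  invisible(x)
}

#' Affection probability for given genotypes
#'
#' @param model A [disease_model()].
#' @param geno Genotype vector of minor-allele counts (length `m`), or a
#'   subjects-by-variants matrix of such counts.
#' @return Affection probability (vector with one entry per subject).
#' @examples
#' mod <- disease_model(0.01, or = c(2, 1))
#' affection_prob(mod, c(1, 0))  # 2/101
#' @export
affection_prob <- function(model, geno) {
  stopifnot(inherits(model, "disease_model"))
  if (is.matrix(geno)) {
    if (ncol(geno) != length(model$beta)) stop("genotype/model dimension mismatch")
    eta <- as.vector(geno %*% model$beta)
  } else {
    if (length(geno) != length(model$beta)) stop("genotype/model dimension mismatch")
    eta <- sum(geno * model$beta)
  }
  stats::plogis(stats::qlogis(model$c) + eta)
}

#' Population prevalence under Hardy-Weinberg genotype frequencies
#'
#' Exact expectation of [affection_prob()] over independent per-variant
#' Hardy-Weinberg genotypes (`P(g=1) = 2q(1-q)`, `P(g=2) = q^2`). Variants
#' sharing the same `(maf, beta)` are grouped so the enumeration convolves a
#' small number of binomial allele-count distributions; non-causal variants
#' do not enter the sum.
#'
#' @param model A [disease_model()].
#' @param panel A [variant_panel()] with one MAF per model coefficient.
#' @return Scalar prevalence in `(0, 1)`.
#' @examples
#' panel <- variant_panel(0.005, m = 10)
#' mod <- disease_model(0.01, or = c(rep(2, 4), rep(1, 6)))
#' population_prevalence(mod, panel)
#' @export
population_prevalence <- function(model, panel) {
  stopifnot(inherits(model, "disease_model"), inherits(panel, "variant_panel"))
  if (nrow(panel) != length(model$beta)) stop("panel/model dimension mismatch")
  causal <- which(model$beta != 0)
  if (length(causal) == 0L) return(model$c)
  grp <- interaction(panel$maf[causal], model$beta[causal], drop = TRUE)
  dist <- data.frame(eta = 0, p = 1)
  for (g in levels(grp)) {
    idx <- causal[grp == g]
    k <- length(idx)
    q <- panel$maf[idx[1]]
    b <- model$beta[idx[1]]
    counts <- 0:(2 * k)  # total minor alleles over k iid HWE variants
    pk <- stats::dbinom(counts, 2 * k, q)
    dist <- data.frame(
      eta = as.vector(outer(dist$eta, b * counts, `+`)),
      p = as.vector(outer(dist$p, pk))
    )
    dist <- stats::aggregate(p ~ eta, data = dist, FUN = sum)
  }
  sum(dist$p * stats::plogis(stats::qlogis(model$c) + dist$eta))
}
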