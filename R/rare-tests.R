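#' Score vector and covariance from case-control genotype data
#'
#' Under the null logistic model with intercept only, the score vector for
#' the genotype coefficients is `U = G'(y - ybar)` and its covariance is
#' `V = ybar (1 - ybar) * sum_i (g_i - gbar)(g_i - gbar)'`. The five score
#' tests ([uminp_test()], [score_test()], [ssu_test()], [ssuw_test()],
#' [sum_test()]) can be applied to the result unchanged.
#'
#' @param cc A `cc_data` object with both cases and controls present.
#' @return A `score_components` object; `rows` holds the centred per-subject
#'   score contributions `(y_i - ybar)(g_i - gbar)` used for sign-flip
#'   resampling.
#' @export
cc_score_components <- function(cc) {
  stopifnot(inherits(cc, "cc_data"))
  y <- cc$y
  if (length(unique(y)) < 2L) stop("both cases and controls are required")
  ybar <- mean(y)
  G <- cc$G
  gbar <- colMeans(G)
  Gc <- sweep(G, 2, gbar)
  U <- as.vector(crossprod(G, y - ybar))
  V <- ybar * (1 - ybar) * crossprod(Gc)
  structure(list(U = U, V = V, n = nrow(G), m = ncol(G), xbar = gbar,
                 rows = Gc * (y - ybar)),
            class = "score_components")
}

#' Multiple-test-corrected single-SNP association test
#'
#' Per variant, the 1-df score chi-square `U_j^2 / V_jj`; the global
#' p-value is the Bonferroni-corrected minimum p over variants with
#' `V_jj > 0` (monomorphic variants are excluded), capped at 1.
#'
#' @param cc A `cc_data` object.
#' @return One-row result tibble with per-variant detail in attribute
#'   `per_variant`.
#' @export
single_snp_association <- function(cc) {
  sc <- cc_score_components(cc)
  d <- diag(sc$V)
  keep <- which(d > 0)
  if (length(keep) == 0L) {
    warning("no polymorphic variants")
    return(test_result("assoc", 0, 1, df = 1, note = "no informative variants"))
  }
  chi <- sc$U[keep]^2 / d[keep]
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  out <- test_result("assoc", max(chi), min(1, length(keep) * min(p)), df = 1)
  attr(out, "per_variant") <- tibble::tibble(
    variant = keep, statistic = chi, p_value = p)
  out
}

# per-variant minor-allele copy totals and case copies
collapsed_counts <- function(cc) {
  nj <- colSums(cc$G)
  aj <- colSums(cc$G[cc$y == 1, , drop = FALSE])
  list(n = nj, a = aj, p0 = mean(cc$y))
}

#' C-alpha overdispersion test (analytic one-tailed normal p-value)
#'
#' With `p0` the case fraction of subjects, each variant with `n_j` total
#' minor-allele copies of which `a_j` fall in cases contributes
#' `(a_j - n_j p0)^2 - n_j p0 (1 - p0)` to the statistic `T`. The null
#' variance is `c = sum_n m(n) sum_u [(u - n p0)^2 - n p0 (1-p0)]^2
#' Binom(u; n, p0)` where `m(n)` counts variants with exactly `n` copies.
#' Significance of `Z = T / sqrt(c)` is assessed on a one-tailed standard
#' normal. Direction-agnostic in the effects: both protective and risk
#' variants inflate the variance.
#'
#' @param cc A `cc_data` object.
#' @return One-row result tibble.
#' @export
calpha_statistic <- function(cc) {
  stopifnot(inherits(cc, "cc_data"))
  if (length(unique(cc$y)) < 2L) stop("both cases and controls are required")
  ct <- collapsed_counts(cc)
  tstat <- calpha_T(ct$a, ct$n, ct$p0)
  cvar <- 0
  for (n in unique(ct$n[ct$n > 0])) {
    mn <- sum(ct$n == n)
    u <- 0:n
    dev <- (u - n * ct$p0)^2 - n * ct$p0 * (1 - ct$p0)
    cvar <- cvar + mn * sum(dev^2 * stats::dbinom(u, n, ct$p0))
  }
  if (cvar <= 0) {
    warning("C-alpha null variance is zero")
    return(test_result("calpha", tstat, 1, note = "zero variance"))
  }
  z <- tstat / sqrt(cvar)
  test_result("calpha", z, stats::pnorm(z, lower.tail = FALSE), note = "analytic")
}

calpha_T <- function(a, n, p0) {
  sum((a - n * p0)^2 - n * p0 * (1 - p0))
}

#' C-alpha test with permutation p-values
#'
#' The asymptotic normal approximation for C-alpha is unreliable at very low
#' minor-allele frequencies, so the phenotype labels are permuted over
#' subjects and the one-sided empirical p-value `(1 + #{T_perm >= T_obs}) /
#' (n_perm + 1)` is reported.
#'
#' @param cc A `cc_data` object.
#' @param n_perm Number of permutations (at least 100).
#' @return One-row result tibble.
#' @export
calpha_permutation <- function(cc, n_perm = 1000) {
  stopifnot(inherits(cc, "cc_data"), n_perm >= 100)
  ct <- collapsed_counts(cc)
  tobs <- calpha_T(ct$a, ct$n, ct$p0)
  n <- length(cc$y)
  Y <- matrix(0L, n, n_perm)
  for (i in seq_len(n_perm)) Y[, i] <- sample(cc$y)
  A <- crossprod(cc$G, Y)  # m x n_perm case copy counts
  dev <- sweep(A, 1, ct$n * ct$p0)^2 - ct$n * ct$p0 * (1 - ct$p0)
  tperm <- colSums(dev)
  test_result("calpha_perm", tobs, (1 + sum(tperm >= tobs)) / (n_perm + 1),
              note = sprintf("%d permutations", n_perm))
}

#' Beta-density minor-allele-frequency weights for SKAT
#'
#' `w_j = dbeta(maf_j; a1, a2)`. The default `Beta(1, 25)` up-weights the
#' rarest variants; `a1 = a2 = 1` gives unit weights, under which SKAT
#' coincides with the SSU test.
#'
#' @param maf_hat Observed minor-allele frequencies in `[0, 1]`.
#' @param a1,a2 Beta shape parameters.
#' @return A `skat_weights` object (fields `w`, `a1`, `a2`, `maf_hat`).
#' @export
beta_maf_weights <- function(maf_hat, a1 = 1, a2 = 25) {
  stopifnot(all(maf_hat >= 0 & maf_hat <= 1))
  structure(list(w = stats::dbeta(maf_hat, a1, a2), a1 = a1, a2 = a2,
                 maf_hat = maf_hat),
            class = "skat_weights")
}

#' SKAT variance-component score test
#'
#' `Q = (y - ybar)' G W G' (y - ybar)` with `W = diag(w_j^2)`; under the
#' null, `Q` follows the mixture of chi-squares whose weights are the
#' eigenvalues of `ybar(1-ybar) * W^(1/2) G' (I - 11'/n) G W^(1/2)`,
#' evaluated by [mixture_chisq_pvalue()]. With unit weights `Q = U'U`
#' exactly, the SSU statistic.
#'
#' @param cc A `cc_data` object.
#' @param weights A [beta_maf_weights()] object, or `NULL` to compute
#'   `Beta(a1, a2)` weights from the observed MAF of the combined sample.
#' @param a1,a2 Beta shape parameters used when `weights` is `NULL`.
#' @return One-row result tibble.
#' @export
skat_test <- function(cc, weights = NULL, a1 = 1, a2 = 25) {
  stopifnot(inherits(cc, "cc_data"))
  if (length(unique(cc$y)) < 2L) stop("both cases and controls are required")
  if (is.null(weights)) {
    weights <- beta_maf_weights(colMeans(cc$G) / 2, a1, a2)
  }
  w <- weights$w
  y <- cc$y
  ybar <- mean(y)
  S <- as.vector(crossprod(cc$G, y - ybar))
  q <- sum(w^2 * S^2)
  if (q == 0) return(test_result("skat", 0, 1, note = "zero statistic"))
  Gc <- sweep(cc$G, 2, colMeans(cc$G))
  A <- Gc %*% diag(w, length(w))
  lam <- ybar * (1 - ybar) *
    pmax(eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values, 0)
  if (max(lam) == 0) return(test_result("skat", q, 1, note = "zero covariance"))
  test_result("skat", q, mixture_chisq_pvalue(lam, q))
}

#' KBAC test with the cumulative hypergeometric kernel
#'
#' Distinct non-null multi-variant genotypes are counted in cases and
#' controls. Class `i`, carried by `n_iA` cases and `n_iU` controls, is
#' weighted by the cumulative hypergeometric probability of observing up to
#' `n_iA` case carriers among its `n_iA + n_iU` carriers when drawn from
#' `n_A` cases and `n_U` controls; the statistic is
#' `sum_i k_i (n_iA / n_A - n_iU / n_U)`. Risk-direction one-sided p-values
#' are obtained by label permutation with class re-counting.
#'
#' @param cc A `cc_data` object.
#' @param kernel Kernel name; only `"hypergeometric"` is implemented.
#' @param n_perm Number of permutations (at least 100).
#' @return One-row result tibble.
#' @export
kbac_test <- function(cc, kernel = "hypergeometric", n_perm = 1000) {
  stopifnot(inherits(cc, "cc_data"), n_perm >= 100)
  kernel <- match.arg(kernel, "hypergeometric")
  y <- cc$y
  nA <- sum(y == 1)
  nU <- sum(y == 0)
  if (nA == 0 || nU == 0) stop("both cases and controls are required")
  carrier <- rowSums(cc$G != 0) > 0
  if (!any(carrier)) {
    warning("no non-null genotypes in the sample")
    return(test_result("kbac", 0, 1, note = "no carriers"))
  }
  key <- apply(cc$G[carrier, , drop = FALSE], 1, paste, collapse = ",")
  cls <- match(key, unique(key))
  k <- max(cls)
  ti <- tabulate(cls, k)                     # carriers per class
  yc <- y[carrier]
  kbac_stat <- function(ai) {
    ki <- stats::phyper(ai, nA, nU, ti)
    sum(ki * (ai / nA - (ti - ai) / nU))
  }
  aobs <- as.vector(rowsum(yc, cls))
  tobs <- kbac_stat(aobs)
  nc <- sum(carrier)
  n <- length(y)
  exceed <- 0L
  Z <- outer(cls, seq_len(k), `==`) + 0  # carrier x class indicator
  for (i in seq_len(n_perm)) {
    # labels on carrier positions under a full permutation of y
    yp <- y[sample.int(n, nc)]
    ai <- as.vector(crossprod(Z, yp))
    if (kbac_stat(ai) >= tobs) exceed <- exceed + 1L
  }
  test_result("kbac", tobs, (1 + exceed) / (n_perm + 1),
              note = sprintf("%d permutations", n_perm))
}

#' Run the case-control test battery
#'
#' @param cc A `cc_data` object.
#' @param tests Character vector among `c("assoc", "uminp", "score", "ssu",
#'   "ssuw", "sum", "calpha", "calpha_perm", "skat", "kbac")`.
#' @param n_perm Permutation budget for `calpha_perm` and `kbac`.
#' @param skat_a1,skat_a2 SKAT Beta weight parameters.
#' @param cluster Collapse related cases (and matched controls) with
#'   [cluster_related()] before testing?
#' @return Tibble with one row per test.
#' @export
cc_test_battery <- function(cc, tests = c("assoc", "uminp", "score", "ssu",
                                          "ssuw", "sum", "calpha_perm",
                                          "skat", "kbac"),
                            n_perm = 1000, skat_a1 = 1, skat_a2 = 25,
                            cluster = FALSE) {
  stopifnot(inherits(cc, "cc_data"))
  if (cluster) cc <- cluster_related(cc)
  sc <- NULL
  get_sc <- function() {
    if (is.null(sc)) sc <<- cc_score_components(cc)
    sc
  }
  run1 <- function(t) {
    switch(t,
           assoc = single_snp_association(cc),
           uminp = uminp_test(get_sc()),
           score = score_test(get_sc()),
           ssu = ssu_test(get_sc()),
           ssuw = ssuw_test(get_sc()),
           sum = sum_test(get_sc()),
           calpha = calpha_statistic(cc),
           calpha_perm = calpha_permutation(cc, n_perm = n_perm),
           skat = skat_test(cc, a1 = skat_a1, a2 = skat_a2),
           kbac = kbac_test(cc, n_perm = n_perm),
           stop("unknown case-control test: ", t))
  }
  dplyr::bind_rows(lapply(tests, run1))
}
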