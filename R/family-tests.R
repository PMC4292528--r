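#' Score vector and covariance from a transmission matrix
#'
#' From the `n x m` transmission-disequilibrium matrix `X` (one row per
#' trio), the score vector is the column sum `U = sum_i X_i` and its
#' covariance is estimated by the sum of outer products of the centred rows,
#' `V = sum_i (X_i - Xbar)(X_i - Xbar)'` (no Bessel `n/(n-1)` factor; see
#' the methods vignette for this convention).
#'
#' @param X Numeric `n x m` matrix with `n >= 2`.
#' @return A `score_components` object with fields `U`, `V`, `n`, `m`,
#'   `xbar`, and `rows` (the centred per-unit score contributions, used by
#'   resampling-based p-values).
#' @export
score_components <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two trios to estimate V")
  U <- colSums(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  V <- crossprod(Xc)
  structure(list(U = U, V = V, n = nrow(X), m = ncol(X), xbar = xbar,
                 rows = X),
            class = "score_components")
}

#' @export
print.score_components <- function(x, ...) {
  cat(sprintf("score_components: m = %d variants from n = %d units\n", x$m, x$n))
  cat("  U:", paste(signif(x$U, 4), collapse = " "), "\n")
  invisible(x)
}

test_result <- function(method, statistic, p_value, df = NA_real_, note = NA_character_) {
  tibble::tibble(method = method, statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value), df = as.numeric(df),
                 note = note)
}

#' Multiple-test-corrected single-SNP TDT
#'
#' Per variant `j`, with `b` minor and `c` major alleles transmitted from
#' heterozygous parents over all trios, the TDT statistic is
#' `(b - c)^2 / (b + c)` on 1 df. The global p-value is the
#' Bonferroni-corrected minimum p over variants with at least one
#' informative transmission, capped at 1.
#'
#' @param tc A `transmission_counts` object.
#' @return One-row tibble (`method`, `statistic`, `p_value`, `df`, `note`);
#'   per-variant statistics are attached as attribute `per_variant`.
#' @export
tdt_single_snp <- function(tc) {
  stopifnot(inherits(tc, "transmission_counts"))
  b <- colSums(tc$B)
  cc <- colSums(tc$C)
  inf <- b + cc > 0
  if (!any(inf)) {
    warning("no informative transmissions at any variant")
    return(test_result("tdt", 0, 1, df = 1, note = "no informative variants"))
  }
  chi <- (b[inf] - cc[inf])^2 / (b[inf] + cc[inf])
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  out <- test_result("tdt", max(chi), min(1, sum(inf) * min(p)), df = 1)
  attr(out, "per_variant") <- tibble::tibble(
    variant = which(inf), b = b[inf], c = cc[inf], statistic = chi, p_value = p)
  out
}

#' UminP test: maximum standardized score component
#'
#' The statistic is `max_j U_j^2 / V_jj` over variants with positive
#' diagonal variance. The asymptotic p-value integrates the multivariate
#' normal rectangle probability implied by the joint null law of `U`
#' (correlation from `V`); the `signflip` method instead flips the signs of
#' whole rows of the transmission (or per-subject score) matrix.
#'
#' @param sc A [score_components()] object.
#' @param method `"asymptotic"` or `"signflip"`.
#' @param n_flips Monte-Carlo size for the sign-flip method.
#' @return One-row result tibble.
#' @export
uminp_test <- function(sc, method = c("asymptotic", "signflip"), n_flips = 1e4) {
  stopifnot(inherits(sc, "score_components"))
  method <- match.arg(method)
  d <- diag(sc$V)
  keep <- which(d > 0)
  if (length(keep) == 0L) {
    warning("no variant has positive score variance")
    return(test_result("uminp", 0, 1, note = "no informative variants"))
  }
  tstat <- max(sc$U[keep]^2 / d[keep])
  if (method == "asymptotic" && length(keep) == 1L) {
    return(test_result("uminp", tstat, 2 * stats::pnorm(-sqrt(tstat)),
                       note = "asymptotic"))
  }
  if (method == "asymptotic" && length(keep) <= 20L) {
    Vk <- sc$V[keep, keep, drop = FALSE]
    R <- stats::cov2cor(Vk)
    z <- sqrt(tstat)
    p <- tryCatch({
      rect <- mvtnorm::pmvnorm(lower = rep(-z, length(keep)),
                               upper = rep(z, length(keep)), corr = R)
      1 - as.numeric(rect)
    }, error = function(e) NA_real_)
    if (!is.na(p)) {
      return(test_result("uminp", tstat, min(max(p, 0), 1), note = "asymptotic"))
    }
  }
  # sign-flip Monte-Carlo fallback / explicit method
  X <- sc$rows[, keep, drop = FALSE]
  n <- nrow(X)
  exceed <- 0L
  for (i in seq_len(n_flips)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    Uf <- colSums(X * s)
    if (max(Uf^2 / d[keep]) >= tstat) exceed <- exceed + 1L
  }
  test_result("uminp", tstat, (1 + exceed) / (n_flips + 1), note = "signflip")
}

#' Score test with the full covariance matrix
#'
#' `T = U' V^- U` with a pseudo-inverse (relative eigenvalue cutoff
#' `1e-8 * max eigenvalue`); null distribution chi-square with df equal to
#' the numerical rank of `V`.
#'
#' @param sc A [score_components()] object.
#' @return One-row result tibble.
#' @export
score_test <- function(sc) {
  stopifnot(inherits(sc, "score_components"))
  eg <- eigen(sc$V, symmetric = TRUE)
  tol <- 1e-8 * max(eg$values, 0)
  keep <- eg$values > tol
  r <- sum(keep)
  if (r == 0L) {
    warning("score covariance has rank zero")
    return(test_result("score", 0, 1, df = 0, note = "rank 0"))
  }
  proj <- crossprod(eg$vectors[, keep, drop = FALSE], sc$U)
  tstat <- sum(proj^2 / eg$values[keep])
  test_result("score", tstat, stats::pchisq(tstat, df = r, lower.tail = FALSE),
              df = r)
}

#' SSU test: sum of squared score components
#'
#' `T = U'U`; the null distribution is the mixture
#' `sum_j lambda_j chisq_1` with `lambda_j` the eigenvalues of `V`,
#' evaluated by [mixture_chisq_pvalue()].
#'
#' @param sc A [score_components()] object.
#' @return One-row result tibble.
#' @export
ssu_test <- function(sc) {
  stopifnot(inherits(sc, "score_components"))
  tstat <- sum(sc$U^2)
  lam <- eigen(sc$V, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  if (max(lam) == 0) {
    warning("score covariance is zero")
    return(test_result("ssu", tstat, 1, note = "zero covariance"))
  }
  test_result("ssu", tstat, mixture_chisq_pvalue(lam, tstat))
}

#' SSUw test: variance-weighted sum of squared score components
#'
#' `T = sum_j U_j^2 / V_jj` over variants with `V_jj > 0`; the null mixture
#' weights are the eigenvalues of `diag(V)^(-1/2) V diag(V)^(-1/2)`
#' restricted to the included variants.
#'
#' @param sc A [score_components()] object.
#' @return One-row result tibble.
#' @export
ssuw_test <- function(sc) {
  stopifnot(inherits(sc, "score_components"))
  d <- diag(sc$V)
  keep <- which(d > 0)
  if (length(keep) == 0L) {
    warning("no variant has positive score variance")
    return(test_result("ssuw", 0, 1, note = "no informative variants"))
  }
  tstat <- sum(sc$U[keep]^2 / d[keep])
  Dh <- 1 / sqrt(d[keep])
  R <- sc$V[keep, keep, drop = FALSE] * tcrossprod(Dh)
  lam <- pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
  test_result("ssuw", tstat, mixture_chisq_pvalue(lam, tstat))
}

#' Sum test: common-effect one-df score test
#'
#' `T = (1'U)^2 / (1'V1)`, chi-square on 1 df. Assumes every variant shifts
#' risk by the same per-allele amount, so opposite-direction effects cancel.
#'
#' @param sc A [score_components()] object.
#' @return One-row result tibble.
#' @export
sum_test <- function(sc) {
  stopifnot(inherits(sc, "score_components"))
  denom <- sum(sc$V)
  if (denom <= 0) {
    warning("1'V1 is not positive")
    return(test_result("sum", 0, 1, df = 1, note = "zero variance"))
  }
  tstat <- sum(sc$U)^2 / denom
  test_result("sum", tstat, stats::pchisq(tstat, df = 1, lower.tail = FALSE),
              df = 1)
}

#' Run the family-based test battery on transmission counts
#'
#' @param tc A `transmission_counts` object.
#' @param tests Character vector among
#'   `c("tdt", "uminp", "score", "ssu", "ssuw", "sum")`.
#' @param ... Passed to individual tests.
#' @return Tibble with one row per test.
#' @export
family_test_battery <- function(tc, tests = c("tdt", "uminp", "score", "ssu",
                                              "ssuw", "sum"), ...) {
  stopifnot(inherits(tc, "transmission_counts"))
  sc <- score_components(tc$X)
  run1 <- function(t) {
    switch(t,
           tdt = tdt_single_snp(tc),
           uminp = uminp_test(sc, ...),
           score = score_test(sc),
           ssu = ssu_test(sc),
           ssuw = ssuw_test(sc),
           sum = sum_test(sc),
           stop("unknown family test: ", t))
  }
  dplyr::bind_rows(lapply(tests, run1))
}
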