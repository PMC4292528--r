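test_that("score components are column sums and centred outer products", {
  X <- rbind(1, -1)
  sc <- score_components(X)
  expect_equal(sc$U, 0)
  expect_equal(unname(sc$V), cbind(2))
  # a zero column contributes nothing
  X2 <- cbind(c(1, -1, 2), 0)
  sc2 <- score_components(X2)
  expect_equal(unname(sc2$U), c(2, 0))
  expect_equal(unname(sc2$V[, 2]), c(0, 0))
  # brute-force double-loop oracle on random data
  set.seed(301)
  X3 <- matrix(sample(-2:2, 60, replace = TRUE), 12, 5)
  sc3 <- score_components(X3)
  xb <- colMeans(X3)
  V <- matrix(0, 5, 5)
  for (i in 1:12) V <- V + tcrossprod(X3[i, ] - xb)
  expect_equal(unname(sc3$V), V)
  expect_equal(unname(sc3$U), colSums(X3))
  expect_error(score_components(matrix(1, 1, 2)), "two trios")
})

test_that("single-SNP TDT applies the Bonferroni-corrected minimum p", {
  # b=10, c=5 at one variant: chi2 = 25/15
  B <- matrix(c(rep(1, 10), rep(0, 5)), ncol = 1)
  C <- matrix(c(rep(0, 10), rep(1, 5)), ncol = 1)
  tc <- famrare:::new_transmission_counts(B, C, 15, 1)
  res <- tdt_single_snp(tc)
  expect_equal(res$statistic, 25 / 15)
  expect_equal(res$p_value, pchisq(25 / 15, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.1967)
  # balanced transmissions at every variant: global p = 1
  tc2 <- famrare:::new_transmission_counts(cbind(c(1, 0), c(1, 0)),
                                           cbind(c(0, 1), c(0, 1)), 2, 2)
  expect_equal(tdt_single_snp(tc2)$p_value, 1)
  # Bonferroni multiplies by the informative-variant count
  B3 <- cbind(c(1, 1, 1, 1), c(0, 0, 0, 0))
  C3 <- cbind(c(0, 0, 0, 0), c(0, 0, 0, 0))
  tc3 <- famrare:::new_transmission_counts(B3, C3, 4, 2)
  expect_equal(tdt_single_snp(tc3)$p_value,
               pchisq(4, 1, lower.tail = FALSE))  # one informative variant only
  tcz <- famrare:::new_transmission_counts(cbind(c(0, 0)), cbind(c(0, 0)), 2, 1)
  expect_warning(rz <- tdt_single_snp(tcz), "informative")
  expect_equal(rz$p_value, 1)
})

test_that("UminP reduces to the two-sided normal for one variant", {
  X <- matrix(c(2, 1, -1, 1, 0, 1), ncol = 1)
  sc <- score_components(X)
  res <- uminp_test(sc)
  z <- sum(X) / sqrt(sc$V[1, 1])
  expect_equal(res$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-4)
})

test_that("UminP with independent variants matches the product rule", {
  # diagonal V: rectangle probability factorises
  set.seed(302)
  sc <- structure(list(U = c(1.5, -2, 0.5), V = diag(c(1, 2, 0.5)),
                       n = 100, m = 3, xbar = rep(0, 3),
                       rows = matrix(0, 100, 3)),
                  class = "score_components")
  res <- uminp_test(sc)
  tmax <- max(sc$U^2 / diag(sc$V))
  expect_equal(res$p_value, 1 - pchisq(tmax, 1)^3, tolerance = 1e-4)
})

test_that("UminP sign-flip agrees with the asymptotic rectangle", {
  set.seed(303)
  fam <- simulate_families("trio", 800, variant_panel(0.2, m = 3),
                           disease_model(0.05, or = c(1.5, 1, 1)))
  sc <- score_components(extract_transmissions(fam)$X)
  pa <- uminp_test(sc)$p_value
  pf <- uminp_test(sc, method = "signflip", n_flips = 4000)$p_value
  expect_lt(abs(pa - pf), 0.04)
  # degenerate zero score
  sc0 <- score_components(rbind(c(1, 0), c(-1, 0)))
  expect_equal(uminp_test(sc0)$statistic, 0)
  expect_gt(uminp_test(sc0)$p_value, 0.95)
})

test_that("the full score test uses the pseudo-inverse rank", {
  sc <- structure(list(U = c(3, 4), V = diag(2), n = 10, m = 2,
                       xbar = c(0, 0), rows = matrix(0, 10, 2)),
                  class = "score_components")
  res <- score_test(sc)
  expect_equal(res$statistic, 25)
  expect_equal(res$df, 2)
  # U in the null space of a singular V gives statistic 0
  V <- matrix(c(1, 1, 1, 1), 2)  # null space spanned by (1,-1)
  sc2 <- structure(list(U = c(1, -1), V = V, n = 10, m = 2, xbar = c(0, 0),
                        rows = matrix(0, 10, 2)), class = "score_components")
  expect_equal(score_test(sc2)$statistic, 0, tolerance = 1e-10)
  expect_equal(score_test(sc2)$df, 1)
  # against a direct linear solve for a random positive-definite V
  set.seed(304)
  A <- matrix(rnorm(16), 4)
  V3 <- crossprod(A) + diag(4)
  U3 <- rnorm(4)
  sc3 <- structure(list(U = U3, V = V3, n = 10, m = 4, xbar = rep(0, 4),
                        rows = matrix(0, 10, 4)), class = "score_components")
  expect_equal(score_test(sc3)$statistic, sum(U3 * solve(V3, U3)),
               tolerance = 1e-10)
})

test_that("SSU and SSUw match their closed forms and scaling laws", {
  sc <- structure(list(U = c(2, 0), V = diag(2), n = 10, m = 2,
                       xbar = c(0, 0), rows = matrix(0, 10, 2)),
                  class = "score_components")
  expect_equal(ssu_test(sc)$statistic, 4)
  # identity V collapses the mixture to a chi-square with m df
  expect_equal(ssu_test(sc)$p_value, pchisq(4, 2, lower.tail = FALSE),
               tolerance = 1e-5)
  # diagonal V: SSUw equals the score test
  scd <- structure(list(U = c(1, 3), V = diag(c(2, 5)), n = 10, m = 2,
                        xbar = c(0, 0), rows = matrix(0, 10, 2)),
                   class = "score_components")
  expect_equal(ssuw_test(scd)$statistic, score_test(scd)$statistic)
  expect_equal(ssuw_test(scd)$p_value, pchisq(ssuw_test(scd)$statistic, 2,
                                              lower.tail = FALSE),
               tolerance = 1e-5)
  # SSUw is invariant to per-variant rescaling of the transmission columns
  set.seed(305)
  X <- matrix(rnorm(200), 50, 4)
  s1 <- ssuw_test(score_components(X))
  s2 <- ssuw_test(score_components(sweep(X, 2, c(2, 0.5, 3, 1), `*`)))
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-10)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-8)
})

test_that("SSU p-values are calibrated against sign-flip resampling", {
  set.seed(306)
  fam <- simulate_families("trio", 400, variant_panel(0.2, m = 4),
                           null_model(m = 4, c = 0.05))
  X <- extract_transmissions(fam)$X
  sc <- score_components(X)
  nf <- 2000
  pvals <- numeric(nf)
  for (i in seq_len(nf)) {
    s <- sample(c(-1, 1), nrow(X), replace = TRUE)
    pvals[i] <- ssu_test(score_components(X * s))$p_value
  }
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("the sum test collapses the score vector to one degree of freedom", {
  sc <- structure(list(U = c(1, 1), V = diag(2), n = 10, m = 2,
                       xbar = c(0, 0), rows = matrix(0, 10, 2)),
                  class = "score_components")
  res <- sum_test(sc)
  expect_equal(res$statistic, 2)
  expect_equal(round(res$p_value, 4), 0.1573)
  # opposite effects cancel
  sc2 <- structure(list(U = c(1, -1), V = diag(2), n = 10, m = 2,
                        xbar = c(0, 0), rows = matrix(0, 10, 2)),
                   class = "score_components")
  expect_equal(sum_test(sc2)$statistic, 0)
  # single variant: same as the per-variant statistic
  sc3 <- score_components(matrix(c(1, -1, 1, 1), ncol = 1))
  expect_equal(sum_test(sc3)$statistic,
               sum(sc3$U)^2 / sc3$V[1, 1])
})

test_that("battery statistics are invariant under variant permutation", {
  set.seed(307)
  fam <- simulate_families("trio", 300, variant_panel(c(0.1, 0.2, 0.3), m = 3),
                           disease_model(0.05, or = c(2, 1, 1)))
  X <- extract_transmissions(fam)$X
  perm <- c(2, 3, 1)
  a <- family_test_battery(famrare:::new_transmission_counts(
    pmax(X, 0), pmax(-X, 0), nrow(X), 3),
    tests = c("uminp", "score", "ssu", "ssuw", "sum"))
  # permuting columns leaves every statistic unchanged
  Xp <- X[, perm]
  b <- family_test_battery(famrare:::new_transmission_counts(
    pmax(Xp, 0), pmax(-Xp, 0), nrow(Xp), 3),
    tests = c("uminp", "score", "ssu", "ssuw", "sum"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
})
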