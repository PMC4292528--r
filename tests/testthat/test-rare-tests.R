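test_that("case-control score components match the logistic null score", {
  cc <- manual_cc(G = cbind(c(1, 0, 0, 0)), y = c(1, 1, 0, 0))
  sc <- cc_score_components(cc)
  expect_equal(unname(sc$U), 0.5)
  # brute-force per-subject double loop
  set.seed(401)
  G <- matrix(rbinom(60, 2, 0.3), 20, 3)
  y <- rep(c(1, 0), 10)
  cc2 <- manual_cc(G, y)
  sc2 <- cc_score_components(cc2)
  U <- numeric(3); V <- matrix(0, 3, 3)
  yb <- mean(y); gb <- colMeans(G)
  for (i in 1:20) {
    U <- U + G[i, ] * (y[i] - yb)
    V <- V + yb * (1 - yb) * tcrossprod(G[i, ] - gb)
  }
  expect_equal(unname(sc2$U), U)
  expect_equal(unname(sc2$V), V)
  # permuting subjects changes nothing
  p <- sample(20)
  sc3 <- cc_score_components(manual_cc(G[p, ], y[p]))
  expect_equal(sc3$U, sc2$U)
  expect_equal(sc3$V, sc2$V)
  expect_error(cc_score_components(manual_cc(G, rep(1, 20))), "cases and controls")
})

test_that("single-SNP association equals n r^2 per variant with Bonferroni", {
  set.seed(402)
  G <- cbind(rbinom(40, 2, 0.3), rbinom(40, 2, 0.2), 0)  # third monomorphic
  y <- rep(c(1, 0), 20)
  res <- single_snp_association(manual_cc(G, y))
  pv <- attr(res, "per_variant")
  expect_equal(nrow(pv), 2)  # monomorphic variant excluded
  # score chi-square for binary y is n * cor^2
  for (j in 1:2) {
    expect_equal(pv$statistic[pv$variant == j], 40 * cor(G[, j], y)^2,
                 tolerance = 1e-10)
  }
  expect_equal(res$p_value, min(1, 2 * min(pv$p_value)))
  # single variant: no correction
  res1 <- single_snp_association(manual_cc(G[, 1, drop = FALSE], y))
  expect_equal(res1$p_value, attr(res1, "per_variant")$p_value)
})

test_that("C-alpha statistic and variance match hand enumeration", {
  # p0 = 1/2, one variant with both copies in cases: T = 0.5, c = 0.25, Z = 1
  cc <- manual_cc(G = cbind(c(2, 0, 0, 0)), y = c(1, 1, 0, 0))
  res <- calpha_statistic(cc)
  expect_equal(res$statistic, 1.0)  # Z = T / sqrt(c) = 0.5 / 0.5
  expect_equal(res$p_value, pnorm(1, lower.tail = FALSE))
  # singletons contribute nothing at p0 = 1/2
  cc2 <- manual_cc(G = cbind(c(1, 0, 0, 0), c(0, 0, 1, 0), c(2, 0, 0, 0)),
                   y = c(1, 1, 0, 0))
  res2 <- calpha_statistic(cc2)
  expect_equal(res2$statistic, 1.0)  # only the n=2 variant contributes
  # perfectly balanced copies give a negative statistic (under-dispersion)
  cc3 <- manual_cc(G = cbind(c(1, 1, 1, 1)), y = c(1, 1, 0, 0))
  res3 <- calpha_statistic(cc3)
  expect_lt(res3$statistic, 0)
  expect_gt(res3$p_value, 0.5)
})

test_that("permutation C-alpha is one-sided and add-one corrected", {
  set.seed(403)
  # cases identical to controls: observed T at the permutation centre
  G <- rbind(matrix(rbinom(40, 2, 0.2), 10), matrix(rbinom(40, 2, 0.2), 10))
  y <- rep(c(1, 0), each = 10)
  res <- calpha_permutation(manual_cc(G, y), n_perm = 500)
  expect_gte(res$p_value, 1 / 501)
  expect_lte(res$p_value, 1)
  # p stabilises as the permutation budget grows
  set.seed(404)
  p1 <- calpha_permutation(manual_cc(G, y), n_perm = 400)$p_value
  set.seed(404)
  p2 <- calpha_permutation(manual_cc(G, y), n_perm = 1600)$p_value
  expect_lt(abs(p1 - p2), 0.12)
})

test_that("Beta-density MAF weights follow the closed form", {
  w <- beta_maf_weights(c(0, 0.005, 0.5), a1 = 1, a2 = 25)
  expect_equal(w$w[1], 25)
  expect_equal(w$w[2], 25 * 0.995^24)
  expect_equal(round(w$w[2], 2), 22.17)
  expect_equal(beta_maf_weights(c(0.1, 0.4), 1, 1)$w, c(1, 1))
})

test_that("SKAT with unit weights is exactly the SSU test", {
  set.seed(405)
  G <- matrix(rbinom(300, 2, 0.05), 100, 3)
  y <- rep(c(1, 0), 50)
  cc <- manual_cc(G, y)
  sc <- cc_score_components(cc)
  skat <- skat_test(cc, weights = beta_maf_weights(colMeans(G) / 2, 1, 1))
  ssu <- ssu_test(sc)
  expect_equal(skat$statistic, sum(sc$U^2))
  expect_equal(skat$statistic, ssu$statistic)
  expect_equal(skat$p_value, ssu$p_value, tolerance = 1e-10)
  # zero genotype matrix
  expect_equal(skat_test(manual_cc(matrix(0, 10, 2), rep(c(1, 0), 5)))$p_value, 1)
})

test_that("SKAT asymptotic p-values agree with label permutation", {
  set.seed(406)
  G <- matrix(rbinom(600, 2, 0.1), 200, 3)
  y <- rep(c(1, 0), 100)
  cc <- manual_cc(G, y)
  obs <- skat_test(cc)
  nperm <- 4000
  qs <- numeric(nperm)
  w <- beta_maf_weights(colMeans(G) / 2)
  for (i in seq_len(nperm)) {
    yp <- sample(y)
    s <- as.vector(crossprod(G, yp - mean(yp)))
    qs[i] <- sum(w$w^2 * s^2)
  }
  pperm <- (1 + sum(qs >= obs$statistic)) / (nperm + 1)
  se <- sqrt(pperm * (1 - pperm) / nperm)
  expect_lt(abs(obs$p_value - pperm), 4 * se + 0.01)
})

test_that("KBAC matches exhaustive enumeration on a toy sample", {
  # 4 cases, 4 controls, 2 variants
  G <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 0),
             c(1, 0), c(0, 0), c(0, 0), c(0, 0))
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  cc <- manual_cc(G, y)
  # independent oracle: direct statistic from class counts
  kbac_oracle <- function(yy) {
    carrier <- rowSums(G) > 0
    key <- apply(G[carrier, , drop = FALSE], 1, paste, collapse = ",")
    nA <- sum(yy == 1); nU <- sum(yy == 0)
    s <- 0
    for (k in unique(key)) {
      rows <- which(key == k)
      a <- sum(yy[carrier][rows] == 1)
      t <- length(rows)
      s <- s + phyper(a, nA, nU, t) * (a / nA - (t - a) / nU)
    }
    s
  }
  set.seed(407)
  res <- kbac_test(cc, n_perm = 2000)
  expect_equal(res$statistic, kbac_oracle(y))
  # exact permutation p by exhaustive enumeration over all case assignments
  combs <- combn(8, 4)
  stats <- apply(combs, 2, function(idx) {
    yy <- rep(0, 8); yy[idx] <- 1
    kbac_oracle(yy)
  })
  pexact <- mean(stats >= res$statistic - 1e-12)
  expect_lt(abs(res$p_value - pexact), 3 * sqrt(pexact * (1 - pexact) / 2000) + 1e-3)
})

test_that("KBAC degenerate inputs behave as documented", {
  # identical case and control genotype tables: statistic 0
  G <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  res <- kbac_test(manual_cc(G, c(1, 1, 0, 0)), n_perm = 100)
  expect_equal(res$statistic, 0)
  # one class carried only by cases saturates the kernel
  G2 <- rbind(c(2, 1), c(2, 1), c(0, 0), c(0, 0))
  res2 <- kbac_test(manual_cc(G2, c(1, 1, 0, 0)), n_perm = 100)
  expect_gt(res2$statistic, 0)
  expect_equal(res2$statistic, 1 * (2 / 2 - 0 / 2))  # k saturates at 1
  # all-null genotypes warn
  expect_warning(res3 <- kbac_test(manual_cc(matrix(0, 4, 2), c(1, 1, 0, 0)),
                                   n_perm = 100), "non-null")
  expect_equal(res3$p_value, 1)
})

test_that("analytic C-alpha tracks the SSU ordering on shared data", {
  # rank agreement between the two variance-component statistics
  set.seed(408)
  zs <- numeric(40); ts <- numeric(40)
  panel <- variant_panel(0.05, m = 5)
  mod <- disease_model(0.05, or = c(1.5, 1.5, 1, 1, 1))
  for (i in 1:40) {
    fam <- simulate_families("trio", 150, panel, mod)
    ctl <- simulate_controls(panel, mod, 150)
    ucc <- make_ucc(fam, ctl)
    zs[i] <- calpha_statistic(ucc)$statistic
    ts[i] <- ssu_test(cc_score_components(ucc))$statistic
  }
  expect_gt(cor(zs, ts, method = "spearman"), 0.95)
})
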