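# Mendelian transmission table: rows index the ordered parental genotype pair
# (gf, gm) as 3*gf + gm + 1, columns the child minor-allele count 0..2.
mendel_matrix <- local({
  M <- matrix(0, 9, 3)
  for (gf in 0:2) {
    for (gm in 0:2) {
      pf <- gf / 2  # P(father transmits a minor allele)
      pm <- gm / 2
      r <- 3 * gf + gm + 1
      M[r, 1] <- (1 - pf) * (1 - pm)
      M[r, 2] <- pf * (1 - pm) + (1 - pf) * pm
      M[r, 3] <- pf * pm
    }
  }
  M
})

hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

new_family_sample <- function(structure, father, mother, children,
                              panel, stratum = NULL) {
  structure(list(structure = structure, father = father, mother = mother,
                 children = children, panel = panel,
                 n = nrow(father), stratum = stratum),
            class = "family_sample")
}

#' @export
print.family_sample <- function(x, ...) {
  cat(sprintf("family_sample: %d %s families, %d variants, %d affected child(ren) per family\n",
              x$n, x$structure, ncol(x$father), length(x$children)))
  invisible(x)
}

#' Sample unrelated parental genotypes under Hardy-Weinberg equilibrium
#'
#' @param panel A [variant_panel()].
#' @param n Number of parent pairs.
#' @return List with `father` and `mother`, each an `n x m` matrix of
#'   minor-allele counts.
#' @export
sample_parents <- function(panel, n) {
  stopifnot(inherits(panel, "variant_panel"), n >= 1)
  m <- nrow(panel)
  draw <- function() {
    g <- vapply(panel$maf, function(q) stats::rbinom(n, 2L, q), integer(n))
    matrix(g, nrow = n, ncol = m)
  }
  list(father = draw(), mother = draw())
}

#' Transmit alleles from parents to one child
#'
#' Each parent passes one allele per variant; a heterozygous parent passes
#' the minor or major allele with probability one half each. The per-parent
#' transmitted-minor-allele indicators are returned so transmission counts
#' derived from genotypes alone can be cross-checked against the realised
#' transmissions.
#'
#' @param father_g,mother_g `n x m` matrices of parental minor-allele counts.
#' @return List with `child` (`n x m` counts), `father_minor`, `mother_minor`
#'   (0/1 indicators of a transmitted minor allele).
#' @export
mendelian_transmit <- function(father_g, mother_g) {
  stopifnot(is.matrix(father_g), all(dim(father_g) == dim(mother_g)))
  tf <- matrix(stats::rbinom(length(father_g), 1L, father_g / 2),
               nrow = nrow(father_g))
  tm <- matrix(stats::rbinom(length(mother_g), 1L, mother_g / 2),
               nrow = nrow(mother_g))
  list(child = tf + tm, father_minor = tf, mother_minor = tm)
}

# --- exact tilted ascertainment sampler ------------------------------------
#
# Affection depends on the offspring genotype only, so the ascertained joint
# law factorises: (i) the child (or sib-pair) genotypes at causal variants
# follow the Hardy-Weinberg (pair) marginal tilted by the penetrance of each
# affected child; (ii) non-causal child genotypes follow the untilted
# marginal; (iii) parents are drawn from their exact conditional given the
# child genotypes. Step (i) is computed by a forward-backward dynamic program
# over the per-child causal burden, so no truncation is involved.

# joint law of two sibs' genotypes at one variant, parents integrated out;
# 9-vector indexed 3*gc1 + gc2 + 1
sib_pair_probs <- function(q) {
  h <- hwe_probs(q)
  hp <- as.vector(outer(h, h))  # parent-pair probs, index 3*gf+gm+1
  out <- numeric(9)
  for (a in 0:2) for (b in 0:2) {
    out[3 * a + b + 1] <- sum(hp * mendel_matrix[, a + 1] * mendel_matrix[, b + 1])
  }
  out
}

state_key <- function(S) {
  if (is.null(dim(S))) S <- matrix(S, ncol = 1)
  apply(S, 1, paste, collapse = "|")
}

# Burden states are integer matrices: per child, the total minor-allele count
# within each group of causal variants sharing the same effect size. Integer
# states make the backward pass match forward states exactly.

# forward DP over causal variants
burden_forward <- function(group, n_groups, outcomes, outcome_probs, nch,
                           max_states = 2e5) {
  K <- length(group)
  fw <- vector("list", K + 1)
  fw[[1]] <- list(S = matrix(0L, 1, nch * n_groups), p = 1)
  for (j in seq_len(K)) {
    oc <- outcomes[[j]]          # n_out x nch child genotype tuples
    op <- outcome_probs[[j]]
    cols <- (seq_len(nch) - 1L) * n_groups + group[j]
    old <- fw[[j]]
    nold <- nrow(old$S)
    nout <- nrow(oc)
    S <- old$S[rep(seq_len(nold), times = nout), , drop = FALSE]
    S[, cols] <- S[, cols] + oc[rep(seq_len(nout), each = nold), , drop = FALSE]
    p <- rep(old$p, times = nout) * rep(op, each = nold)
    key <- state_key(S)
    first <- !duplicated(key)
    idx <- match(key, key[first])
    pagg <- as.vector(tapply(p, idx, sum))
    if (sum(first) > max_states) {
      stop("burden state space too large for the tilted sampler; use method = \"rejection\"")
    }
    fw[[j + 1]] <- list(S = S[first, , drop = FALSE], p = pagg)
  }
  fw
}

# sample child genotypes at causal variants for n ascertained families
sample_causal_children <- function(n, beta_causal, outcomes, outcome_probs,
                                   nch, l0) {
  K <- length(beta_causal)
  beta_groups <- unique(beta_causal)
  group <- match(beta_causal, beta_groups)
  G <- length(beta_groups)
  fw <- burden_forward(group, G, outcomes, outcome_probs, nch)
  top <- fw[[K + 1]]
  w <- rep(1, nrow(top$S))
  for (k in seq_len(nch)) {
    eta <- as.vector(top$S[, (k - 1L) * G + seq_len(G), drop = FALSE] %*% beta_groups)
    w <- w * stats::plogis(l0 + eta)
  }
  probs <- top$p * w
  if (!any(probs > 0)) stop("ascertainment probability is zero under this model")
  cur <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  geno <- array(0L, dim = c(n, K, nch))
  for (j in K:1) {
    oc <- outcomes[[j]]
    op <- outcome_probs[[j]]
    cols <- (seq_len(nch) - 1L) * G + group[j]
    prev <- fw[[j]]
    prev_key <- state_key(prev$S)
    cur_tab <- fw[[j + 1]]
    nxt <- integer(n)
    for (s in unique(cur)) {
      fams <- which(cur == s)
      # previous state reached by undoing each outcome
      Sprev <- matrix(cur_tab$S[s, ], nrow(oc), ncol(cur_tab$S), byrow = TRUE)
      Sprev[, cols] <- Sprev[, cols] - oc
      prev_idx <- match(state_key(Sprev), prev_key)
      pi_prev <- prev$p[prev_idx]
      pi_prev[is.na(pi_prev)] <- 0
      pr <- op * pi_prev
      pick <- sample.int(nrow(oc), length(fams), replace = TRUE, prob = pr)
      geno[fams, j, ] <- oc[pick, ]
      nxt[fams] <- prev_idx[pick]
    }
    cur <- nxt
  }
  geno
}

# parents conditional on child genotype(s) at one variant: list over child
# outcome index of 9-vectors over (gf, gm)
parent_conditionals <- function(q, nch) {
  h <- hwe_probs(q)
  hp <- as.vector(outer(h, h))
  if (nch == 1L) {
    lapply(0:2, function(gc) hp * mendel_matrix[, gc + 1])
  } else {
    lapply(0:8, function(k) {
      a <- k %/% 3; b <- k %% 3
      hp * mendel_matrix[, a + 1] * mendel_matrix[, b + 1]
    })
  }
}

sample_parents_given_children <- function(children_idx, cond) {
  # children_idx: per-family child-outcome index (0-based); cond: conditionals
  n <- length(children_idx)
  par_idx <- integer(n)
  for (k in unique(children_idx)) {
    fams <- which(children_idx == k)
    pr <- cond[[k + 1]]
    par_idx[fams] <- sample.int(9L, length(fams), replace = TRUE, prob = pr)
  }
  list(father = (par_idx - 1L) %/% 3L, mother = (par_idx - 1L) %% 3L)
}

#' Simulate nuclear families ascertained on affected offspring
#'
#' Families are drawn from the distribution induced by Hardy-Weinberg
#' parental genotypes, Mendelian transmission, the logistic penetrance
#' model, and ascertainment: trios condition on the single child being
#' affected, affected sib-pairs (`asp`) on both children, and enriched trios
#' are affected sib-pairs with one affected sibling discarded. The default
#' sampler draws from the exact ascertained distribution (see Details);
#' `method = "rejection"` performs naive rejection sampling and is retained
#' as a validation oracle and as a fallback for high-prevalence models.
#'
#' @details The exact sampler enumerates the tilted distribution of offspring
#'   genotypes at causal variants via a dynamic program over the per-child
#'   causal burden, then draws parents from their conditional distribution
#'   given the offspring. Its output distribution equals that of naive
#'   rejection sampling, without the `O(1/prevalence)` (trios) or
#'   `O(1/prevalence^2)` (sib-pairs) acceptance cost.
#'
#' @param structure One of `"trio"`, `"asp"`, `"enriched_trio"`.
#' @param n_families Number of families to return.
#' @param panel A [variant_panel()].
#' @param model A [disease_model()].
#' @param method `"tilted"` (exact, default) or `"rejection"`.
#' @param max_attempts Rejection-sampling guard: total families drawn before
#'   giving up.
#' @return A `family_sample`: matrices `father`, `mother` and a list
#'   `children` of one (`trio`, `enriched_trio`) or two (`asp`) `n x m`
#'   offspring genotype matrices; all retained children are affected.
#' @examples
#' panel <- variant_panel(0.05, m = 2)
#' mod <- disease_model(0.05, or = c(2, 1))
#' fam <- simulate_families("trio", 100, panel, mod)
#' @export
simulate_families <- function(structure = c("trio", "asp", "enriched_trio"),
                              n_families, panel, model,
                              method = c("tilted", "rejection"),
                              max_attempts = 1e6) {
  structure <- match.arg(structure)
  method <- match.arg(method)
  stopifnot(inherits(panel, "variant_panel"), inherits(model, "disease_model"),
            n_families >= 1)
  m <- nrow(panel)
  if (length(model$beta) != m) stop("panel/model dimension mismatch")
  if (model$c == 0 && all(model$beta == 0)) {
    stop("ascertainment probability is zero under this model")
  }
  nch <- if (structure == "trio") 1L else 2L
  if (method == "rejection") {
    fam <- reject_families(nch, n_families, panel, model, max_attempts)
  } else {
    fam <- tilted_families(nch, n_families, panel, model)
  }
  if (structure == "enriched_trio") fam$children <- fam$children[1]
  new_family_sample(structure, fam$father, fam$mother, fam$children, panel)
}

tilted_families <- function(nch, n, panel, model) {
  m <- nrow(panel)
  l0 <- stats::qlogis(model$c)
  causal <- which(model$beta != 0)
  if (nch == 1L) {
    oc_tuples <- matrix(0:2, 3, 1)
    oc_prob <- function(q) hwe_probs(q)
  } else {
    oc_tuples <- cbind(rep(0:2, each = 3), rep(0:2, times = 3))
    oc_prob <- function(q) {
      p <- sib_pair_probs(q)
      # reorder to match oc_tuples (gc1 outer, gc2 inner)
      p[3 * oc_tuples[, 1] + oc_tuples[, 2] + 1]
    }
  }
  children <- array(0L, dim = c(n, m, nch))
  if (length(causal) > 0) {
    outcomes <- rep(list(oc_tuples), length(causal))
    oprobs <- lapply(panel$maf[causal], oc_prob)
    children[, causal, ] <- sample_causal_children(
      n, model$beta[causal], outcomes, oprobs, nch, l0)
  } else if (model$c <= 0) {
    stop("ascertainment probability is zero under this model")
  }
  noncausal <- setdiff(seq_len(m), causal)
  for (j in noncausal) {
    pr <- oc_prob(panel$maf[j])
    pick <- sample.int(nrow(oc_tuples), n, replace = TRUE, prob = pr)
    children[, j, ] <- oc_tuples[pick, ]
  }
  father <- matrix(0L, n, m)
  mother <- matrix(0L, n, m)
  cond_cache <- list()
  for (j in seq_len(m)) {
    qk <- as.character(panel$maf[j])
    if (is.null(cond_cache[[qk]])) {
      cond_cache[[qk]] <- parent_conditionals(panel$maf[j], nch)
    }
    child_idx <- if (nch == 1L) children[, j, 1] else 3L * children[, j, 1] + children[, j, 2]
    par <- sample_parents_given_children(child_idx, cond_cache[[qk]])
    father[, j] <- par$father
    mother[, j] <- par$mother
  }
  kids <- lapply(seq_len(nch), function(k) {
    matrix(children[, , k], nrow = n, ncol = m)
  })
  list(father = father, mother = mother, children = kids)
}

reject_families <- function(nch, n, panel, model, max_attempts) {
  m <- nrow(panel)
  father <- matrix(0L, 0, m); mother <- matrix(0L, 0, m)
  kids <- replicate(nch, matrix(0L, 0, m), simplify = FALSE)
  attempts <- 0
  batch <- max(1000L, n)
  while (nrow(father) < n) {
    if (attempts >= max_attempts) {
      stop("rejection sampler exceeded max_attempts; ascertainment probability too small")
    }
    b <- min(batch, max_attempts - attempts)
    attempts <- attempts + b
    par <- sample_parents(panel, b)
    drawn <- lapply(seq_len(nch), function(k) {
      mendelian_transmit(par$father, par$mother)$child
    })
    aff <- Reduce(`&`, lapply(drawn, function(ch) {
      stats::runif(b) < affection_prob(model, ch)
    }))
    keep <- which(aff)
    father <- rbind(father, par$father[keep, , drop = FALSE])
    mother <- rbind(mother, par$mother[keep, , drop = FALSE])
    for (k in seq_len(nch)) {
      kids[[k]] <- rbind(kids[[k]], drawn[[k]][keep, , drop = FALSE])
    }
  }
  idx <- seq_len(n)
  list(father = father[idx, , drop = FALSE], mother = mother[idx, , drop = FALSE],
       children = lapply(kids, function(x) x[idx, , drop = FALSE]))
}

#' Simulate unrelated controls from the population
#'
#' Subjects are drawn from Hardy-Weinberg genotype frequencies; with
#' `screened = TRUE` (default) affected subjects are rejected so the sample
#' consists of confirmed unaffected controls. At prevalences around 1% the
#' difference from unscreened population controls is negligible.
#'
#' @param panel A [variant_panel()].
#' @param model A [disease_model()] (used for screening).
#' @param n Number of controls.
#' @param screened Reject affected subjects?
#' @param max_attempts Screening guard: total subjects drawn before giving up.
#' @return A `cohort_sample` with genotype matrix `G` and logical `affected`
#'   (all `FALSE` when screened).
#' @export
simulate_controls <- function(panel, model, n, screened = TRUE,
                              max_attempts = 1e6) {
  stopifnot(inherits(panel, "variant_panel"), inherits(model, "disease_model"),
            n >= 1)
  m <- nrow(panel)
  draw <- function(b) {
    matrix(vapply(panel$maf, function(q) stats::rbinom(b, 2L, q), integer(b)),
           nrow = b, ncol = m)
  }
  if (!screened) {
    G <- draw(n)
    aff <- stats::runif(n) < affection_prob(model, G)
    return(structure(list(G = G, affected = aff, stratum = NULL),
                     class = "cohort_sample"))
  }
  G <- matrix(0L, 0, m)
  attempts <- 0
  while (nrow(G) < n) {
    if (attempts >= max_attempts) {
      stop("control screening exceeded max_attempts; affection probability too high")
    }
    b <- min(max(1000L, n), max_attempts - attempts)
    attempts <- attempts + b
    cand <- draw(b)
    keep <- stats::runif(b) >= affection_prob(model, cand)
    G <- rbind(G, cand[keep, , drop = FALSE])
  }
  structure(list(G = G[seq_len(n), , drop = FALSE],
                 affected = rep(FALSE, n), stratum = NULL),
            class = "cohort_sample")
}

#' @export
print.cohort_sample <- function(x, ...) {
  cat(sprintf("cohort_sample: %d subjects, %d variants\n", nrow(x$G), ncol(x$G)))
  invisible(x)
}

#' Simulate families and controls from a stratified population
#'
#' Each stratum has its own variant panel and disease model; families (and
#' controls) are allocated to strata in proportion to the stratum weights and
#' each family lies wholly within one stratum. Stratum labels are retained.
#'
#' @param strata List of strata, each a list with elements `weight`, `panel`
#'   and `model`; weights must sum to 1 and all panels share the variant count.
#' @param structure Family structure, as in [simulate_families()].
#' @param n_families Total number of families.
#' @param n_controls Total number of unrelated controls (0 for none).
#' @param ... Passed on to [simulate_families()] and [simulate_controls()].
#' @return List with `families` (a `family_sample`) and `controls` (a
#'   `cohort_sample` or `NULL`).
#' @export
simulate_stratified <- function(strata, structure, n_families, n_controls = 0,
                                ...) {
  stopifnot(length(strata) >= 1)
  w <- vapply(strata, function(s) s$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("stratum weights must sum to 1")
  m <- nrow(strata[[1]]$panel)
  if (!all(vapply(strata, function(s) nrow(s$panel), numeric(1)) == m)) {
    stop("all strata must share the same number of variants")
  }
  nf <- as.vector(stats::rmultinom(1, n_families, w))
  nc <- if (n_controls > 0) as.vector(stats::rmultinom(1, n_controls, w)) else rep(0L, length(strata))
  fams <- list(); ctrls <- list()
  for (i in seq_along(strata)) {
    if (nf[i] > 0) {
      f <- simulate_families(structure, nf[i], strata[[i]]$panel, strata[[i]]$model, ...)
      f$stratum <- rep(i, nf[i])
      fams[[length(fams) + 1]] <- f
    }
    if (nc[i] > 0) {
      ctl <- simulate_controls(strata[[i]]$panel, strata[[i]]$model, nc[i])
      ctl$stratum <- rep(i, nc[i])
      ctrls[[length(ctrls) + 1]] <- ctl
    }
  }
  families <- Reduce(bind_family_samples, fams)
  controls <- if (length(ctrls) > 0) Reduce(bind_cohort_samples, ctrls) else NULL
  list(families = families, controls = controls)
}

bind_family_samples <- function(a, b) {
  stopifnot(a$structure == b$structure, length(a$children) == length(b$children))
  new_family_sample(
    a$structure,
    rbind(a$father, b$father), rbind(a$mother, b$mother),
    Map(rbind, a$children, b$children),
    a$panel, stratum = c(a$stratum, b$stratum))
}

bind_cohort_samples <- function(a, b) {
  structure(list(G = rbind(a$G, b$G), affected = c(a$affected, b$affected),
                 stratum = c(a$stratum, b$stratum)),
            class = "cohort_sample")
}
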