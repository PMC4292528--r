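new_transmission_counts <- function(B, C, n, m) {
  structure(list(B = B, C = C, X = B - C, n = n, m = m),
            class = "transmission_counts")
}

#' @export
print.transmission_counts <- function(x, ...) {
  cat(sprintf("transmission_counts: %d trios x %d variants\n", x$n, x$m))
  invisible(x)
}

new_cc_data <- function(G, y, cluster) {
  structure(list(G = G, y = as.integer(y), cluster = cluster),
            class = "cc_data")
}

#' @export
print.cc_data <- function(x, ...) {
  cat(sprintf("cc_data: %d cases, %d controls, %d variants\n",
              sum(x$y == 1), sum(x$y == 0), ncol(x$G)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.cc_data <- function(x, ...) {
  g <- tibble::as_tibble(as.data.frame(x$G), .name_repair = "minimal")
  names(g) <- paste0("g", seq_len(ncol(x$G)))
  dplyr::bind_cols(
    tibble::tibble(subject = seq_along(x$y), phenotype = x$y, cluster = x$cluster),
    g)
}

# per-child transmission rows; each affected sib contributes one trio row
child_transmissions <- function(father, mother, child) {
  hom_minor <- (father == 2L) + (mother == 2L)
  het <- (father == 1L) + (mother == 1L)
  B <- child - hom_minor
  C <- het - B
  bad <- which(B < 0 | C < 0 | B > 2 | C > 2, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("Mendelian inconsistency in family %d at variant %d",
                 bad[1, 1], bad[1, 2]))
  }
  list(B = B, C = C)
}

#' Transmission counts from family data
#'
#' For each trio and variant, `B` counts minor alleles transmitted to the
#' affected offspring from heterozygous parents and `C` the major alleles
#' transmitted from heterozygous parents; the transmission-disequilibrium
#' contribution is `X = B - C`. Affected sib-pairs are treated as two
#' independent trios sharing parents (no prior hypothesis of linkage), so an
#' `asp` sample yields two rows per family.
#'
#' The counting rule `B = g_child - #(homozygous-minor parents)` needs no
#' phase information: a homozygous parent's transmission is forced, so every
#' minor allele beyond those forced copies came from a heterozygous parent.
#'
#' @param fam A `family_sample`.
#' @return A `transmission_counts` object with matrices `B`, `C`, `X`.
#' @export
extract_transmissions <- function(fam) {
  stopifnot(inherits(fam, "family_sample"))
  parts <- lapply(fam$children, function(ch) {
    child_transmissions(fam$father, fam$mother, ch)
  })
  # interleave rows so each family's sibs are adjacent
  nch <- length(parts)
  B <- do.call(rbind, lapply(parts, `[[`, "B"))
  C <- do.call(rbind, lapply(parts, `[[`, "C"))
  ord <- order(rep(seq_len(fam$n), times = nch))
  new_transmission_counts(B[ord, , drop = FALSE], C[ord, , drop = FALSE],
                          n = fam$n * nch, m = ncol(fam$father))
}

#' Pseudo-case-control data from family data
#'
#' Each affected offspring becomes a case; one pseudo-control per offspring
#' is built from the two untransmitted parental alleles, so
#' `g_case + g_pseudo = g_father + g_mother` at every variant. Cluster labels
#' group siblings and their pseudo-controls by family.
#'
#' @param fam A `family_sample`.
#' @return A `cc_data` object with equal numbers of cases and controls.
#' @export
make_pcc <- function(fam) {
  stopifnot(inherits(fam, "family_sample"))
  # validate Mendelian consistency with the same rule as transmissions
  invisible(lapply(fam$children, function(ch) {
    child_transmissions(fam$father, fam$mother, ch)
  }))
  cases <- do.call(rbind, fam$children)
  pseudo <- do.call(rbind, lapply(fam$children, function(ch) {
    fam$father + fam$mother - ch
  }))
  famid <- rep(seq_len(fam$n), times = length(fam$children))
  new_cc_data(rbind(cases, pseudo),
              c(rep(1L, nrow(cases)), rep(0L, nrow(pseudo))),
              c(famid, famid))
}

#' Unrelated-case-control data from family data plus population controls
#'
#' Affected offspring are retained as cases (two per `asp` family) and
#' unrelated controls are appended; parental genotypes are discarded.
#' Sibling cases share a cluster label. When the number of controls equals
#' the number of cases, controls are grouped in input order into blocks
#' matching the case-cluster sizes so that [cluster_related()] can sum them
#' the same way; any exchangeable grouping of the unrelated controls yields
#' the same null distribution.
#'
#' @param fam A `family_sample`.
#' @param controls A `cohort_sample` on the same variant panel.
#' @return A `cc_data` object.
#' @export
make_ucc <- function(fam, controls) {
  stopifnot(inherits(fam, "family_sample"), inherits(controls, "cohort_sample"))
  if (ncol(controls$G) != ncol(fam$father)) {
    stop("controls and families are on different variant panels")
  }
  cases <- do.call(rbind, fam$children)
  nch <- length(fam$children)
  case_cluster <- rep(seq_len(fam$n), times = nch)
  n_ctl <- nrow(controls$G)
  if (n_ctl == nrow(cases)) {
    # blocks of the case-cluster sizes, in input order
    ctl_cluster <- rep(seq_len(fam$n), each = nch)
  } else {
    ctl_cluster <- rep(NA_integer_, n_ctl)
  }
  new_cc_data(rbind(cases, controls$G),
              c(rep(1L, nrow(cases)), rep(0L, n_ctl)),
              c(case_cluster, ctl_cluster))
}

#' Collapse related cases (and matched controls) into composite subjects
#'
#' Cases sharing a cluster label have their minor-allele counts summed into
#' a single composite case, and the matched controls are summed in the same
#' group sizes; the sample size shrinks by the per-family case count (a
#' factor of 2 for affected sib-pairs) but the composite subjects are
#' independent, restoring the sampling assumptions of the case-control
#' tests. Output cluster labels are singletons. This is equivalent to using
#' families rather than individuals as the sampling unit of the score
#' vector and its covariance.
#'
#' @param cc A `cc_data` object with cluster labels.
#' @return A `cc_data` object with one row per cluster and arm.
#' @export
cluster_related <- function(cc) {
  stopifnot(inherits(cc, "cc_data"))
  if (anyNA(cc$cluster)) {
    stop("cluster labels are missing; controls cannot be matched to case clusters")
  }
  case_sizes <- table(cc$cluster[cc$y == 1])
  ctl_sizes <- table(cc$cluster[cc$y == 0])
  if (length(case_sizes) != length(ctl_sizes) ||
      !all(names(case_sizes) == names(ctl_sizes)) ||
      !all(as.vector(case_sizes) == as.vector(ctl_sizes))) {
    stop("control counts per cluster do not match case counts")
  }
  lev <- sort(unique(cc$cluster))
  sum_arm <- function(arm) {
    f <- factor(cc$cluster[cc$y == arm], levels = lev)
    unname(rowsum(cc$G[cc$y == arm, , drop = FALSE], f))
  }
  Gcase <- sum_arm(1L)
  Gctl <- sum_arm(0L)
  new_cc_data(rbind(Gcase, Gctl),
              c(rep(1L, nrow(Gcase)), rep(0L, nrow(Gctl))),
              c(seq_along(lev), seq_along(lev)))
}
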