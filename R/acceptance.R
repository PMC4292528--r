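#' Reproduce the headline type-I-error and power estimates
#'
#' Re-runs the simulation study cells that summarise the method comparison:
#' under the global null (10 variants, MAF 0.5%, all OR 1, background risk
#' 1%, 1200 cases), the type-I error of the corrected single-SNP TDT and the
#' SSU test on trio transmission data, and of the corrected single-SNP
#' association test, permutation C-alpha and SKAT on unclustered
#' unrelated-case-control data built from affected-sib-pair cases; and, in
#' the baseline causal scenarios (4 causal variants; OR 2.00 for trios, 1.72
#' for sib-pairs, 1.54 for enriched trios), the power of the TDT (trios,
#' family format), SSU (clustered sib-pair UCC data; enriched-trio
#' transmissions) and KBAC (trio UCC data; enriched-trio pseudo-case-control
#' data).
#'
#' Closed-form tests use `n_reps_closed` replicates; permutation tests
#' (C-alpha-P, KBAC) use `n_reps_perm` replicates of `n_perm` label
#' permutations each. All rejection proportions are at alpha = 0.05 and
#' reported in percent.
#'
#' @param seed Master seed; every cell derives its replicate substreams from
#'   it deterministically.
#' @param n_reps_closed Replicates for closed-form tests.
#' @param n_reps_perm Replicates for permutation tests.
#' @param n_perm Label permutations per replicate.
#' @param progress Print progress messages?
#' @return Tibble with columns `quantity`, `structure`, `format`, `test`,
#'   `cluster`, `n_reps`, `value_pct`, `mc_se_pct`.
#' @export
reproduce_headline_results <- function(seed = 1, n_reps_closed = 1000,
                                       n_reps_perm = 300, n_perm = 1000,
                                       progress = FALSE) {
  roster <- function(test, format, cluster = FALSE) {
    tibble::tibble(test = test, format = format, cluster = cluster)
  }
  cells <- list(
    list(quantity = "type1", structure = "trio", or = 1, n_reps = n_reps_closed,
         tests = roster(c("tdt", "ssu"), "family")),
    list(quantity = "type1", structure = "asp", or = 1, n_reps = n_reps_closed,
         tests = roster(c("assoc", "skat"), "ucc")),
    list(quantity = "type1", structure = "asp", or = 1, n_reps = n_reps_perm,
         tests = roster("calpha_perm", "ucc")),
    list(quantity = "power", structure = "trio", or = 2.00, n_reps = n_reps_closed,
         tests = roster("tdt", "family")),
    list(quantity = "power", structure = "asp", or = 1.72, n_reps = n_reps_closed,
         tests = roster("ssu", "ucc", cluster = TRUE)),
    list(quantity = "power", structure = "enriched_trio", or = 1.54,
         n_reps = n_reps_closed, tests = roster("ssu", "family")),
    list(quantity = "power", structure = "trio", or = 2.00, n_reps = n_reps_perm,
         tests = roster("kbac", "ucc")),
    list(quantity = "power", structure = "enriched_trio", or = 1.54,
         n_reps = n_reps_perm, tests = roster("kbac", "pcc"))
  )
  out <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (progress) {
      message(sprintf("[%d/%d] %s %s: %s on %s (%d replicates)",
                      i, length(cells), cell$quantity, cell$structure,
                      paste(cell$tests$test, collapse = "/"),
                      paste(unique(cell$tests$format), collapse = "/"),
                      cell$n_reps))
    }
    cfg <- scenario_config(cell$structure, or_values = cell$or,
                           n_reps = cell$n_reps, n_perm = n_perm,
                           seed = derive_seed(seed, i * 1000L),
                           tests = cell$tests)
    pt <- estimate_power(cfg)
    out[[i]] <- dplyr::mutate(pt, quantity = cell$quantity,
                              structure = cell$structure)
  }
  dplyr::bind_rows(out) |>
    dplyr::transmute(.data$quantity, .data$structure, .data$format,
                     .data$test, .data$cluster, .data$n_reps,
                     value_pct = 100 * .data$proportion,
                     mc_se_pct = 100 * .data$mc_se)
}
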