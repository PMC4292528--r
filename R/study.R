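children_per_family <- function(structure) {
  if (structure == "asp") 2L else 1L
}

# deterministic substream seed for replicate rep of a run seeded with seed;
# kept below 2^31 so set.seed() accepts it on every platform
derive_seed <- function(seed, rep) {
  as.integer((as.double(seed %% 2147483647L) * 69621 + rep * 10007) %% 2147483646 + 1)
}

#' Default test roster for a family structure
#'
#' Six family-format tests, nine tests each on pseudo-case-control (PCC) and
#' unrelated-case-control (UCC) data. When cases come from affected
#' sib-pairs, sibling cases in the UCC data are not independent, so the five
#' score tests are run on clustered data there (single-SNP association,
#' C-alpha, SKAT and KBAC are left unclustered, which inflates their type-I
#' error; the clustered roster reproduces the usable tests).
#'
#' @param structure `"trio"`, `"asp"` or `"enriched_trio"`.
#' @return Tibble with columns `test`, `format`, `cluster`.
#' @export
default_roster <- function(structure = c("trio", "asp", "enriched_trio")) {
  structure <- match.arg(structure)
  fam <- tibble::tibble(test = c("tdt", "uminp", "score", "ssu", "ssuw", "sum"),
                        format = "family", cluster = FALSE)
  cc_tests <- c("assoc", "uminp", "score", "ssu", "ssuw", "sum",
                "calpha_perm", "skat", "kbac")
  score_tests <- c("uminp", "score", "ssu", "ssuw", "sum")
  pcc <- tibble::tibble(test = cc_tests, format = "pcc", cluster = FALSE)
  ucc <- tibble::tibble(test = cc_tests, format = "ucc",
                        cluster = structure == "asp" & cc_tests %in% score_tests)
  dplyr::bind_rows(fam, pcc, ucc)
}

#' Scenario configuration for a simulation study
#'
#' Collects the parameters of one simulated scenario: family structure,
#' numbers of cases and controls, the variant panel, the disease model, the
#' replication and permutation budgets, and the roster of tests to run.
#'
#' @param structure `"trio"`, `"asp"` or `"enriched_trio"`.
#' @param n_cases Number of affected offspring (must be divisible by the
#'   children per family: 2 for `asp`).
#' @param m Number of variants.
#' @param maf Minor-allele frequency, scalar or length `m`.
#' @param causal_idx Indices of causal variants.
#' @param or_values Odds ratio per causal variant (scalar recycled).
#' @param c Background affection probability.
#' @param n_controls Number of unrelated controls for UCC data (defaults to
#'   `n_cases`).
#' @param alpha Significance level.
#' @param n_reps Number of replicates.
#' @param n_perm Permutation budget for permutation-based tests.
#' @param seed Master seed; replicate `r` uses a substream derived
#'   deterministically from `(seed, r)`.
#' @param strata Optional list of strata (each `list(weight, panel, model)`)
#'   for stratified-population scenarios.
#' @param tests Roster tibble (`test`, `format`, `cluster`); defaults to
#'   [default_roster()].
#' @param screened_controls Screen controls for affection?
#' @param sim_method `"tilted"` or `"rejection"`.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(structure = c("trio", "asp", "enriched_trio"),
                            n_cases = 1200, m = 10, maf = 0.005,
                            causal_idx = 1:4, or_values = 2.0, c = 0.01,
                            n_controls = n_cases, alpha = 0.05,
                            n_reps = 1000, n_perm = 1000, seed = 1,
                            strata = NULL, tests = NULL,
                            screened_controls = TRUE,
                            sim_method = c("tilted", "rejection")) {
  structure <- match.arg(structure)
  sim_method <- match.arg(sim_method)
  nch <- children_per_family(structure)
  if (n_cases %% nch != 0) {
    stop("n_cases must be divisible by the number of children per family")
  }
  if (length(maf) == 1L) maf <- rep(maf, m)
  stopifnot(length(maf) == m, all(causal_idx %in% seq_len(m)),
            alpha > 0, alpha < 1)
  if (length(or_values) == 1L) or_values <- rep(or_values, length(causal_idx))
  stopifnot(length(or_values) == length(causal_idx))
  if (is.null(tests)) tests <- default_roster(structure)
  structure(list(structure = structure, n_cases = n_cases, m = m, maf = maf,
                 causal_idx = causal_idx, or_values = or_values, c = c,
                 n_controls = n_controls, alpha = alpha, n_reps = n_reps,
                 n_perm = n_perm, seed = seed, strata = strata, tests = tests,
                 screened_controls = screened_controls,
                 sim_method = sim_method),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config: %s, %d cases, %d variants (MAF %s), %d causal (OR %s), c = %g\n",
              x$structure, x$n_cases, x$m,
              paste(unique(signif(x$maf, 3)), collapse = "/"),
              length(x$causal_idx),
              paste(unique(signif(x$or_values, 3)), collapse = "/"), x$c))
  cat(sprintf("  alpha = %g, %d replicates, %d permutations, seed %d\n",
              x$alpha, x$n_reps, x$n_perm, x$seed))
  invisible(x)
}

config_panel <- function(cfg) variant_panel(cfg$maf)

config_model <- function(cfg) {
  beta <- rep(0, cfg$m)
  beta[cfg$causal_idx] <- log(cfg$or_values)
  disease_model(cfg$c, beta = beta)
}

#' Run one replicate of a scenario
#'
#' Simulates one ascertained family sample (and unrelated controls when the
#' roster includes UCC tests), builds the family, PCC and UCC data sets from
#' the *same* simulated families, applies clustering where the roster
#' demands, and runs every selected test. Fully determined by
#' `(cfg$seed, rep_index)`.
#'
#' @param cfg A [scenario_config()].
#' @param rep_index Replicate number (1-based).
#' @return Tibble with columns `rep`, `test`, `format`, `cluster`,
#'   `statistic`, `p_value`.
#' @export
run_replicate <- function(cfg, rep_index = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(derive_seed(cfg$seed, rep_index))
  roster <- cfg$tests
  need_ucc <- any(roster$format == "ucc")
  nch <- children_per_family(cfg$structure)
  n_fam <- cfg$n_cases %/% nch
  tryCatch({
    if (is.null(cfg$strata)) {
      panel <- config_panel(cfg)
      model <- config_model(cfg)
      fam <- simulate_families(cfg$structure, n_fam, panel, model,
                               method = cfg$sim_method)
      controls <- if (need_ucc) {
        simulate_controls(panel, model, cfg$n_controls,
                          screened = cfg$screened_controls)
      }
    } else {
      sim <- simulate_stratified(cfg$strata, cfg$structure, n_fam,
                                 n_controls = if (need_ucc) cfg$n_controls else 0,
                                 method = cfg$sim_method)
      fam <- sim$families
      controls <- sim$controls
    }
    data <- list()
    out <- vector("list", nrow(roster))
    for (i in seq_len(nrow(roster))) {
      fmt <- roster$format[i]
      if (fmt == "family") {
        if (is.null(data$tc)) data$tc <- extract_transmissions(fam)
        res <- family_test_battery(data$tc, tests = roster$test[i])
      } else {
        key <- paste(fmt, roster$cluster[i], sep = "_")
        if (is.null(data[[key]])) {
          cc <- if (fmt == "pcc") make_pcc(fam) else make_ucc(fam, controls)
          if (roster$cluster[i]) cc <- cluster_related(cc)
          data[[key]] <- cc
        }
        res <- cc_test_battery(data[[key]], tests = roster$test[i],
                               n_perm = cfg$n_perm, cluster = FALSE)
      }
      out[[i]] <- dplyr::mutate(res, format = fmt, cluster = roster$cluster[i])
    }
    dplyr::bind_rows(out) |>
      dplyr::transmute(rep = rep_index, test = .data$method, .data$format,
                       .data$cluster, .data$statistic, .data$p_value)
  }, error = function(e) {
    stop(sprintf("replicate %d: %s", rep_index, conditionMessage(e)))
  })
}

#' Estimate power (or type-I error) of every test in a scenario
#'
#' Runs `cfg$n_reps` independent replicates and reports, per test and data
#' format, the proportion of replicates with `p < alpha` together with its
#' binomial Monte-Carlo standard error. A p-value exactly equal to `alpha`
#' counts as a non-rejection.
#'
#' @param cfg A [scenario_config()].
#' @param progress Print a progress line every 100 replicates?
#' @return A tibble of class `power_table` with columns `test`, `format`,
#'   `cluster`, `n_reps`, `rejections`, `proportion`, `mc_se`.
#' @export
estimate_power <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  reps <- vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    reps[[r]] <- run_replicate(cfg, r)
    if (progress && r %% 100 == 0) {
      message(sprintf("  replicate %d / %d", r, cfg$n_reps))
    }
  }
  res <- dplyr::bind_rows(reps) |>
    dplyr::group_by(.data$test, .data$format, .data$cluster) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      rejections = sum(.data$p_value < cfg$alpha),
      proportion = .data$rejections / .data$n_reps,
      mc_se = sqrt(.data$proportion * (1 - .data$proportion) / .data$n_reps),
      .groups = "drop")
  attr(res, "alpha") <- cfg$alpha
  class(res) <- c("power_table", class(res))
  res
}

#' Calibrate a shared odds ratio to a target power
#'
#' Assigns a common odds ratio to every causal variant and bisects until the
#' most powerful test in the roster reaches the target power within `tol`.
#' Power is estimated at a reduced replicate budget; a coarse monotonicity
#' scan establishes the bracket first.
#'
#' @param cfg A [scenario_config()] with at least one causal variant.
#' @param target_power Target power for the most powerful test.
#' @param tol Acceptable absolute deviation from the target.
#' @param n_reps Replicates per power evaluation.
#' @param or_max Upper end of the search bracket.
#' @param max_iter Bisection iteration cap.
#' @return List with `or`, `power`, and the evaluation `trace` tibble.
#' @export
calibrate_or <- function(cfg, target_power = 0.90, tol = 0.02, n_reps = 200,
                         or_max = 8, max_iter = 20) {
  stopifnot(inherits(cfg, "scenario_config"), length(cfg$causal_idx) >= 1)
  eval_power <- function(or) {
    cfg2 <- cfg
    cfg2$or_values <- rep(or, length(cfg$causal_idx))
    cfg2$n_reps <- n_reps
    pt <- estimate_power(cfg2)
    max(pt$proportion)
  }
  trace <- tibble::tibble(or = numeric(), power = numeric())
  note <- function(or, p) trace <<- dplyr::add_row(trace, or = or, power = p)
  p_lo <- eval_power(1); note(1, p_lo)
  if (p_lo >= target_power) {
    return(list(or = 1, power = p_lo, trace = trace))
  }
  p_hi <- eval_power(or_max); note(or_max, p_hi)
  if (p_hi < target_power) stop("target power not reachable below or_max")
  lo <- 1; hi <- or_max
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # bisect on the log-OR scale
    p_mid <- eval_power(mid); note(mid, p_mid)
    if (abs(p_mid - target_power) <= tol) {
      return(list(or = mid, power = p_mid, trace = trace))
    }
    if (p_mid < target_power) lo <- mid else hi <- mid
  }
  list(or = sqrt(lo * hi), power = eval_power(sqrt(lo * hi)), trace = trace)
}

#' Pre-registered scenario batteries
#'
#' Emits families of [scenario_config()]s matching the study's systematic
#' parameter sweeps, all sharing the baseline parameters (10 variants, MAF
#' 0.5%, background risk 1%, 1200 cases, alpha 0.05, 1000 replicates) except
#' for the swept parameter. Baseline per-structure odds ratios are 2.00
#' (trios), 1.72 (affected sib-pairs) and 1.54 (enriched trios), the values
#' giving the most powerful test roughly 90% power.
#'
#' @param kind One of `"null"`, `"baseline"`, `"causal_count"`,
#'   `"total_variants"`, `"or_sweep_1"`, `"or_sweep_4"`, `"protective"`,
#'   `"fluctuation"`, `"stratified"`, `"subsample"`.
#' @param structure Family structure for the sweep batteries.
#' @param strata Stratum list, required for `kind = "stratified"`.
#' @param ... Overrides passed to every [scenario_config()].
#' @return Named list of `scenario_config` objects.
#' @export
scenario_battery <- function(kind = c("null", "baseline", "causal_count",
                                      "total_variants", "or_sweep_1",
                                      "or_sweep_4", "protective",
                                      "fluctuation", "stratified",
                                      "subsample"),
                             structure = "trio", strata = NULL, ...) {
  kind <- match.arg(kind)
  base_or <- c(trio = 2.00, asp = 1.72, enriched_trio = 1.54)
  structures <- c("trio", "asp", "enriched_trio")
  cfg <- function(...) scenario_config(...)
  out <- switch(kind,
    null = stats::setNames(
      lapply(structures, function(s) cfg(structure = s, or_values = 1, ...)),
      paste0("null_", structures)),
    baseline = stats::setNames(
      lapply(structures, function(s) {
        cfg(structure = s, or_values = base_or[[s]], ...)
      }),
      paste0("baseline_", structures)),
    causal_count = stats::setNames(
      lapply(1:10, function(k) {
        cfg(structure = structure, causal_idx = seq_len(k),
            or_values = base_or[[structure]], ...)
      }),
      paste0("causal_", 1:10)),
    total_variants = stats::setNames(
      lapply(c(10, 20, 30, 40, 50), function(m) {
        cfg(structure = structure, m = m, causal_idx = 1:4,
            or_values = base_or[[structure]], ...)
      }),
      paste0("m_", c(10, 20, 30, 40, 50))),
    or_sweep_1 = stats::setNames(
      lapply(seq(1, 3, by = 0.25), function(or) {
        cfg(structure = structure, causal_idx = 1, or_values = or, ...)
      }),
      paste0("or1_", seq(1, 3, by = 0.25))),
    or_sweep_4 = stats::setNames(
      lapply(seq(1, 3, by = 0.25), function(or) {
        cfg(structure = structure, causal_idx = 1:4, or_values = or, ...)
      }),
      paste0("or4_", seq(1, 3, by = 0.25))),
    protective = stats::setNames(
      lapply(0:4, function(k) {
        or <- rep(base_or[[structure]], 4)
        if (k > 0) or[seq_len(k)] <- 1 / or[seq_len(k)]
        cfg(structure = structure, causal_idx = 1:4, or_values = or, ...)
      }),
      paste0("protective_", 0:4)),
    fluctuation = {
      or <- base_or[[structure]] * c(0.8, 1.2, 0.9, 1.1)
      list(fluctuation = cfg(structure = structure, causal_idx = 1:4,
                             or_values = or, ...))
    },
    stratified = {
      if (is.null(strata)) stop("stratified scenarios need a stratum specification")
      list(stratified = cfg(structure = structure, strata = strata, ...))
    },
    subsample = stats::setNames(
      lapply(seq(100, 1100, by = 100), function(n) {
        cfg(structure = structure, n_cases = n, n_controls = n,
            or_values = base_or[[structure]], ...)
      }),
      paste0("n_", seq(100, 1100, by = 100)))
  )
  out
}
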