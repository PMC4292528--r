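# genotype count -> PED allele pair ("1" = major, "2" = minor)
geno_to_alleles <- function(g) {
  c("1 1", "1 2", "2 2")[g + 1L]
}

alleles_to_geno <- function(a1, a2) {
  (a1 == "2") + (a2 == "2")
}

#' Write a family sample as PLINK-style PED plus a variant table
#'
#' Emits `<prefix>.ped` (family ID, individual ID, paternal/maternal IDs,
#' sex, affection status, then two allele columns per variant; allele 1 is
#' the major, allele 2 the minor) and `<prefix>.var.tsv` (variant label and
#' MAF). Parents have unknown affection (0); retained offspring are affected
#' (2).
#'
#' @param fam A `family_sample`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_ped <- function(fam, prefix) {
  stopifnot(inherits(fam, "family_sample"))
  m <- ncol(fam$father)
  rows <- character(0)
  fam_row <- function(fid, iid, pat, mat, sex, pheno, g) {
    paste(fid, iid, pat, mat, sex, pheno,
          paste(geno_to_alleles(g), collapse = " "))
  }
  for (i in seq_len(fam$n)) {
    fid <- paste0("F", i)
    rows <- c(rows,
              fam_row(fid, 1, 0, 0, 1, 0, fam$father[i, ]),
              fam_row(fid, 2, 0, 0, 2, 0, fam$mother[i, ]),
              vapply(seq_along(fam$children), function(k) {
                fam_row(fid, 2 + k, 1, 2, 0, 2, fam$children[[k]][i, ])
              }, character(1)))
  }
  ped_path <- paste0(prefix, ".ped")
  var_path <- paste0(prefix, ".var.tsv")
  writeLines(rows, ped_path)
  utils::write.table(
    data.frame(label = fam$panel$variant, maf = fam$panel$maf),
    var_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ped = ped_path, variants = var_path))
}

#' Read a PED file plus variant table into a family sample
#'
#' Expects nuclear families written in the layout of [write_ped()]: two
#' founders per family followed by one or two affected offspring. Families
#' with two offspring are read as affected sib-pairs, families with one as
#' trios (pass `structure = "enriched_trio"` to tag single-offspring
#' families as enriched trios).
#'
#' @param prefix Path prefix, or explicit `ped` / `variants` paths.
#' @param ped,variants Optional explicit file paths.
#' @param structure Structure tag for single-offspring families.
#' @return A `family_sample`.
#' @export
read_ped <- function(prefix = NULL, ped = NULL, variants = NULL,
                     structure = "trio") {
  if (is.null(ped)) ped <- paste0(prefix, ".ped")
  if (is.null(variants)) variants <- paste0(prefix, ".var.tsv")
  vt <- utils::read.table(variants, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  panel <- variant_panel(vt$maf, labels = vt$label)
  m <- nrow(panel)
  tok <- strsplit(readLines(ped), "[ \t]+")
  n_col <- 6 + 2 * m
  if (any(lengths(tok) != n_col)) {
    stop("PED rows do not match the variant table (expected ", n_col, " fields)")
  }
  tab <- do.call(rbind, tok)
  geno <- alleles_to_geno(tab[, 6 + 2 * (1:m) - 1, drop = FALSE],
                          tab[, 6 + 2 * (1:m), drop = FALSE])
  geno <- matrix(as.integer(geno), nrow = nrow(tab), ncol = m)
  fid <- tab[, 1]
  pat <- tab[, 3]
  aff <- tab[, 6]
  fids <- unique(fid)
  founder <- pat == "0"
  father <- mother <- matrix(0L, length(fids), m)
  kids <- list()
  n_off <- NULL
  for (i in seq_along(fids)) {
    rows <- which(fid == fids[i])
    f_rows <- rows[founder[rows]]
    o_rows <- rows[!founder[rows]]
    if (length(f_rows) != 2L || length(o_rows) < 1L || length(o_rows) > 2L) {
      stop("family ", fids[i], " is not a nuclear family with 1-2 offspring")
    }
    if (any(aff[o_rows] != "2")) {
      stop("family ", fids[i], " has unaffected offspring")
    }
    if (is.null(n_off)) {
      n_off <- length(o_rows)
      kids <- replicate(n_off, matrix(0L, length(fids), m), simplify = FALSE)
    } else if (length(o_rows) != n_off) {
      stop("mixed numbers of offspring per family are not supported")
    }
    father[i, ] <- geno[f_rows[1], ]
    mother[i, ] <- geno[f_rows[2], ]
    for (k in seq_len(n_off)) kids[[k]][i, ] <- geno[o_rows[k], ]
  }
  struct <- if (n_off == 2L) "asp" else match.arg(structure, c("trio", "enriched_trio"))
  new_family_sample(struct, father, mother, kids, panel)
}

#' Write case-control data as TSV
#'
#' Columns: `subject`, `phenotype` (1 = case), `cluster`, then one
#' minor-allele-count column per variant (`g1..gm`).
#'
#' @param cc A `cc_data` object.
#' @param path Output file.
#' @export
write_cc_tsv <- function(cc, path) {
  stopifnot(inherits(cc, "cc_data"))
  utils::write.table(as_tibble(cc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read case-control data from TSV
#'
#' @param path File written by [write_cc_tsv()].
#' @return A `cc_data` object.
#' @export
read_cc_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  gcols <- grep("^g[0-9]+$", names(tab))
  if (length(gcols) == 0L) stop("no genotype columns (g1..gm) found")
  cl <- tab$cluster
  new_cc_data(as.matrix(tab[, gcols, drop = FALSE]), tab$phenotype, cl)
}
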