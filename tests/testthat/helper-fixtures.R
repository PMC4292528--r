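# small in-code fixtures shared across test files

baseline_panel <- function(m = 10, maf = 0.005) variant_panel(maf, m = m)

baseline_model <- function(or = 2, n_causal = 4, m = 10, c = 0.01) {
  disease_model(c, or = c(rep(or, n_causal), rep(1, m - n_causal)))
}

null_model <- function(m = 10, c = 0.01) disease_model(c, or = rep(1, m))

# hand-built family sample: genotype rows supplied directly
manual_family <- function(father, mother, children, structure = "trio",
                          maf = NULL) {
  father <- as.matrix(father); mother <- as.matrix(mother)
  if (!is.list(children)) children <- list(as.matrix(children))
  children <- lapply(children, as.matrix)
  m <- ncol(father)
  if (is.null(maf)) maf <- rep(0.1, m)
  famrare:::new_family_sample(structure, father, mother, children,
                              variant_panel(maf))
}

manual_cc <- function(G, y, cluster = seq_along(y)) {
  famrare:::new_cc_data(as.matrix(G), y, cluster)
}
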