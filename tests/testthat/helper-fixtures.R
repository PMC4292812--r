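# Small fixtures shared across test files; everything is generated in code.

tiny_annotation <- function(n = 2000, seed = 42, include_sex = TRUE) {
  generate_annotation(n, seed = seed, include_sex = include_sex)
}

tiny_pool <- function(n_probes = 2000, n_samples = 4, seed = 42,
                      annotation = tiny_annotation(n_probes, seed),
                      ...) {
  generate_pool(methylome_model(n_probes = n_probes, seed = seed, ...),
                n_samples, annotation)
}

# a patient/PDX pair with planted changes, plus the combined beta matrix
tiny_pair <- function(n_probes = 2000, frac_changing = 0.027, seed = 7) {
  ann <- tiny_annotation(n_probes, seed)
  pool <- tiny_pool(n_probes, 2, seed, ann)
  plan <- pair_plan(frac_changing = frac_changing, seed = seed + 1)
  pdx <- generate_pdx_pair(pool[, 1], plan)
  beta <- cbind(pool, X = pdx$beta)
  colnames(beta) <- c("P", "S2", "X")
  list(beta = beta, planted = pdx$planted, annotation = ann, plan = plan)
}
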