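# Shared fixture builders. Everything is generated in code; no files.

# feature matrix from a named list of covered-sample ids
fm_from_cov <- function(cov, sample_ids) {
  a <- matrix(0L, length(cov), length(sample_ids),
              dimnames = list(names(cov), sample_ids))
  for (i in seq_along(cov)) a[i, cov[[i]]] <- 1L
  feature_matrix(a)
}

# the three-sample worked instance used across optimizer tests:
# d' = (-0.6, -0.4, 0.3), increased; f1 = {s1}, f2 = {s1, s2}, f3 = {s3}
worked_instance <- function() {
  fm <- fm_from_cov(list("F1(A)" = "s1", "F2(A)" = c("s1", "s2"),
                         "F3(A)" = "s3"),
                    c("s1", "s2", "s3"))
  weighted_instance(setNames(c(-1.2, -0.8, 0.6), c("s1", "s2", "s3")),
                    "increased", fm)
}

# random instance generator for oracle-equivalence tests; mixes in
# same-gene I/O pairs so the two-hit exception path is exercised
random_instance <- function(n, m, direction, p_one = 0.25) {
  d <- rnorm(n)
  if (direction == "increased" && !any(d < 0)) d[1] <- -abs(d[1]) - 0.1
  if (direction == "decreased" && !any(d > 0)) d[1] <- abs(d[1]) + 0.1
  genes <- sprintf("G%02d", sample.int(max(2L, ceiling(m / 2)), m,
                                       replace = TRUE))
  cls <- sample(c("A", "I", "O"), m, replace = TRUE)
  labs <- paste0(genes, "(", cls, ")")
  dup <- duplicated(labs)
  labs[dup] <- sprintf("H%02d(A)", seq_len(sum(dup)))  # keep labels unique
  a <- matrix(rbinom(m * n, 1L, p_one), m, n,
              dimnames = list(labs, sprintf("s%03d", seq_len(n))))
  fm <- feature_matrix(a)
  weighted_instance(setNames(d, colnames(a)), direction, fm)
}

# tiny annotated mutation-record table exercising all grouping rules
rule_records <- function() {
  mutation_records(
    gene = c("KRAS", "TP53", "KEAP1", "NFE2L2", "BRAF", "EGFR"),
    sample = c("c1", "c1", "c2", "c3", "c2", "c3"),
    variant_class = "Missense_Mutation",
    protein_change = c("p.G12D", "p.R175H", "p.X1", "p.X2", "p.V600E",
                       "p.T790M"),
    in_oncokb = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    oncogenic = c("Oncogenic", "Likely Oncogenic", "Likely Neutral",
                  "Oncogenic", "Oncogenic", "Oncogenic"),
    mutation_effect = c("Gain-of-function", "Likely Loss-of-function",
                        "Unknown", "Switch-of-function", "Gain-of-function",
                        "Gain-of-function"))
}
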