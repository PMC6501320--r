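# Builders for small in-code fixtures.

make_variants <- function(n = 1, gene = "BRCA2", transcript = "NM_000059",
                          exon = 11L, cdna_change = "c.5754dupT",
                          protein_change = "p.H1918fs",
                          functional_class = "frameshift_indel",
                          splice_distance = NA_integer_,
                          read_depth = 300, variant_quality = 500,
                          genotype_quality = 99, allelic_ratio = 0.5,
                          is_last_exon = FALSE,
                          sample_id = sprintf("s%03d", seq_len(n))) {
  r <- function(x) rep_len(x, n)
  data.frame(sample_id = r(sample_id), gene = r(gene),
             transcript = r(transcript),
             exon = r(exon), cdna_change = r(cdna_change),
             protein_change = r(protein_change),
             functional_class = r(functional_class),
             splice_distance = r(splice_distance), read_depth = r(read_depth),
             variant_quality = r(variant_quality),
             genotype_quality = r(genotype_quality),
             allelic_ratio = r(allelic_ratio), is_last_exon = r(is_last_exon),
             stringsAsFactors = FALSE)
}

make_subjects <- function(n_cases = 4, n_controls = 4,
                          age = c(rep(35, n_cases), rep(55, n_controls))) {
  n <- n_cases + n_controls
  validate_subjects(data.frame(
    subject_id = c(sprintf("case_%03d", seq_len(n_cases)),
                   sprintf("control_%03d", seq_len(n_controls))),
    status = rep(c("case", "control"), c(n_cases, n_controls)),
    age = age,
    er_status = "unknown", grade = "unknown",
    fh_first_degree = "no", fh_any = "no", stringsAsFactors = FALSE))
}

make_clinvar <- function(gene = character(0), transcript = character(0),
                         cdna_change = character(0), label = character(0)) {
  validate_clinvar(data.frame(gene = gene, transcript = transcript,
                              cdna_change = cdna_change, label = label,
                              stringsAsFactors = FALSE))
}

empty_clinvar <- function() make_clinvar()

# Independent brute-force oracle for the one-sided hypergeometric tail:
# sums point probabilities directly instead of calling the tail function.
brute_fisher_tail <- function(a, b, c, d) {
  K <- a + c; n1 <- a + b; N <- a + b + c + d
  ks <- a:min(K, n1)
  # log-scale to survive the large binomial coefficients
  sum(exp(lchoose(K, ks) + lchoose(N - K, n1 - ks) - lchoose(N, n1)))
}
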