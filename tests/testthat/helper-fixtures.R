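# Small programmatic fixtures shared across the test files.

# A hand-sized summary table; override any column via ...
toy_table <- function(trait = "exp", n_snp = 5, ...) {
  df <- data.frame(
    rsid = sprintf("rs%d", seq_len(n_snp)),
    chrom = rep("1", n_snp),
    pos = 1e6 * seq_len(n_snp),
    effect_allele = rep("A", n_snp),
    other_allele = rep("G", n_snp),
    eaf = seq(0.15, 0.45, length.out = n_snp),
    beta = seq(0.05, 0.11, length.out = n_snp),
    se = rep(0.005, n_snp),
    pval = rep(1e-10, n_snp),
    n = rep(1e5, n_snp),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  summary_table(df, trait_id = trait, quiet = TRUE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# mr_input with exact per-variant values, defaulting to tight exposure ses
toy_input <- function(bx, by, byse = rep(0.01, length(bx)),
                      bxse = rep(1e-4, length(bx))) {
  mr_input(bx = bx, bxse = bxse, by = by, byse = byse)
}
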