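test_that("delimited summary statistics parse, with row-level validation", {
  df <- as.data.frame(toy_table(n_snp = 5))
  path <- write_tsv(df)
  tab <- read_sumstats(path, trait_id = "exp")
  expect_s3_class(tab, "summary_table")
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$beta, df$beta)

  # invalid rows are rejected and accounted for, not silently kept
  df_bad <- df
  df_bad$se[2] <- 0          # zero standard error
  df_bad$eaf[3] <- 1.2       # impossible frequency
  df_bad$other_allele[4] <- "AT"  # indel
  tab2 <- suppressMessages(read_sumstats(write_tsv(df_bad), trait_id = "exp"))
  expect_equal(nrow(tab2), 2L)
  drops <- attr(tab2, "dropped")
  expect_equal(unname(drops["bad_se"]), 1)
  expect_equal(unname(drops["bad_eaf"]), 1)
  expect_equal(unname(drops["bad_alleles"]), 1)

  # all rows invalid -> empty-input error
  df_bad$se <- 0
  expect_error(suppressMessages(
    read_sumstats(write_tsv(df_bad), trait_id = "exp")), "no valid rows")
})

test_that("column maps rename arbitrary source headers and name missing fields", {
  df <- as.data.frame(toy_table(n_snp = 3))
  names(df) <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE", "P", "N")
  path <- write_tsv(df)
  cmap <- c(rsid = "SNP", chrom = "CHR", pos = "BP", effect_allele = "A1",
            other_allele = "A2", eaf = "FRQ", beta = "BETA", se = "SE",
            pval = "P", n = "N")
  tab <- read_sumstats(path, column_map = cmap, trait_id = "exp")
  expect_equal(nrow(tab), 3L)

  expect_error(
    read_sumstats(path, column_map = cmap[names(cmap) != "se"],
                  trait_id = "exp"),
    "se")
  # n may be omitted from the map when a table-level fallback is given
  tab2 <- read_sumstats(path, column_map = cmap[names(cmap) != "n"],
                        trait_id = "exp", n_default = 12345)
  expect_true(all(tab2$n == 12345))
})

test_that("result tables round-trip through TSV", {
  fit <- mr_ivw(toy_input(bx = c(0.1, 0.2), by = c(0.02, 0.04)))
  path <- tempfile(fileext = ".tsv")
  write_results(fit, path)
  back <- utils::read.delim(path)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$method, fit$method)

  # empty result set -> header-only file, no crash
  empty <- fit[0, ]
  write_results(empty, path)
  expect_equal(nrow(utils::read.delim(path)), 0L)

  expect_error(write_results(fit, file.path(tempdir(), "no_such_dir", "x.tsv")),
               "no_such_dir")
})

test_that("harmonization aligns swapped, strand-flipped and palindromic alleles", {
  exp_tab <- toy_table("exp", n_snp = 3)
  # rs1: swapped alleles; rs2: complementary strand; rs3: as-is
  out_df <- as.data.frame(exp_tab)
  out_df$beta <- c(-0.05, 0.02, 0.01)
  out_df$eaf <- c(0.3, 0.25, 0.35)
  out_df$effect_allele <- c("G", "T", "A")
  out_df$other_allele <- c("A", "C", "G")
  out_tab <- summary_table(out_df, "out", quiet = TRUE)

  h <- harmonize(list(exp_tab, out_tab))
  expect_equal(n_snps(h), 3L)
  i <- match(c("rs1", "rs2", "rs3"), h$snps$rsid)
  expect_equal(h$actions$out[i],
               c("sign_flipped", "strand_flipped", "as_is"))
  expect_equal(h$traits$out$beta[i], c(0.05, 0.02, 0.01))
  expect_equal(h$traits$out$eaf[i], c(0.7, 0.25, 0.35))
})

test_that("palindromic variants follow the frequency policy", {
  mk <- function(eaf_exp, eaf_out) {
    base <- as.data.frame(toy_table("x", n_snp = 1))
    base$effect_allele <- "A"; base$other_allele <- "T"
    e <- base; e$eaf <- eaf_exp
    o <- base; o$eaf <- eaf_out; o$beta <- -0.02
    list(summary_table(e, "exp", quiet = TRUE),
         summary_table(o, "out", quiet = TRUE))
  }
  # ambiguous frequency (0.50) -> dropped under infer_by_freq(0.42)
  h <- harmonize(mk(0.50, 0.50))
  expect_equal(n_snps(h), 0L)
  expect_true("palindromic_ambiguous_freq" %in% h$dropped$reason)
  # clear frequencies on the same side -> kept as-is
  h2 <- harmonize(mk(0.2, 0.25))
  expect_equal(h2$actions$out[1], "as_is")
  expect_equal(h2$traits$out$beta[1], -0.02)
  # opposite sides -> sign flip
  h3 <- harmonize(mk(0.2, 0.8))
  expect_equal(h3$actions$out[1], "sign_flipped")
  expect_equal(h3$traits$out$beta[1], 0.02)
  # drop_all removes palindromes regardless of frequency
  expect_equal(n_snps(harmonize(mk(0.2, 0.2),
                                palindrome_policy = "drop_all")), 0L)
})

test_that("unmatched and irreconcilable variants are dropped with reasons", {
  exp_tab <- toy_table("exp", n_snp = 3)
  out_df <- as.data.frame(toy_table("out", n_snp = 3))
  out_df$rsid[3] <- "rs99"                    # absent from exposure
  out_df$effect_allele[2] <- "A"; out_df$other_allele[2] <- "C"  # no match
  out_tab <- summary_table(out_df, "out", quiet = TRUE)
  h <- harmonize(list(exp_tab, out_tab))
  expect_equal(h$snps$rsid, "rs1")
  expect_setequal(h$dropped$reason[h$dropped$rsid == "rs2"],
                  "irreconcilable_alleles")
  expect_true("unmatched_rsid" %in% h$dropped$reason)
})

test_that("harmonization is idempotent and ordered by exposure p-value", {
  set.seed(7)
  n <- 12
  exp_tab <- toy_table("exp", n_snp = n, pval = runif(n, 1e-12, 1e-8),
                       beta = rnorm(n, 0, 0.05))
  out_df <- as.data.frame(toy_table("out", n_snp = n,
                                    beta = rnorm(n, 0, 0.02)))
  flip <- seq_len(n) %% 2 == 0
  out_df$effect_allele[flip] <- "G"; out_df$other_allele[flip] <- "A"
  out_df$beta[flip] <- -out_df$beta[flip]
  out_tab <- summary_table(out_df, "out", quiet = TRUE)

  h1 <- harmonize(list(exp_tab, out_tab))
  # deterministic order: exposure p ascending, rsid tiebreak
  expect_equal(order(h1$traits$exp$pval, h1$snps$rsid), seq_len(n_snps(h1)))
  # idempotence: re-harmonizing the harmonized tables changes nothing
  h2 <- harmonize(as_summary_tables(h1))
  expect_equal(h2$snps, h1$snps)
  expect_equal(h2$traits$out$beta, h1$traits$out$beta)
  expect_true(all(h2$actions$out == "as_is"))
})

test_that("recoding outcome alleles leaves the harmonized set invariant", {
  set.seed(11)
  n <- 10
  exp_tab <- toy_table("exp", n_snp = n, beta = rnorm(n, 0, 0.05))
  out_tab <- toy_table("out", n_snp = n, beta = rnorm(n, 0, 0.02))
  # swap the roles of both alleles and negate beta: same physical claim
  sw <- as.data.frame(out_tab)
  sw$effect_allele <- out_tab$other_allele
  sw$other_allele <- out_tab$effect_allele
  sw$beta <- -sw$beta
  sw$eaf <- 1 - sw$eaf
  out_sw <- summary_table(sw, "out", quiet = TRUE)

  h1 <- harmonize(list(exp_tab, out_tab))
  h2 <- harmonize(list(exp_tab, out_sw))
  expect_equal(h2$traits$out$beta, h1$traits$out$beta)
  expect_equal(h2$traits$out$eaf, h1$traits$out$eaf)
  expect_equal(h2$snps, h1$snps)
})
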