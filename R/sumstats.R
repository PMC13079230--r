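#' @keywords internal
"_PACKAGE"

# Required per-variant fields of a summary table, in canonical order.
SUMSTAT_FIELDS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")

#' Construct a validated GWAS summary-statistic table
#'
#' A `summary_table` holds per-variant association records for one trait:
#' rsID, chromosome, position, effect/other allele, effect-allele frequency,
#' per-allele effect (`beta`, in SD units of the trait), its standard error,
#' association p-value and per-variant sample size.  Rows violating the type
#' invariants (non-ACGT or identical alleles, `se <= 0`, `eaf` outside (0,1),
#' `pval` outside (0,1], duplicated rsIDs, indels/multi-allelic records) are
#' dropped with a per-reason count; only biallelic SNVs survive.
#'
#' @param df data.frame containing at least the columns
#'   `rsid, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n`.
#' @param trait_id label for the trait the table describes.
#' @param n_default table-level sample size used where per-variant `n` is
#'   missing (GWAS exports frequently omit it); required downstream by the
#'   F-statistic and power calculations.
#' @param quiet suppress the row-drop accounting message.
#' @return A `summary_table`: a data.frame with the ten canonical columns,
#'   attributes `trait_id` and `dropped` (named vector of drop counts).
#' @export
summary_table <- function(df, trait_id, n_default = NULL, quiet = FALSE) {
  stopifnot(is.data.frame(df), is.character(trait_id), length(trait_id) == 1L)
  missing_cols <- setdiff(SUMSTAT_FIELDS, names(df))
  if (length(missing_cols) && !(identical(missing_cols, "n") && !is.null(n_default)))
    stop("summary table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"n" %in% names(df)) df$n <- NA_real_

  df <- df[SUMSTAT_FIELDS]
  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  if (!is.null(n_default)) df$n[is.na(df$n)] <- n_default

  drops <- c(
    missing_fields = 0, bad_alleles = 0, bad_eaf = 0, bad_se = 0,
    bad_pval = 0, bad_n = 0, duplicate_rsid = 0
  )
  bases <- c("A", "C", "G", "T")
  ok_core <- !is.na(df$rsid) & nzchar(df$rsid) & !is.na(df$pos) & df$pos >= 1 &
    !is.na(df$beta) & is.finite(df$beta) & !is.na(df$chrom)
  drops["missing_fields"] <- sum(!ok_core)
  ok_allele <- df$effect_allele %in% bases & df$other_allele %in% bases &
    df$effect_allele != df$other_allele
  drops["bad_alleles"] <- sum(ok_core & !ok_allele)
  ok_eaf <- !is.na(df$eaf) & df$eaf > 0 & df$eaf < 1
  drops["bad_eaf"] <- sum(ok_core & ok_allele & !ok_eaf)
  ok_se <- !is.na(df$se) & df$se > 0 & is.finite(df$se)
  drops["bad_se"] <- sum(ok_core & ok_allele & ok_eaf & !ok_se)
  ok_p <- !is.na(df$pval) & df$pval > 0 & df$pval <= 1
  drops["bad_pval"] <- sum(ok_core & ok_allele & ok_eaf & ok_se & !ok_p)
  ok_n <- !is.na(df$n) & df$n > 0
  drops["bad_n"] <- sum(ok_core & ok_allele & ok_eaf & ok_se & ok_p & !ok_n)

  keep <- ok_core & ok_allele & ok_eaf & ok_se & ok_p & ok_n
  df <- df[keep, , drop = FALSE]
  dup <- duplicated(df$rsid)
  drops["duplicate_rsid"] <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL

  if (!quiet && any(drops > 0)) {
    bad <- drops[drops > 0]
    message("summary_table [", trait_id, "]: dropped ", sum(bad), " row(s): ",
            paste(names(bad), bad, sep = "=", collapse = ", "))
  }
  if (nrow(df) == 0L)
    stop("no valid rows remain for trait '", trait_id, "'", call. = FALSE)

  structure(df, class = c("summary_table", "data.frame"),
            trait_id = trait_id, dropped = drops)
}

#' @export
print.summary_table <- function(x, ...) {
  cat("GWAS summary table: trait '", attr(x, "trait_id"), "', ",
      nrow(x), " variants\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Trait label of a summary table
#' @param x a `summary_table`.
#' @return character scalar.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header and maps arbitrary
#' source headers onto the canonical fields via `column_map`.  Validation and
#' row filtering are delegated to [summary_table()].
#'
#' @param path path to the file.  The delimiter is taken from the extension
#'   (`.csv` means comma, anything else tab) unless `delim` is given.
#' @param column_map named character vector or list mapping each canonical
#'   field name (`r paste(SUMSTAT_FIELDS, collapse = ", ")`) to the source
#'   header.  `NULL` means the file already uses canonical names.  `n` may be
#'   omitted from the map when `n_default` is supplied.
#' @param trait_id label for the trait.
#' @param n_default table-level sample size fallback, see [summary_table()].
#' @param delim field delimiter override.
#' @param quiet suppress row-drop accounting.
#' @return A validated `summary_table`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(rsid = c("rs1", "rs2"), chrom = "1", pos = c(1e5, 2e5),
#'                  effect_allele = "A", other_allele = "G",
#'                  eaf = 0.3, beta = c(0.02, -0.01), se = 0.004,
#'                  pval = c(1e-9, 0.01), n = 50000)
#' utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
#' read_sumstats(tf, trait_id = "toy")
read_sumstats <- function(path, column_map = NULL, trait_id,
                          n_default = NULL, delim = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("summary-statistic file not found: ", path,
                               call. = FALSE)
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)

  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    need <- SUMSTAT_FIELDS
    if (!is.null(n_default)) need <- setdiff(need, "n")
    absent <- setdiff(need, names(column_map))
    if (length(absent))
      stop("column_map does not map required field(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src))
      stop("mapped column(s) absent from file header: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    mapped <- raw[unname(column_map)]
    names(mapped) <- names(column_map)
    raw <- mapped
  }
  summary_table(raw, trait_id = trait_id, n_default = n_default, quiet = quiet)
}

#' Read a column map from a YAML file
#'
#' Convenience reader for configs that keep source-header mappings in YAML
#' (GWAS-Catalog-style exports vary widely in their headers).
#'
#' @param path YAML file whose top level maps canonical field names to source
#'   headers.
#' @return named character vector usable as `column_map` in [read_sumstats()].
#' @export
read_column_map <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML column maps",
         call. = FALSE)
  unlist(yaml::read_yaml(path))
}

#' Write a result table to tab-delimited text
#'
#' Columns are written in their existing (deterministic) order; values
#' round-trip through [utils::read.delim()].  An empty result set yields a
#' header-only file.
#'
#' @param x data.frame (or object coercible to one, e.g. a `summary_table`
#'   or the `estimates` table of an [mr_fit()]).
#' @param path output path; its directory must exist.
#' @return `invisible(path)`.
#' @export
write_results <- function(x, path) {
  x <- as.data.frame(x)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write results: directory does not exist: ", dir,
         call. = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
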