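# Pluggable LD sources for clumping: sparse pairwise r2 tables (plink-style)
# or a reference dosage matrix from which r2 is the squared Pearson
# correlation of dosages.

#' LD source from a sparse pairwise r2 table
#'
#' Pairs absent from the table are taken to have r2 = 0, the usual semantics
#' of sparse LD exports that only report pairs above some floor.
#'
#' @param pairs data.frame with columns `rsid_a`, `rsid_b`, `r2`.
#' @return an `ld_source` of subclass `ld_pairs`.
#' @export
ld_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("rsid_a", "rsid_b", "r2") %in% names(pairs)))
  if (nrow(pairs) && (any(pairs$r2 < 0) || any(pairs$r2 > 1)))
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  env <- new.env(parent = emptyenv(), size = max(64L, 2L * nrow(pairs)))
  if (nrow(pairs)) {
    key <- paste(pmin(pairs$rsid_a, pairs$rsid_b),
                 pmax(pairs$rsid_a, pairs$rsid_b), sep = "\r")
    for (i in seq_len(nrow(pairs))) assign(key[i], pairs$r2[i], envir = env)
  }
  structure(list(table = env, n_pairs = nrow(pairs)),
            class = c("ld_pairs", "ld_source"))
}

#' Read a 3-column LD pair table (rsid_a, rsid_b, r2) from TSV
#' @param path tab-delimited file with a header.
#' @return an `ld_source`.
#' @export
read_ld_pairs <- function(path) {
  ld_pairs(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' LD source with no linkage (all off-diagonal r2 = 0)
#'
#' Appropriate for variant panels known to be mutually independent, e.g.
#' pre-pruned instrument lists or simulated panels without LD blocks.
#' @return an `ld_source`.
#' @export
ld_independent <- function() {
  ld_pairs(data.frame(rsid_a = character(0), rsid_b = character(0),
                      r2 = numeric(0)))
}

#' LD source from reference genotype dosages
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns;
#'   column names are rsIDs.  r2 between two variants is the squared Pearson
#'   correlation of their dosage columns.
#' @return an `ld_source` of subclass `ld_genotypes`.
#' @export
ld_genotypes <- function(dosages) {
  stopifnot(is.matrix(dosages), !is.null(colnames(dosages)))
  structure(list(dosages = dosages), class = c("ld_genotypes", "ld_source"))
}

#' Pairwise r2 from an LD source
#'
#' @param ld an `ld_source`.
#' @param rsid_a,rsid_b rsIDs (vectors recycled to common length).
#' @return numeric vector of r2 values; `r2(i, i) = 1` always.
#' @export
ld_r2 <- function(ld, rsid_a, rsid_b) UseMethod("ld_r2")

#' @export
ld_r2.ld_pairs <- function(ld, rsid_a, rsid_b) {
  n <- max(length(rsid_a), length(rsid_b))
  rsid_a <- rep_len(rsid_a, n); rsid_b <- rep_len(rsid_b, n)
  key <- paste(pmin(rsid_a, rsid_b), pmax(rsid_a, rsid_b), sep = "\r")
  out <- vapply(seq_len(n), function(i) {
    if (rsid_a[i] == rsid_b[i]) return(1)
    v <- get0(key[i], envir = ld$table, ifnotfound = 0)
    as.numeric(v)
  }, numeric(1))
  out
}

#' @export
ld_r2.ld_genotypes <- function(ld, rsid_a, rsid_b) {
  n <- max(length(rsid_a), length(rsid_b))
  rsid_a <- rep_len(rsid_a, n); rsid_b <- rep_len(rsid_b, n)
  vapply(seq_len(n), function(i) {
    if (rsid_a[i] == rsid_b[i]) return(1)
    cols <- colnames(ld$dosages)
    if (!(rsid_a[i] %in% cols) || !(rsid_b[i] %in% cols))
      stop("LD source does not cover pair (", rsid_a[i], ", ", rsid_b[i], ")",
           call. = FALSE)
    stats::cor(ld$dosages[, rsid_a[i]], ld$dosages[, rsid_b[i]])^2
  }, numeric(1))
}

#' Export all pairwise r2 values of an LD source as a table
#' @param ld an `ld_genotypes` source.
#' @param min_r2 omit pairs below this value (sparse output).
#' @return data.frame with `rsid_a`, `rsid_b`, `r2`.
#' @export
ld_pair_table <- function(ld, min_r2 = 0) {
  stopifnot(inherits(ld, "ld_genotypes"))
  r <- stats::cor(ld$dosages)^2
  ids <- colnames(ld$dosages)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(rsid_a = ids[idx[, 1]], rsid_b = ids[idx[, 2]],
                    r2 = r[idx], stringsAsFactors = FALSE)
  out[out$r2 >= min_r2, , drop = FALSE]
}
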