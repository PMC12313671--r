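# Reading, validating and writing GWAS summary-statistics tables.
#
# Canonical schema (tab-separated, header row):
#   variant_id chrom pos effect_allele other_allele eaf beta se pval n
# One row per SNP; `beta` is the per-allele effect of `effect_allele`
# (log-odds for binary traits), `eaf` its frequency, `n` the GWAS sample size.

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")
SUMSTATS_NUMERIC <- c("pos", "eaf", "beta", "se", "pval", "n")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table (gzip accepted by `.gz` extension), optionally
#' renaming non-canonical column names, validates every row against the schema
#' invariants (alleles over ACGT and distinct, `eaf` in (0,1), `se > 0`,
#' `pval` in (0,1], `n > 0`, unique `variant_id`) and returns the valid rows
#' in file order.  Malformed rows are dropped, reported with their file line
#' numbers in `attr(x, "rejected")`, and summarised in a warning.
#'
#' @param path Path to a TSV (optionally gzip-compressed) with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(variant_id = "SNP", beta = "BETA")`.
#'   Unmapped canonical names are looked up directly.
#' @param trait Optional trait label stored as an attribute and picked up by
#'   [harmonize()] for table naming.
#' @return A `data.frame` with the canonical columns, attributes `rejected`
#'   (data frame of line/variant_id/reason) and `trait`.
#' @seealso [write_sumstats()], [harmonize()]
#' @export
read_sumstats <- function(path, column_map = NULL, trait = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    mr_error("mr_io_error", sprintf("summary-statistics file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) mr_error("mr_io_error", sprintf("cannot parse %s: %s",
                                                        path, conditionMessage(e))))
  if (nrow(df) == 0L && ncol(df) == 0L) {
    mr_error("mr_io_error", sprintf("empty summary-statistics file: %s", path))
  }
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(!nzchar(names(column_map)))) {
      mr_error("mr_domain_error", "`column_map` must be a named character vector")
    }
    bad <- setdiff(names(column_map), SUMSTATS_COLS)
    if (length(bad)) {
      mr_error("mr_domain_error",
               sprintf("unknown canonical column(s) in `column_map`: %s",
                       paste(bad, collapse = ", ")))
    }
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        mr_error("mr_missing_column",
                 sprintf("mapped column '%s' (for '%s') not present in %s",
                         src, canon, path))
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing)) {
    mr_error("mr_missing_column",
             sprintf("missing mandatory column(s): %s", paste(missing, collapse = ", ")))
  }
  df <- df[SUMSTATS_COLS]

  out <- data.frame(variant_id = df$variant_id,
                    chrom = df$chrom,
                    pos = suppressWarnings(as.numeric(df$pos)),
                    effect_allele = toupper(df$effect_allele),
                    other_allele = toupper(df$other_allele),
                    eaf = suppressWarnings(as.numeric(df$eaf)),
                    beta = suppressWarnings(as.numeric(df$beta)),
                    se = suppressWarnings(as.numeric(df$se)),
                    pval = suppressWarnings(as.numeric(df$pval)),
                    n = suppressWarnings(as.numeric(df$n)),
                    stringsAsFactors = FALSE)

  reason <- rep(NA_character_, nrow(out))
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  num_bad <- Reduce(`|`, lapply(out[SUMSTATS_NUMERIC], function(col) is.na(col)))
  flag(num_bad, "unparsable or missing numeric field")
  flag(!grepl("^[ACGT]+$", out$effect_allele) | !grepl("^[ACGT]+$", out$other_allele),
       "allele not a sequence over A/C/G/T")
  flag(out$effect_allele == out$other_allele, "effect_allele equals other_allele")
  flag(out$pos < 1 | out$pos != floor(out$pos), "pos must be a positive integer")
  flag(!(out$eaf > 0 & out$eaf < 1), "eaf outside (0,1)")
  flag(!(out$se > 0), "se must be > 0")
  flag(!(out$pval > 0 & out$pval <= 1), "pval outside (0,1]")
  flag(out$n <= 0 | out$n != floor(out$n), "n must be a positive integer")
  flag(duplicated(out$variant_id), "duplicate variant_id (first occurrence kept)")

  keep <- is.na(reason)
  rejected <- data.frame(line = which(!keep) + 1L,  # +1 for the header row
                         variant_id = df$variant_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf("read_sumstats: rejected %d malformed row(s) in %s (see attr(x, 'rejected'))",
                    nrow(rejected), path), call. = FALSE)
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$pos <- as.integer(out$pos)
  # n stays double: integral-valued, but biobank-scale sizes can exceed
  # the 32-bit integer range
  out$n <- as.numeric(out$n)
  attr(out, "rejected") <- rejected
  attr(out, "trait") <- trait
  out
}

#' Write a GWAS summary-statistics table
#'
#' Writes the canonical tab-separated schema.  Numeric fields are printed with
#' 17 significant digits so that a write/read round trip reproduces every
#' value exactly.  An empty record set produces a header-only file.
#'
#' @param records Data frame with the canonical columns (see [read_sumstats()]).
#' @param path Output path; a `.gz` extension writes gzip-compressed text.
#' @export
write_sumstats <- function(records, path) {
  missing <- setdiff(SUMSTATS_COLS, names(records))
  if (length(missing)) {
    mr_error("mr_domain_error",
             sprintf("records lack column(s): %s", paste(missing, collapse = ", ")))
  }
  txt <- data.frame(lapply(records[SUMSTATS_COLS], function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }), stringsAsFactors = FALSE)
  names(txt) <- SUMSTATS_COLS
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  ok <- tryCatch({
    utils::write.table(txt, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, finally = close(con))
  if (!isTRUE(ok)) mr_error("mr_io_error", sprintf("cannot write %s: %s",
                                                   path, conditionMessage(ok)))
  invisible(path)
}
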