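# Pairwise LD (r^2) container used by the clumping step.  The simulator emits
# one directly; files come as a sparse pair list or a square matrix with an id
# header row/column.

#' Construct an LD matrix object
#'
#' @param ids Character vector of variant ids (defines row/column order).
#' @param r2 Square symmetric matrix of r-squared values in `[0, 1]` with a
#'   unit diagonal.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(ids, r2) {
  ids <- as.character(ids)
  r2 <- as.matrix(r2)
  if (nrow(r2) != length(ids) || ncol(r2) != length(ids)) {
    mr_error("mr_domain_error", "r2 must be square with one row/column per id")
  }
  if (anyDuplicated(ids)) mr_error("mr_domain_error", "LD matrix ids must be unique")
  if (any(r2 < 0 | r2 > 1)) mr_error("mr_domain_error", "r2 values must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-8) mr_error("mr_domain_error", "r2 must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-8)) mr_error("mr_domain_error", "r2 diagonal must be 1")
  dimnames(r2) <- list(ids, ids)
  structure(list(ids = ids, r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from file
#'
#' Accepts either a sparse pair list (`variant_id_a  variant_id_b  r2`;
#' symmetric completion implied, absent pairs treated as r2 = 0) or a square
#' matrix file whose first column and header row carry the variant ids.
#'
#' @param path TSV path.
#' @param ids For the pair-list format, the full id universe (ids absent from
#'   the file get zero off-diagonal LD); defaults to the ids seen in the file.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path, ids = NULL) {
  if (!file.exists(path)) mr_error("mr_io_error", sprintf("LD file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (all(c("variant_id_a", "variant_id_b", "r2") %in% names(df))) {
    ids <- ids %||% unique(c(df$variant_id_a, df$variant_id_b))
    r2 <- diag(1, length(ids))
    dimnames(r2) <- list(ids, ids)
    ia <- match(df$variant_id_a, ids)
    ib <- match(df$variant_id_b, ids)
    if (anyNA(ia) || anyNA(ib)) {
      mr_error("mr_domain_error", "pair list names variants absent from `ids`")
    }
    r2[cbind(ia, ib)] <- df$r2
    r2[cbind(ib, ia)] <- df$r2
    ld_matrix(ids, r2)
  } else {
    ids <- as.character(df[[1]])
    r2 <- as.matrix(df[, -1, drop = FALSE])
    ld_matrix(ids, r2)
  }
}

#' Write an LD matrix as a sparse pair list
#'
#' Upper-triangle pairs with `r2 > 0` are written; the diagonal and symmetric
#' completion are implied.
#'
#' @param ld An [ld_matrix()].
#' @param path Output TSV path.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  idx <- which(upper.tri(ld$r2) & ld$r2 > 0, arr.ind = TRUE)
  df <- data.frame(variant_id_a = ld$ids[idx[, 1]],
                   variant_id_b = ld$ids[idx[, 2]],
                   r2 = sprintf("%.17g", ld$r2[idx]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$variant_id_a, df$variant_id_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
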