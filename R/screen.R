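# Batch screening of many exposures against one outcome, with
# Benjamini-Hochberg FDR control across the screen and publication-style
# table exports.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]) after validating
#' the inputs: sorted ascending, `q_i = min_{j >= i} p_j m / j`, returned in
#' input order and capped at 1.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) mr_error("mr_domain_error", "empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1)) {
    mr_error("mr_domain_error", "p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

as_sumstats_input <- function(x, label) {
  if (is.character(x) && length(x) == 1L) read_sumstats(x, trait = label) else x
}

#' Screen many exposures against one outcome
#'
#' For each exposure: p-value selection with fallback, MAF and F filters,
#' optional LD clumping, harmonization against the shared outcome, Steiger
#' filtering, then every applicable estimator plus heterogeneity (Cochran's
#' Q), the Egger intercept test and, on request, MR-PRESSO.  BH adjustment is
#' applied across exposures within the primary-method family by default (one
#' p-value per exposure: IVW, or the Wald ratio for a single instrument);
#' `fdr_family = "per_method"` instead adjusts within every method family.
#' Exposures yielding no instruments are reported in `attr(x, "skipped")`,
#' never silently dropped.  With a fixed seed and fixed inputs the screen is
#' bit-reproducible.
#'
#' @param exposures Named list of summary-statistics data frames or file
#'   paths (names become exposure labels).
#' @param outcome Summary-statistics data frame or file path.
#' @param ld Optional [ld_matrix()] used for clumping.
#' @param config A [selection_config()].
#' @param seed Integer seed (drives the bootstrap SEs and MR-PRESSO).
#' @param methods Passed to [mr_estimate_all()] (`"all"` or a subset; rows
#'   for the primary method are always computed).
#' @param presso Run [mr_presso()] per exposure when at least 4 instruments
#'   survive.
#' @param fdr_family `"primary"` (default) or `"per_method"`.
#' @param reverse Swap the roles of exposure and outcome (reverse MR: the
#'   shared table is instrumented against each listed table in turn).
#' @param n_boot_median,n_boot_mode Bootstrap sizes for the median/mode SEs.
#' @return A data frame of class `screen_result` with one row per exposure
#'   and method; `attr(x, "skipped")` lists exposures with no usable
#'   instruments and why.
#' @export
run_screen <- function(exposures, outcome, ld = NULL,
                       config = selection_config(), seed = 1L,
                       methods = "all", presso = FALSE,
                       fdr_family = c("primary", "per_method"),
                       reverse = FALSE,
                       n_boot_median = 5000L, n_boot_mode = 1000L) {
  fdr_family <- match.arg(fdr_family)
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    mr_error("mr_domain_error", "`exposures` must be a fully named list")
  }
  outcome_tab <- as_sumstats_input(outcome, "outcome")
  outcome_name <- attr(outcome_tab, "trait") %||% "outcome"

  rows <- list()
  skipped <- data.frame(exposure = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  skip <- function(label, reason) {
    skipped[nrow(skipped) + 1L, ] <<- list(label, reason)
  }

  for (i in seq_along(exposures)) {
    label <- names(exposures)[i]
    exp_tab <- as_sumstats_input(exposures[[i]], label)
    iv_side <- if (reverse) outcome_tab else exp_tab
    target_side <- if (reverse) exp_tab else outcome_tab

    sel <- select_instruments(iv_side, config, ld)
    if (nrow(sel$records) == 0L) {
      skip(label, "no instruments pass p-value/MAF/F selection")
      next
    }
    h <- tryCatch(
      harmonize(sel$records, target_side,
                exposure_name = if (reverse) outcome_name else label,
                outcome_name = if (reverse) label else outcome_name),
      mr_no_overlap = function(e) NULL)
    if (is.null(h) || nrow(h$instruments) == 0L) {
      skip(label, "no instruments survive harmonization")
      next
    }
    st <- steiger_filter(h$instruments, config)
    if (nrow(st$table) == 0L) {
      skip(label, "no instruments survive Steiger filtering")
      next
    }
    tab <- st$table
    k <- nrow(tab)
    applicable <- if (k == 1L) "wald_ratio" else if (k == 2L) {
      c("ivw", "max_likelihood")
    } else {
      c("ivw", "max_likelihood", "egger", "weighted_median",
        "simple_mode", "weighted_mode")
    }
    wanted <- if (identical(methods, "all")) "all" else {
      # a method subset narrows, but never empties, each exposure's rows
      hit <- intersect(methods, applicable)
      if (length(hit)) hit else applicable[1]
    }
    est <- mr_estimate_all(tab, seed = sub_seed(seed, i), methods = wanted,
                           n_boot_median = n_boot_median,
                           n_boot_mode = n_boot_mode)
    if (!any(est$primary)) {
      # the primary p-value anchors the FDR family, so always compute it
      prim <- as.data.frame(primary_mr(tab))
      prim$primary <- TRUE
      est <- rbind(est, prim)
    }
    het_p <- if (k >= 2L && all(tab$beta_exp != 0)) cochran_q(tab)$pval else NA_real_
    egger_p <- if (k >= 3L) mr_egger(tab)$intercept_p else NA_real_
    presso_p <- if (presso && k >= 4L) {
      mr_presso(tab, seed = sub_seed(seed, i + 500000L))$global_p
    } else NA_real_

    est$exposure <- if (reverse) outcome_name else label
    est$outcome <- if (reverse) label else outcome_name
    est$threshold_used <- sel$threshold_used
    est$heterogeneity_p <- het_p
    est$egger_intercept_p <- egger_p
    est$presso_global_p <- presso_p
    est$steiger_removed <- st$n_removed
    rows[[length(rows) + 1L]] <- est
  }

  if (!length(rows)) {
    mr_error("mr_no_instruments", "every exposure was skipped; nothing to report")
  }
  out <- do.call(rbind, rows)
  out$or_value <- exp(out$beta)
  out$or_ci_low <- exp(out$ci_low)
  out$or_ci_high <- exp(out$ci_high)

  out$fdr <- NA_real_
  if (fdr_family == "primary") {
    idx <- which(out$primary)
    out$fdr[idx] <- bh_adjust(out$pval[idx])
  } else {
    for (m in unique(out$method)) {
      idx <- which(out$method == m & !is.na(out$pval))
      if (length(idx)) out$fdr[idx] <- bh_adjust(out$pval[idx])
    }
  }
  out$nominal <- !is.na(out$pval) & out$pval < 0.05
  out$fdr_significant <- !is.na(out$fdr) & out$fdr < 0.05

  cols <- c("exposure", "outcome", "method", "primary", "n_snps", "beta", "se",
            "ci_low", "ci_high", "or_value", "or_ci_low", "or_ci_high",
            "pval", "fdr", "nominal", "fdr_significant", "threshold_used",
            "heterogeneity_p", "egger_intercept_p", "presso_global_p",
            "steiger_removed")
  out <- out[cols]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "seed") <- seed
  class(out) <- c("screen_result", "data.frame")
  out
}

fmt_cell <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

#' Export screen results as figure-backing tables
#'
#' Writes `forest.tsv` (per-exposure primary-method odds ratio, CI, p-value
#' and FDR, the data behind a forest plot) and `methods_matrix.tsv`
#' (exposures by methods odds-ratio matrix with a p-value column per method,
#' the data behind a method-comparison ring/heatmap).  Rows are ordered by
#' FDR then label, and formatting is fixed, so re-exporting identical rows
#' yields byte-identical files.
#'
#' @param rows A `screen_result` from [run_screen()].
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
export_tables <- function(rows, out_dir) {
  if (nrow(rows) == 0L) mr_error("mr_domain_error", "no rows to export")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  prim <- rows[rows$primary, , drop = FALSE]
  prim <- prim[order(prim$fdr, prim$exposure), , drop = FALSE]
  forest <- data.frame(exposure = prim$exposure, outcome = prim$outcome,
                       method = prim$method, n_snps = prim$n_snps,
                       or_value = fmt_cell(prim$or_value),
                       or_ci_low = fmt_cell(prim$or_ci_low),
                       or_ci_high = fmt_cell(prim$or_ci_high),
                       pval = fmt_cell(prim$pval), fdr = fmt_cell(prim$fdr),
                       stringsAsFactors = FALSE)
  forest_path <- file.path(out_dir, "forest.tsv")
  utils::write.table(forest, forest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  methods <- sort(unique(rows$method))
  exposures <- unique(prim$exposure)  # already FDR-ordered
  mat <- data.frame(exposure = exposures, stringsAsFactors = FALSE)
  for (m in methods) {
    sub <- rows[rows$method == m, , drop = FALSE]
    j <- match(exposures, sub$exposure)
    mat[[paste0("or_", m)]] <- fmt_cell(sub$or_value[j])
    mat[[paste0("p_", m)]] <- fmt_cell(sub$pval[j])
  }
  matrix_path <- file.path(out_dir, "methods_matrix.tsv")
  utils::write.table(mat, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(forest = forest_path, methods_matrix = matrix_path))
}
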