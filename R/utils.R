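# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed errors so callers can distinguish failure modes with tryCatch().
mr_error <- function(class, message, call = sys.call(-1), ...) {
  stop(errorCondition(message, class = c(class, "mr_error", "error", "condition"),
                      call = call, ...))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    mr_error("mr_domain_error", sprintf("`%s` must be a single finite number", name))
  }
}

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer regardless of the user-facing seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k)) %% 2147483629)
}

crit95 <- function() stats::qnorm(0.975)

two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

is_instrument_table <- function(x) inherits(x, "instrument_table")

assert_instrument_table <- function(x, min_snps = 1L, fun = "this estimator") {
  if (!is_instrument_table(x)) {
    mr_error("mr_domain_error", "input must be an instrument_table (see harmonize())")
  }
  if (nrow(x) < min_snps) {
    if (min_snps == 2L && nrow(x) == 1L) {
      mr_error("mr_insufficient_instruments",
               sprintf("%s needs >= 2 SNPs; use mr_wald_ratio() for a single instrument", fun))
    }
    mr_error("mr_insufficient_instruments",
             sprintf("%s needs >= %d SNPs, got %d", fun, min_snps, nrow(x)))
  }
  invisible(x)
}
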