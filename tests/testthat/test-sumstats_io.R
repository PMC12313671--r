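# Summary-statistics I/O and allele harmonization.

test_that("a well-formed table reads back with no rejections", {
  df <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(df, path)
  got <- read_sumstats(path)
  expect_equal(nrow(got), 3L)
  expect_equal(nrow(attr(got, "rejected")), 0L)
  expect_equal(got$variant_id, df$variant_id)
})

test_that("invalid rows are rejected with line numbers and reasons", {
  df <- make_sumstats(c("rs1", "rs2", "rs3", "rs4", "rs2"))
  df$se[2] <- 0                      # invariant violation
  df$eaf[3] <- 1.5                   # out of range
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(df, path)
  expect_warning(got <- read_sumstats(path), "rejected 3")
  rej <- attr(got, "rejected")
  expect_equal(nrow(got), 2L)
  expect_setequal(rej$line, c(3L, 4L, 6L))  # data rows offset by the header
  expect_match(rej$reason[rej$line == 3L], "se")
  expect_match(rej$reason[rej$line == 6L], "duplicate")
})

test_that("unparsable numerics are collected, missing columns are fatal", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "pval", "n"), collapse = "\t"),
               "rs1\t1\t1000\tA\tG\t0.3\tnot_a_number\t0.01\t0.5\t50000",
               "rs2\t1\t2000\tA\tG\t0.3\t0.1\t0.01\t0.5\t50000"), path)
  expect_warning(got <- read_sumstats(path), "rejected 1")
  expect_match(attr(got, "rejected")$reason, "numeric")

  df2 <- make_sumstats(c("rs1", "rs2"))
  names_bad <- path
  writeLines(gsub("\tse\t", "\tstderr\t", readLines({write_sumstats(df2, path); path})),
             names_bad)
  expect_error(read_sumstats(names_bad), "se", class = "mr_missing_column")
  expect_error(read_sumstats(withr::local_tempfile(fileext = ".tsv")),
               class = "mr_io_error")
})

test_that("a column map reproduces the canonical-name parse", {
  df <- make_sumstats(sprintf("rs%d", 1:5), beta = rnorm(5, 0, 0.1))
  canon <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(df, canon)
  mapped <- withr::local_tempfile(fileext = ".tsv")
  txt <- readLines(canon)
  txt[1] <- "SNP\tCHR\tBP\tEA\tNEA\tEAF\tBETA\tSE\tP\tN"
  writeLines(txt, mapped)
  cm <- c(variant_id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "EA",
          other_allele = "NEA", eaf = "EAF", beta = "BETA", se = "SE",
          pval = "P", n = "N")
  expect_equal(read_sumstats(mapped, column_map = cm),
               read_sumstats(canon), ignore_attr = TRUE)
})

test_that("write/read round trip is the identity, including signs and gzip", {
  bundle <- simulate_pair(sim_config(n_snps = 100L, seed = PROP_SEED))
  df <- bundle$exposure
  expect_true(any(df$beta < 0))
  for (ext in c(".tsv", ".tsv.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_sumstats(df, path)
    got <- read_sumstats(path)
    attributes(got) <- attributes(got)[c("names", "row.names", "class")]
    attributes(df) <- attributes(df)[c("names", "row.names", "class")]
    expect_identical(got, df)
  }
})

test_that("an empty record set writes a header-only file", {
  df <- make_sumstats(character(0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(df, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_sumstats(path)), 0L)
})

# --- harmonization ---------------------------------------------------------

test_that("swapped outcome alleles flip the beta sign and eaf", {
  exposure <- make_sumstats("rs1", effect_allele = "A", other_allele = "G",
                            beta = 0.2, eaf = 0.3)
  outcome <- make_sumstats("rs1", effect_allele = "G", other_allele = "A",
                           beta = -0.05, eaf = 0.7)
  h <- harmonize(exposure, outcome)
  expect_equal(h$instruments$beta_out, 0.05)
  expect_equal(h$instruments$eaf_out, 0.3)
  expect_equal(h$report$n_flipped, 1L)
  expect_equal(h$report$n_matched, 1L)
})

test_that("ambiguous palindromic SNPs are dropped, unambiguous ones kept", {
  exposure <- make_sumstats(c("rs1", "rs2"), effect_allele = "A",
                            other_allele = "T", eaf = c(0.5, 0.2))
  outcome <- make_sumstats(c("rs1", "rs2"), effect_allele = "A",
                           other_allele = "T", eaf = c(0.5, 0.25))
  h <- harmonize(exposure, outcome)
  expect_equal(h$report$n_palindromic_dropped, 1L)
  expect_equal(h$instruments$variant_id, "rs2")

  # both eafs inside the tolerance band: dropped even though they agree
  exposure$eaf <- outcome$eaf <- c(0.45, 0.45)
  h2 <- harmonize(exposure, outcome)
  expect_equal(h2$report$n_palindromic_dropped, 2L)
})

test_that("incompatible allele pairs are dropped as mismatches", {
  exposure <- make_sumstats("rs1", effect_allele = "A", other_allele = "G")
  outcome <- make_sumstats("rs1", effect_allele = "A", other_allele = "C")
  h <- harmonize(exposure, outcome)
  expect_equal(h$report$n_allele_mismatch_dropped, 1L)
  expect_equal(nrow(h$instruments), 0L)
})

test_that("no overlapping variants raises a typed error", {
  exposure <- make_sumstats("rs1")
  outcome <- make_sumstats("rs2")
  expect_error(harmonize(exposure, outcome), class = "mr_no_overlap")
})

test_that("harmonizing an aligned pair is the identity (idempotence)", {
  bundle <- simulate_pair(sim_config(n_snps = 30L, seed = PROP_SEED))
  h <- harmonize(bundle$exposure, bundle$outcome)
  expect_equal(h$report$n_flipped, 0L)
  expect_equal(h$report$n_matched, 30L)
  expect_identical(h$instruments$beta_out, bundle$outcome$beta)
  expect_identical(h$instruments$beta_exp, bundle$exposure$beta)
})

test_that("flipping every outcome record's labels and sign changes nothing", {
  bundle <- simulate_pair(sim_config(n_snps = 30L, seed = PROP_SEED + 1L))
  flipped <- bundle$outcome
  flipped[c("effect_allele", "other_allele")] <- flipped[c("other_allele", "effect_allele")]
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h0 <- harmonize(bundle$exposure, bundle$outcome)
  h1 <- harmonize(bundle$exposure, flipped)
  expect_equal(h1$instruments, h0$instruments, ignore_attr = TRUE)
  expect_equal(h1$report$n_flipped, h0$report$n_matched)
})

test_that("report counts always account for every input SNP", {
  bundle <- simulate_pair(sim_config(n_snps = 40L, seed = PROP_SEED + 2L))
  rep <- harmonize(bundle$exposure, bundle$outcome)$report
  expect_lte(rep$n_matched + rep$n_palindromic_dropped + rep$n_allele_mismatch_dropped,
             rep$n_input)
  expect_true(all(unlist(rep) >= 0))
})
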