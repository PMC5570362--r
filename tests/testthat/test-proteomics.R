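# Peptide-to-protein ratio aggregation and the DE calling rules.

make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1]], peptide_id = r[[2]], replicate = r[[3]],
               intensity_light = r[[4]], intensity_medium = r[[5]],
               intensity_heavy = NA_real_)))
}

test_that("peptide ratios aggregate by median with both-channels-present rule", {
  rec <- make_records(
    list("P1", "a", 1, 1000, 250),
    list("P2", "a", 1, 100, 200), list("P2", "b", 1, 100, 400),
    list("P2", "c", 1, 100, 800),
    list("P3", "a", 1, NA, 500))          # control channel missing
  out <- aggregate_protein_ratios(rec, treatment = "medium",
                                  control = "light")
  expect_equal(out$ratio_1[out$protein_id == "P1"], 0.25)
  expect_equal(out$ratio_1[out$protein_id == "P2"], 4)   # median of 2,4,8
  expect_true(is.na(out$ratio_1[out$protein_id == "P3"]))
  expect_equal(out$n_observed[out$protein_id == "P3"], 0)
  expect_error(aggregate_protein_ratios(rec, treatment = "super"),
               "among")
})

test_that("z-test of log ratios matches the closed-form normal computation", {
  expect_equal(ztest_logratio(c(1, 1, 1)), 1)
  r <- c(2.5, 2.8, 2.2)
  lr <- log2(r)
  z <- mean(lr) / (sd(lr) / sqrt(3))
  expect_equal(z, 13.0845, tolerance = 1e-4)
  expect_equal(ztest_logratio(r), 2 * pnorm(-abs(z)))
  expect_lt(ztest_logratio(r), 1e-10)
  # sign symmetry: r and 1/r give identical p
  set.seed(9)
  for (i in 1:20) {
    rr <- exp(rnorm(3, runif(1, -1, 1), 0.4))
    expect_equal(ztest_logratio(rr), ztest_logratio(1 / rr),
                 tolerance = 1e-12)
  }
  expect_error(ztest_logratio(2), "at least two")
  expect_equal(ztest_logratio(c(2, 2, 2)), 0)  # sd 0, mean != 0
})

test_that("DE calls implement the conjunctive rules and the all-or-nothing rule", {
  expect_equal(call_de(c(2.5, 2.8, 2.2))$call, "up")
  expect_equal(call_de(c(1.0, 1.1, 0.95))$call, "ns")
  aon <- call_de(c(12, NA, NA))
  expect_equal(aon$call, "up")
  expect_true(aon$all_or_nothing)
  expect_equal(aon$n_observed, 1)
  down <- call_de(c(0.20, 0.23, 0.251))   # mean 0.227
  expect_equal(down$call, "down")
  expect_equal(down$signed_fold_change, -1 / 0.227, tolerance = 1e-12)
  expect_equal(round(down$signed_fold_change, 2), -4.41)
  expect_equal(call_de(numeric(0))$call, "insufficient")
  expect_equal(call_de(c(3, NA, NA))$call, "insufficient")
})

test_that("thresholds are strict at 2, 0.5, 10 and 0.1", {
  expect_equal(call_de(c(2, 2, 2))$call, "ns")       # mean exactly 2
  expect_equal(call_de(c(0.5, 0.5, 0.5))$call, "ns") # mean exactly 0.5
  ten <- call_de(c(10, NA, NA))
  expect_false(ten$all_or_nothing)                   # exactly 10 is not > 10
  expect_equal(ten$call, "insufficient")
  tenth <- call_de(c(0.1, NA, NA))
  expect_false(tenth$all_or_nothing)
  expect_equal(tenth$call, "insufficient")
})

test_that("signed fold change maps ratios below one to negative reciprocals", {
  expect_equal(signed_fold_change(4), 4)
  expect_equal(signed_fold_change(0.25), -4)
  expect_equal(signed_fold_change(1), 1)
  expect_error(signed_fold_change(0), "positive")
})

test_that("calls are invariant to per-replicate intensity scaling", {
  tab <- gen_proteomics_table(n_proteins = 30, seed = 4)
  calls1 <- de_call_table(aggregate_protein_ratios(tab))
  tab2 <- tab
  one_rep <- tab2$replicate == 2
  for (ch in c("intensity_light", "intensity_medium", "intensity_heavy"))
    tab2[[ch]][one_rep] <- tab2[[ch]][one_rep] * 37.5
  calls2 <- de_call_table(aggregate_protein_ratios(tab2))
  expect_equal(calls2$call, calls1$call)
  expect_equal(calls2$mean_ratio, calls1$mean_ratio, tolerance = 1e-12)
})

test_that("label swap inverts every ratio and maps up to down", {
  tab <- gen_proteomics_table(n_proteins = 30, seed = 8)
  fwd <- de_call_table(aggregate_protein_ratios(
    tab, treatment = "medium", control = "light"))
  # swapping treatment/control channel assignment inverts ratios; the
  # median roll-up commutes with inversion, so calls flip up <-> down
  rev <- de_call_table(aggregate_protein_ratios(
    tab, treatment = "light", control = "medium"))
  expect_equal(rev$mean_ratio[rev$protein_id == "petE_plastocyanin"] > 2,
               fwd$mean_ratio[fwd$protein_id == "petE_plastocyanin"] < 0.5)
  map <- c(up = "down", down = "up", ns = "ns",
           insufficient = "insufficient")
  # restrict to single-peptide-consistent proteins where median inversion
  # is exact: all proteins here have 3 peptides, median of odd n inverts
  expect_equal(rev$call, unname(map[fwd$call]))
})

test_that("median centring rescales each replicate to median ratio 1", {
  tab <- gen_proteomics_table(n_proteins = 50, seed = 3)
  ratios <- aggregate_protein_ratios(tab)
  centred <- median_centre_ratios(ratios)
  expect_equal(median(centred$ratio_1, na.rm = TRUE), 1)
})

test_that("peptide TSV reader enforces the schema", {
  tab <- gen_proteomics_table(n_proteins = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_peptide_tsv(f)
  expect_equal(nrow(back), nrow(tab))
  expect_error(read_peptide_tsv(textConnection("a\tb\n1\t2")), "columns")
})
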