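# Triplex dimethyl-label proteomics: peptide-intensity aggregation to
# protein treatment/control ratios and the rule-based differential
# expression caller.

#' Aggregate peptide channel intensities to protein ratios
#'
#' In triplex dimethyl labelling the three growth conditions are tagged with
#' light/medium/heavy formaldehyde isotopologues, mixed 1:1:1 and run
#' together; relative protein abundance is read from the intensity ratio of
#' the channel peaks of each peptide. Per protein and biological replicate
#' this computes the treatment/control intensity ratio of every peptide
#' observed in both channels, then rolls peptides up by the median (or
#' mean). Proteins with no usable peptide in a replicate get `NA` there.
#'
#' @param records data.frame with columns `protein_id, peptide_id,
#'   replicate` and `intensity_light, intensity_medium, intensity_heavy`
#'   (`NA` = channel missing).
#' @param treatment,control Channel names among `"light"`, `"medium"`,
#'   `"heavy"` (the experiments label control light and low Cu medium).
#' @param roll_up `"median"` (default) or `"mean"` across peptides.
#' @return data.frame with one row per protein: `protein_id`, one `ratio_<r>`
#'   column per replicate, and `n_observed`.
#' @export
#' @examples
#' tab <- gen_proteomics_table(n_proteins = 5, seed = 1)
#' aggregate_protein_ratios(tab)
aggregate_protein_ratios <- function(records, treatment = "medium",
                                     control = "light",
                                     roll_up = c("median", "mean")) {
  roll_up <- match.arg(roll_up)
  channels <- c("light", "medium", "heavy")
  if (!treatment %in% channels || !control %in% channels)
    stop("treatment and control must be among: ",
         paste(channels, collapse = ", "))
  need <- c("protein_id", "peptide_id", "replicate",
            paste0("intensity_", channels))
  missing_cols <- setdiff(c("protein_id", "peptide_id", "replicate",
                            paste0("intensity_", c(treatment, control))),
                          names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  trt <- records[[paste0("intensity_", treatment)]]
  ctl <- records[[paste0("intensity_", control)]]
  usable <- is.finite(trt) & is.finite(ctl) & trt > 0 & ctl > 0
  reps <- sort(unique(records$replicate))
  proteins <- unique(records$protein_id)
  rfun <- if (roll_up == "median") stats::median else mean
  ratio_mat <- matrix(NA_real_, nrow = length(proteins), ncol = length(reps),
                      dimnames = list(proteins, paste0("ratio_", reps)))
  sub <- records[usable, c("protein_id", "replicate")]
  sub$pep_ratio <- trt[usable] / ctl[usable]
  if (nrow(sub)) {
    agg <- stats::aggregate(pep_ratio ~ protein_id + replicate, data = sub,
                            FUN = rfun)
    ratio_mat[cbind(match(agg$protein_id, proteins),
                    match(agg$replicate, reps))] <- agg$pep_ratio
  }
  out <- data.frame(protein_id = proteins, ratio_mat, row.names = NULL,
                    check.names = FALSE)
  out$n_observed <- rowSums(!is.na(ratio_mat))
  out
}

#' One-sample z-test of log2 ratios against no change
#'
#' Tests whether the average treatment/control ratio of a protein differs
#' from 1, taking the between-replicate variance into account:
#' `z = mean(log2 r) / (sd(log2 r)/sqrt(n))`, with a two-sided p-value from
#' the standard normal. The log2 scale makes the test symmetric in r and
#' 1/r. Degenerate spread is handled by convention: sd = 0 with a non-zero
#' mean gives p = 0 (perfectly consistent change), sd = 0 with zero mean
#' gives p = 1.
#'
#' @param ratios Two or more finite positive ratios.
#' @return Two-sided p-value.
#' @export
#' @examples
#' ztest_logratio(c(2.5, 2.8, 2.2)) # ~ 5e-39
ztest_logratio <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  n <- length(ratios)
  if (n < 2L) stop("need at least two observed ratios")
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be finite and positive")
  lr <- log2(ratios)
  m <- mean(lr)
  s <- stats::sd(lr)
  if (s == 0) return(if (m == 0) 1 else 0)
  z <- m / (s / sqrt(n))
  2 * stats::pnorm(-abs(z))
}

#' Signed fold change of a mean ratio
#'
#' Reporting convention for ratio tables: the mean ratio itself when >= 1,
#' and `-1/ratio` when < 1, so a 4.4-fold decrease prints as -4.41 rather
#' than 0.227.
#'
#' @param mean_ratio Positive mean treatment/control ratio.
#' @return Signed fold change.
#' @export
#' @examples
#' signed_fold_change(0.227) # -4.41
signed_fold_change <- function(mean_ratio) {
  if (any(!is.finite(mean_ratio)) || any(mean_ratio <= 0))
    stop("mean ratio must be positive")
  ifelse(mean_ratio >= 1, mean_ratio, -1 / mean_ratio)
}

#' Call differential expression for one protein
#'
#' Applies the conjunctive significance rules to a protein's
#' treatment/control ratios across biological replicates:
#' a protein is *up* iff it was observed in at least two replicates, the
#' arithmetic mean of its ratios is > 2, and the z-test of its log2 ratios
#' gives p < 0.05; *down* symmetrically with mean < 0.5. Independently, any
#' single observed ratio > 10 (or < 0.1) marks an all-or-nothing response
#' and the protein is called up (down) regardless of the other rules. All
#' thresholds are strict. Fewer than two observed ratios (and no
#' all-or-nothing ratio) gives `"insufficient"`.
#'
#' @param ratios Numeric vector of per-replicate ratios (`NA` = not
#'   observed in that replicate).
#' @return One-row data.frame: `call` (`up`/`down`/`ns`/`insufficient`),
#'   `n_observed`, `mean_ratio`, `signed_fold_change`, `p_value`,
#'   `all_or_nothing`.
#' @export
#' @examples
#' call_de(c(2.5, 2.8, 2.2))   # up
#' call_de(c(12, NA, NA))      # all-or-nothing up
call_de <- function(ratios) {
  obs <- ratios[!is.na(ratios)]
  if (any(!is.finite(obs)) || any(obs <= 0))
    stop("observed ratios must be finite and positive")
  n <- length(obs)
  aon_up <- any(obs > 10)
  aon_down <- any(obs < 0.1)
  mean_ratio <- if (n) mean(obs) else NA_real_
  p <- if (n >= 2) ztest_logratio(obs) else NA_real_
  call <- if (aon_up) "up"
  else if (aon_down) "down"
  else if (n < 2) "insufficient"
  else if (mean_ratio > 2 && p < 0.05) "up"
  else if (mean_ratio < 0.5 && p < 0.05) "down"
  else "ns"
  data.frame(
    call = call, n_observed = n, mean_ratio = mean_ratio,
    signed_fold_change = if (n) signed_fold_change(mean_ratio) else NA_real_,
    p_value = p, all_or_nothing = aon_up || aon_down)
}

#' Call differential expression for a protein ratio table
#'
#' Vectorised [call_de()] over the output of [aggregate_protein_ratios()]
#' (or any table with `protein_id` plus `ratio_*` columns). A
#' Benjamini-Hochberg adjusted p-value column is appended for reference;
#' the calls themselves never use it.
#'
#' @param ratio_table data.frame with `protein_id` and `ratio_*` columns.
#' @return Tidy data.frame: `protein_id, n_observed, mean_ratio,
#'   signed_fold_change, p_value, p_adj_BH, all_or_nothing, call`.
#' @export
de_call_table <- function(ratio_table) {
  rcols <- grep("^ratio_", names(ratio_table), value = TRUE)
  if (!length(rcols)) stop("no ratio_* columns found")
  calls <- do.call(rbind, lapply(seq_len(nrow(ratio_table)), function(i)
    call_de(as.numeric(ratio_table[i, rcols]))))
  out <- cbind(data.frame(protein_id = ratio_table$protein_id), calls)
  out$p_adj_BH <- stats::p.adjust(out$p_value, method = "BH")
  out[c("protein_id", "n_observed", "mean_ratio", "signed_fold_change",
        "p_value", "p_adj_BH", "all_or_nothing", "call")]
}

#' Read a peptide intensity table from TSV
#'
#' Schema: `protein_id, peptide_id, replicate, intensity_light,
#' intensity_medium, intensity_heavy`; empty cells are missing channels.
#'
#' @param file TSV path.
#' @return data.frame in the [aggregate_protein_ratios()] input schema.
#' @export
read_peptide_tsv <- function(file) {
  df <- utils::read.delim(file, na.strings = c("", "NA"))
  need <- c("protein_id", "peptide_id", "replicate", "intensity_light",
            "intensity_medium", "intensity_heavy")
  if (!all(need %in% names(df)))
    stop("peptide TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Optional per-replicate median centring of ratios
#'
#' Divides every ratio in a replicate by that replicate's median ratio, the
#' usual correction when label incorporation or mixing is slightly off
#' 1:1:1. Off by default throughout the package.
#'
#' @param ratio_table Output of [aggregate_protein_ratios()].
#' @return The table with each `ratio_*` column median-centred.
#' @export
median_centre_ratios <- function(ratio_table) {
  rcols <- grep("^ratio_", names(ratio_table), value = TRUE)
  for (rc in rcols) {
    med <- stats::median(ratio_table[[rc]], na.rm = TRUE)
    if (is.finite(med) && med > 0)
      ratio_table[[rc]] <- ratio_table[[rc]] / med
  }
  ratio_table
}
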