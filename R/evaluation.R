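# Wild-vs-mutant contact evaluation: per-type count deltas, accuracies and
# the paired one-tailed t-test.

#' Evaluate mutant structures against their wild type
#'
#' Computes the seven-type contact profile of the wild structure and of
#' every mutant, the per-type count deltas, and per-type accuracies:
#' `accuracy` is the fraction of mutants whose delta is >= 0 (count
#' increased or kept), `accuracy_strict` the fraction with delta > 0, and
#' `accuracy_reduced_or_kept` the fraction with delta <= 0 (the reading
#' used for hydrophobic contacts, which are expected to drop when polar
#' side chains are grafted in).
#'
#' @param wild cleaned `prot_structure`
#' @param mutants list of `prot_structure` produced from `wild` by
#'   [graft_sidechains()]
#' @return list with `details` (one row per mutant x contact type: mutant,
#'   type, wild_count, mutant_count, delta) and `summary` (one row per
#'   type with the three accuracies); both empty for an empty mutant list
#' @export
evaluate_proposals <- function(wild, mutants) {
  empty_details <- data.frame(mutant = character(0), type = character(0),
                              wild_count = integer(0),
                              mutant_count = integer(0), delta = integer(0),
                              stringsAsFactors = FALSE)
  if (length(mutants) == 0)
    return(list(details = empty_details,
                summary = data.frame(type = character(0),
                                     accuracy = numeric(0),
                                     accuracy_strict = numeric(0),
                                     accuracy_reduced_or_kept = numeric(0),
                                     stringsAsFactors = FALSE)))
  wp <- classify_contacts(wild)
  details <- do.call(rbind, lapply(mutants, function(m) {
    mp <- classify_contacts(m)
    delta <- contact_delta(wp, mp)
    data.frame(mutant = m$id, type = CONTACT_TYPES,
               wild_count = unlist(wp[CONTACT_TYPES]),
               mutant_count = unlist(mp[CONTACT_TYPES]),
               delta = unname(delta), stringsAsFactors = FALSE)
  }))
  rownames(details) <- NULL
  summary <- do.call(rbind, lapply(CONTACT_TYPES, function(ty) {
    d <- details$delta[details$type == ty]
    data.frame(type = ty, accuracy = mean(d >= 0),
               accuracy_strict = mean(d > 0),
               accuracy_reduced_or_kept = mean(d <= 0),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(details = details, summary = summary)
}

#' Paired one-tailed t-test on contact counts
#'
#' Classic paired t statistic on the differences `mutant - wild`, with the
#' one-tailed p-value from the t distribution on n - 1 degrees of freedom.
#' The test direction must be chosen by the caller (`"greater"` tests for
#' an increase in the mutants).  Zero variance of the differences is a
#' degenerate test and raises an error rather than returning 0 or 1.
#'
#' @param wild_counts,mutant_counts equal-length numeric vectors, n >= 2
#' @param direction "greater" (mutant > wild) or "less"
#' @return list with `statistic`, `p_value`, `df`
#' @export
paired_one_tailed_ttest <- function(wild_counts, mutant_counts,
                                    direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(wild_counts) != length(mutant_counts))
    stop("paired test needs equal-length count vectors")
  if (length(wild_counts) < 2)
    stop("paired test needs at least two pairs")
  diffs <- mutant_counts - wild_counts
  if (stats::var(diffs) == 0)
    stop("degenerate paired test: differences have zero variance")
  fit <- stats::t.test(mutant_counts, wild_counts, paired = TRUE,
                       alternative = direction)
  list(statistic = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter))
}

#' Write an evaluation report as TSV
#'
#' @param ev result of [evaluate_proposals()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_evaluation <- function(ev, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(ev$details, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("", con)
  utils::write.table(ev$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
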