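#' Train a per-length-bin caller profile against a gold standard
#'
#' The pre-training stage. Every input caller is benchmarked per length
#' bin against the truth set ([stratified_metrics()]); within each bin
#' callers are ranked by the chosen metric, descending, and the full
#' per-caller metric rows are retained in the profile for audit. Ties
#' are broken by higher precision (false positives being the field's
#' chronic weakness), then lexicographic caller id, so training is
#' invariant to the order the call sets are supplied in. A bin with no
#' truth events cannot be ranked locally; it falls back to the callers'
#' global (unstratified) ranking and is flagged `untrained` in the
#' profile metadata.
#'
#' @param callsets List of [sv_callset()] objects, one per caller, all
#'   of the same `svtype` and pre-filtered to >= 50 bp.
#' @param truth The gold-standard [sv_callset()], >= 50 bp filtered.
#' @param bins A [length_bins()] partition.
#' @param tau Breakpoint tolerance in bp used for training (default
#'   100, the headline reporting threshold).
#' @param metric Ranking metric: `"fscore"` (default), `"precision"`
#'   or `"sensitivity"`.
#' @param organism,coverage Profile key; defaults taken from `truth`.
#' @param dataset Free-form training-set name stored in the metadata.
#' @return A [caller_profile()].
#' @export
train_profile <- function(callsets, truth, bins = length_bins(), tau = 100,
                          metric = c("fscore", "precision", "sensitivity"),
                          organism = truth$organism,
                          coverage = truth$coverage,
                          dataset = NA_character_) {
  metric <- match.arg(metric)
  stopifnot(length(callsets) >= 1, inherits(truth, "sv_callset"))
  ids <- vapply(callsets, `[[`, character(1), "caller_id")
  if (anyDuplicated(ids)) stop("duplicate caller_id among call sets")
  svtypes <- unique(unlist(lapply(callsets, function(cs)
    unique(cs$records$svtype))))
  svtype <- if (length(svtypes)) svtypes[1] else unique(truth$records$svtype)[1]
  if (length(svtypes) > 1)
    stop("call sets mix svtypes (", paste(svtypes, collapse = ", "),
         "); train one profile per svtype")

  per_caller <- lapply(callsets, stratified_metrics, truth = truth,
                       tau = tau, bins = bins)
  global <- do.call(rbind, lapply(callsets, function(cs)
    compute_metrics(match_callset(cs, truth, tau), caller = cs$caller_id)))

  rank_rows <- function(rows) {
    o <- order(-rows[[metric]], -rows$precision, rows$caller,
               method = "radix")
    rows <- rows[o, , drop = FALSE]
    rows$rank <- seq_len(nrow(rows))
    rownames(rows) <- NULL
    rows[, c("caller", "rank", "sensitivity", "precision", "fscore",
             "n_tp", "n_fp", "n_fn")]
  }

  tru_bin <- assign_bin(truth$records$svlen, bins)
  untrained <- integer(0)
  winners <- lapply(seq_len(n_bins(bins)) - 1L, function(b) {
    if (!any(tru_bin == b)) {
      untrained <<- c(untrained, b)
      rank_rows(global)
    } else {
      rows <- do.call(rbind, lapply(per_caller, function(pm)
        pm[pm$bin == b, , drop = FALSE]))
      rank_rows(rows)
    }
  })

  caller_profile(
    organism = if (is.na(organism)) "unknown" else organism,
    coverage = if (is.na(coverage)) 30 else coverage,
    svtype = svtype, bins = bins, bin_winners = winners,
    tau = tau, metric = metric,
    metadata = list(dataset = dataset, untrained_bins = untrained,
                    callers = sort(ids)))
}

#' Split a truth set by chromosome into training and test sets
#'
#' Chromosome-level hold-out: records on training chromosomes go to the
#' first set, records on test chromosomes to the second, and records on
#' chromosomes in neither are dropped with a message. The two
#' chromosome sets must be disjoint.
#'
#' @param truth An [sv_callset()].
#' @param train_chroms,test_chroms Disjoint chromosome-name sets.
#' @return A list with elements `train` and `test`, both
#'   [sv_callset()]s.
#' @export
train_test_split <- function(truth, train_chroms, test_chroms) {
  stopifnot(inherits(truth, "sv_callset"))
  if (length(intersect(train_chroms, test_chroms)))
    stop("train and test chromosome sets overlap: ",
         paste(intersect(train_chroms, test_chroms), collapse = ", "))
  rec <- truth$records
  in_train <- rec$chrom %in% train_chroms
  in_test <- rec$chrom %in% test_chroms
  dropped <- sum(!in_train & !in_test)
  if (dropped > 0)
    message(sprintf("train_test_split: dropped %d record(s) on unlisted chromosomes",
                    dropped))
  subset_cs <- function(keep) {
    out <- truth
    out$records <- rec[keep, , drop = FALSE]
    rownames(out$records) <- NULL
    out
  }
  test <- subset_cs(in_test)
  if (length(test) == 0) warning("test set is empty")
  list(train = subset_cs(in_train), test = test)
}
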