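#' Default resolution-threshold sweep (bp)
#'
#' Breakpoint tolerances at which call sets are benchmarked. 100 bp is
#' the headline threshold for single-number reports.
#' @export
DEFAULT_TAUS <- c(0, 10, 100, 1000, 10000)

#' Test whether two records match at resolution tau
#'
#' Two records of the same type on the same chromosome match when both
#' the left and the right breakpoint differ by at most `tau` bp
#' (inclusive). Insertions are points (`end == pos`), so for them the
#' rule degenerates to a single position comparison; an optional length
#' gate additionally requires the inserted lengths to agree within
#' `tau`.
#'
#' @param inferred,truth Single records (one-row `data.frame`s or lists
#'   with `chrom`, `pos`, `end`, `svtype`, `svlen`).
#' @param tau Non-negative breakpoint tolerance in bp.
#' @param ins_length_gate If `TRUE`, insertions must also satisfy
#'   `|svlen difference| <= tau`. Default `FALSE`.
#' @return `TRUE` or `FALSE`.
#' @export
records_match <- function(inferred, truth, tau, ins_length_gate = FALSE) {
  stopifnot(tau >= 0)
  if (inferred$chrom != truth$chrom || inferred$svtype != truth$svtype)
    return(FALSE)
  ok <- abs(inferred$pos - truth$pos) <= tau &&
    abs(inferred$end - truth$end) <= tau
  if (ok && ins_length_gate && inferred$svtype == "INS")
    ok <- abs(inferred$svlen - truth$svlen) <= tau
  ok
}

is_sorted_records <- function(rec) {
  o <- order(rec$chrom, rec$pos, rec$end, rec$svtype, method = "radix")
  identical(o, seq_len(nrow(rec)))
}

#' Match a call set against a truth set at resolution tau
#'
#' Pairs inferred records with truth records one-to-one by a greedy,
#' fully deterministic rule: truth records are visited in sorted order
#' and each is paired with the first (in sorted order) not-yet-paired
#' inferred record whose breakpoints both lie within `tau`. A record on
#' either side is used at most once; unpaired inferred records are false
#' positives and unpaired truth records false negatives.
#'
#' @param inferred,truth [sv_callset()] objects (sorted by construction).
#' @param tau Breakpoint tolerance in bp.
#' @param ins_length_gate Passed to [records_match()].
#' @return An object of class `sv_match` with elements `tau`,
#'   `tp` (a `data.frame` of paired row indices `inferred`/`truth`),
#'   `fp` and `fn` (row indices), and the two record tables.
#' @export
match_callset <- function(inferred, truth, tau, ins_length_gate = FALSE) {
  stopifnot(inherits(inferred, "sv_callset"), inherits(truth, "sv_callset"),
            length(tau) == 1L, tau >= 0)
  inf <- inferred$records
  tru <- truth$records
  if (!is_sorted_records(inf) || !is_sorted_records(tru))
    stop("match_callset: records are not in canonical sort order")

  used <- logical(nrow(inf))
  pair_inf <- integer(0)
  pair_tru <- integer(0)
  key_inf <- paste(inf$chrom, inf$svtype, sep = "\r")
  key_tru <- paste(tru$chrom, tru$svtype, sep = "\r")
  groups <- split(seq_len(nrow(inf)), key_inf)

  for (t in seq_len(nrow(tru))) {
    g <- groups[[key_tru[t]]]
    if (is.null(g)) next
    gp <- inf$pos[g]
    lo <- findInterval(tru$pos[t] - tau - 0.5, gp) + 1L
    hi <- findInterval(tru$pos[t] + tau + 0.5, gp)
    if (lo > hi) next
    cand <- g[lo:hi]
    cand <- cand[!used[cand] & abs(inf$end[cand] - tru$end[t]) <= tau]
    if (ins_length_gate && tru$svtype[t] == "INS" && length(cand))
      cand <- cand[abs(inf$svlen[cand] - tru$svlen[t]) <= tau]
    if (length(cand)) {
      i <- cand[1L]   # first in sorted order
      used[i] <- TRUE
      pair_inf <- c(pair_inf, i)
      pair_tru <- c(pair_tru, t)
    }
  }
  structure(list(
    tau = tau,
    tp = data.frame(inferred = pair_inf, truth = pair_tru),
    fp = which(!used),
    fn = setdiff(seq_len(nrow(tru)), pair_tru),
    inferred = inf, truth = tru
  ), class = "sv_match")
}

#' @export
print.sv_match <- function(x, ...) {
  cat(sprintf("sv_match (tau = %g bp): %d TP, %d FP, %d FN\n",
              x$tau, nrow(x$tp), length(x$fp), length(x$fn)))
  invisible(x)
}

#' Harmonic mean of sensitivity and precision
#'
#' `F = 2 * S * P / (S + P)`, with 0 returned when both inputs are 0.
#'
#' @param sensitivity,precision Fractions in `[0, 1]`.
#' @return The F-score, a fraction in `[0, 1]`.
#' @export
f_score <- function(sensitivity, precision) {
  ifelse(sensitivity + precision == 0, 0,
         2 * sensitivity * precision / (sensitivity + precision))
}

metrics_row <- function(n_tp, n_fp, n_fn, tau, bin = NA_integer_,
                        caller = NA_character_) {
  sens <- if (n_tp + n_fn == 0) 0 else n_tp / (n_tp + n_fn)
  prec <- if (n_tp + n_fp == 0) 0 else n_tp / (n_tp + n_fp)
  data.frame(caller = caller, tau = tau, bin = bin,
             n_tp = n_tp, n_fp = n_fp, n_fn = n_fn,
             sensitivity = sens, precision = prec,
             fscore = f_score(sens, prec), stringsAsFactors = FALSE)
}

#' Compute sensitivity, precision and F-score from a match
#'
#' Sensitivity is `TP / (TP + FN)`, precision `TP / (TP + FP)`, and the
#' F-score their harmonic mean. Zero-denominator cases (empty call or
#' truth sets) return 0 rather than `NaN`, so report rows stay
#' comparable.
#'
#' @param m An `sv_match` from [match_callset()].
#' @param caller Optional caller label for the output row.
#' @return A one-row `data.frame` with counts and the three metrics.
#' @export
compute_metrics <- function(m, caller = NA_character_) {
  stopifnot(inherits(m, "sv_match"))
  metrics_row(nrow(m$tp), length(m$fp), length(m$fn), m$tau,
              caller = caller)
}

#' Benchmark a call set across several resolution thresholds
#'
#' Runs [match_callset()] and [compute_metrics()] once per tolerance.
#' Because the match predicate only relaxes as `tau` grows, TP counts
#' (and hence sensitivity and precision) are non-decreasing in `tau`.
#'
#' @param inferred,truth [sv_callset()] objects.
#' @param taus Non-empty vector of tolerances in bp
#'   (default `r toString(c(0, 10, 100, 1000, 10000))`).
#' @param caller Optional caller label for the rows.
#' @return A `data.frame` with one row per `tau`.
#' @export
threshold_sweep <- function(inferred, truth, taus = DEFAULT_TAUS,
                            caller = inferred$caller_id) {
  stopifnot(length(taus) >= 1)
  do.call(rbind, lapply(taus, function(tau)
    compute_metrics(match_callset(inferred, truth, tau), caller = caller)))
}

#' Per-length-bin benchmarking
#'
#' Stratifies both the truth set and the call set by the length bin of
#' each record's own `svlen`, then re-matches within each stratum.
#' Because matching is redone per stratum, per-bin TP counts need not
#' sum to the unstratified TP count when breakpoint jitter moves a call
#' across a bin edge.
#'
#' @param inferred,truth [sv_callset()] objects.
#' @param tau Breakpoint tolerance in bp.
#' @param bins A [length_bins()] partition.
#' @param caller Optional caller label for the rows.
#' @return A `data.frame` with one row per bin (column `bin` is the
#'   0-based bin index).
#' @export
stratified_metrics <- function(inferred, truth, tau, bins = length_bins(),
                               caller = inferred$caller_id) {
  inf <- inferred$records
  tru <- truth$records
  inf_bin <- assign_bin(inf$svlen, bins)
  tru_bin <- assign_bin(tru$svlen, bins)
  rows <- lapply(seq_len(n_bins(bins)) - 1L, function(b) {
    sub_inf <- inferred; sub_inf$records <- sort_records(inf[inf_bin == b, , drop = FALSE])
    sub_tru <- truth; sub_tru$records <- sort_records(tru[tru_bin == b, , drop = FALSE])
    row <- compute_metrics(match_callset(sub_inf, sub_tru, tau),
                           caller = caller)
    row$bin <- b
    row
  })
  do.call(rbind, rows)
}
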