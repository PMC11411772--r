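#' Consensus-merge configuration
#'
#' @param mode `"standard"` (per-bin winner routing), `"precision"`
#'   (keep only multi-caller-supported events) or `"recall"` (union of
#'   all callers).
#' @param dedupe_tau Breakpoint tolerance in bp under which two records
#'   are considered the same event when deduplicating and when counting
#'   support (default 100, matching the evaluation tolerance so "same
#'   event" means the same thing when building and when scoring).
#' @param min_support Minimum number of distinct supporting callers for
#'   precision mode (default 2, the weakest agreement requirement that
#'   still filters caller-private false positives).
#' @param consensus_id Caller label for the merged output.
#' @return A list of class `merge_config`.
#' @export
merge_config <- function(mode = c("standard", "precision", "recall"),
                         dedupe_tau = 100, min_support = 2,
                         consensus_id = "consensus") {
  mode <- match.arg(mode)
  stopifnot(dedupe_tau >= 0, min_support >= 1)
  structure(list(mode = mode, dedupe_tau = dedupe_tau,
                 min_support = as.integer(min_support),
                 consensus_id = consensus_id),
            class = "merge_config")
}

# Priority of each record: its caller's position in `ranking` (unranked
# callers go last), ties resolved by canonical sort order.
record_priority <- function(rec, ranking = NULL) {
  if (is.null(ranking)) return(seq_len(nrow(rec)))
  r <- match(rec$caller, ranking)
  r[is.na(r)] <- length(ranking) + 1L
  order(order(r, seq_len(nrow(rec)), method = "radix"), method = "radix")
}

# Overall caller priority implied by a profile: best bin rank, ties by id.
profile_ranking <- function(profile) {
  tab <- do.call(rbind, lapply(profile$bin_winners, function(w)
    w[, c("caller", "rank")]))
  best <- vapply(split(tab$rank, tab$caller), min, numeric(1))
  names(best)[order(best, names(best), method = "radix")]
}

#' Remove tau-duplicate records from a call set
#'
#' Greedy clustering: records are visited in priority order (by default
#' the canonical sort order) and a record is dropped when an already
#' retained record of the same type on the same chromosome has both
#' breakpoints within `tau`. No two retained records violate the
#' separation predicate, and the operation is idempotent.
#'
#' @param calls An [sv_callset()].
#' @param tau Breakpoint tolerance in bp.
#' @param ranking Optional character vector of caller ids in decreasing
#'   priority; among duplicates the highest-priority caller's record is
#'   the one retained.
#' @return The deduplicated [sv_callset()], sorted.
#' @export
dedupe <- function(calls, tau, ranking = NULL) {
  stopifnot(inherits(calls, "sv_callset"), tau >= 0)
  rec <- calls$records
  if (nrow(rec) <= 1) return(calls)
  ord <- order(record_priority(rec, ranking), method = "radix")
  keep <- logical(nrow(rec))
  kept <- list()  # per (chrom, svtype): list(pos =, end =)
  for (i in ord) {
    key <- paste(rec$chrom[i], rec$svtype[i], sep = "\r")
    k <- kept[[key]]
    dup <- !is.null(k) &&
      any(abs(k$pos - rec$pos[i]) <= tau & abs(k$end - rec$end[i]) <= tau)
    if (!dup) {
      keep[i] <- TRUE
      kept[[key]] <- list(pos = c(k$pos, rec$pos[i]),
                          end = c(k$end, rec$end[i]))
    }
  }
  calls$records <- sort_records(rec[keep, , drop = FALSE])
  calls
}

# For each record in `a`, does any record in `b` (same chrom+svtype)
# match both breakpoints within tau?
has_match_in <- function(a, b, tau) {
  out <- logical(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  key_a <- paste(a$chrom, a$svtype, sep = "\r")
  key_b <- paste(b$chrom, b$svtype, sep = "\r")
  groups <- split(seq_len(nrow(b)), key_b)
  for (i in seq_len(nrow(a))) {
    g <- groups[[key_a[i]]]
    if (is.null(g)) next
    out[i] <- any(abs(b$pos[g] - a$pos[i]) <= tau &
                  abs(b$end[g] - a$end[i]) <= tau)
  }
  out
}

pool_records <- function(callsets) {
  rec <- do.call(rbind, lapply(callsets, function(cs) {
    r <- cs$records
    r$src_caller <- cs$caller_id
    r
  }))
  sort_records(rec)
}

#' Merge call sets into a consensus using a trained profile
#'
#' Discovery mode. In standard mode each length bin contributes the
#' records of that bin's winning caller whose own length falls in the
#' bin; the routed records are concatenated and deduplicated at
#' `cfg$dedupe_tau`. Every consensus record carries its source caller
#' and bin index as provenance. `"precision"` and `"recall"` modes
#' delegate to [optimize_precision()] / [optimize_recall()], using the
#' profile's caller ranking to pick representatives.
#'
#' @param profile A [caller_profile()].
#' @param callsets List of [sv_callset()]s covering at least every
#'   bin-winning caller in the profile; all >= 50 bp filtered.
#' @param cfg A [merge_config()].
#' @return The consensus [sv_callset()].
#' @export
merge_by_profile <- function(profile, callsets, cfg = merge_config()) {
  stopifnot(inherits(profile, "caller_profile"))
  ids <- vapply(callsets, `[[`, character(1), "caller_id")
  names(callsets) <- ids
  ranking <- profile_ranking(profile)
  if (cfg$mode == "recall")
    return(optimize_recall(callsets, cfg, ranking = ranking))
  if (cfg$mode == "precision")
    return(optimize_precision(callsets, cfg, ranking = ranking))

  winners <- bin_winners(profile)
  missing <- setdiff(unique(winners), ids)
  if (length(missing))
    stop("no call set supplied for bin-winning caller(s): ",
         paste(missing, collapse = ", "))
  routed <- lapply(seq_along(winners), function(b) {
    rec <- callsets[[winners[b]]]$records
    if (nrow(rec) == 0) return(rec)
    rec <- rec[assign_bin(rec$svlen, profile$bins) == (b - 1L), ,
               drop = FALSE]
    if (nrow(rec)) {
      rec$src_caller <- winners[b]
      rec$bin <- b - 1L
    }
    rec
  })
  rec <- sort_records(do.call(rbind, routed))
  out <- sv_callset(rec, caller_id = cfg$consensus_id,
                    organism = profile$organism,
                    coverage = callsets[[1]]$coverage)
  out$records$caller <- cfg$consensus_id
  dedupe(out, cfg$dedupe_tau, ranking = ranking)
}

#' Recall-optimized consensus: union of all callers
#'
#' Takes every record from every input caller and deduplicates at
#' `cfg$dedupe_tau`. Because the output tau-contains every input call,
#' its sensitivity on any truth set is at least that of every input
#' caller.
#'
#' @param callsets List of [sv_callset()]s.
#' @param cfg A [merge_config()].
#' @param ranking Optional caller priority for duplicate
#'   representatives (default: canonical sort order).
#' @return The consensus [sv_callset()].
#' @export
optimize_recall <- function(callsets, cfg = merge_config(mode = "recall"),
                            ranking = NULL) {
  stopifnot(length(callsets) >= 1)
  rec <- pool_records(callsets)
  out <- sv_callset(rec, caller_id = cfg$consensus_id,
                    organism = callsets[[1]]$organism,
                    coverage = callsets[[1]]$coverage)
  out$records$caller <- out$records$src_caller
  out <- dedupe(out, cfg$dedupe_tau, ranking = ranking)
  out$records$caller <- cfg$consensus_id
  out
}

#' Precision-optimized consensus: multi-caller agreement filter
#'
#' A record survives only when records within `cfg$dedupe_tau` of it
#' (both breakpoints, same type) exist in at least `cfg$min_support`
#' distinct callers -- a caller's own duplicates count once, so a noisy
#' caller cannot self-confirm. Survivors are then deduplicated, keeping
#' the highest-priority caller's record as representative; the support
#' count is recorded in the output. With `min_support = 1` this reduces
#' exactly to [optimize_recall()].
#'
#' @inheritParams optimize_recall
#' @return The consensus [sv_callset()] with a `support` column.
#' @export
optimize_precision <- function(callsets,
                               cfg = merge_config(mode = "precision"),
                               ranking = NULL) {
  if (length(callsets) < cfg$min_support)
    stop("min_support (", cfg$min_support, ") exceeds the number of callers (",
         length(callsets), ")")
  tau <- cfg$dedupe_tau
  support <- vector("list", length(callsets))
  for (i in seq_along(callsets)) {
    a <- callsets[[i]]$records
    s <- rep(1L, nrow(a))
    for (j in seq_along(callsets))
      if (j != i) s <- s + has_match_in(a, callsets[[j]]$records, tau)
    support[[i]] <- s
  }
  rec <- do.call(rbind, lapply(seq_along(callsets), function(i) {
    r <- callsets[[i]]$records
    r$src_caller <- callsets[[i]]$caller_id
    r$support <- support[[i]]
    r
  }))
  rec <- sort_records(rec[rec$support >= cfg$min_support, , drop = FALSE])
  out <- sv_callset(rec, caller_id = cfg$consensus_id,
                    organism = callsets[[1]]$organism,
                    coverage = callsets[[1]]$coverage)
  out$records$caller <- out$records$src_caller
  out <- dedupe(out, tau, ranking = ranking)
  out$records$caller <- cfg$consensus_id
  out
}
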