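#' Genome model for synthetic fixtures
#'
#' Chromosome names and lengths used to place simulated events. The
#' default is the five human chromosomes conventionally used for
#' chromosome-held-out train/test experiments (GRCh38 lengths for
#' chr15-chr19), large enough to place thousands of well-separated
#' events.
#'
#' @param chroms Named numeric vector of chromosome lengths in bp.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chroms = c(chr15 = 101991189, chr16 = 90338345,
                                    chr17 = 83257441, chr18 = 80373285,
                                    chr19 = 58617616)) {
  stopifnot(length(chroms) >= 1, all(chroms > 0), !is.null(names(chroms)))
  structure(list(chroms = chroms), class = "genome_model")
}

genome_mb <- function(genome) sum(genome$chroms) / 1e6

#' Error model for a simulated caller
#'
#' Describes how an imperfect caller corrupts the truth: a detection
#' probability per length bin (real callers are strong in some length
#' regimes and weak in others), a genome-wide false-positive rate, and
#' zero-mean breakpoint jitter. Used by [corrupt()].
#'
#' @param sensitivity Detection probability per bin (length must equal
#'   the number of bins).
#' @param fp_rate Expected false calls per Mb of genome.
#' @param jitter_sd Standard deviation (bp) of the rounded Gaussian
#'   noise added to each breakpoint.
#' @param length_noise_sd Extra length noise (bp) for insertions.
#' @param bins The [length_bins()] the sensitivities refer to.
#' @param seed Integer seed making the corruption reproducible.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sensitivity, fp_rate = 0, jitter_sd = 0,
                        length_noise_sd = 0, bins = length_bins(),
                        seed = 1L) {
  stopifnot(length(sensitivity) == n_bins(bins),
            all(sensitivity >= 0 & sensitivity <= 1),
            fp_rate >= 0, jitter_sd >= 0, length_noise_sd >= 0)
  structure(list(sensitivity = sensitivity, fp_rate = fp_rate,
                 jitter_sd = jitter_sd, length_noise_sd = length_noise_sd,
                 bins = bins, seed = as.integer(seed)),
            class = "error_model")
}

# Map flat slot index to (chrom, slot offset) given per-chrom slot counts.
allocate_slots <- function(genome, n) {
  len <- genome$chroms
  raw <- n * len / sum(len)
  n_c <- floor(raw)
  rem <- n - sum(n_c)
  if (rem > 0) {
    o <- order(raw - n_c, decreasing = TRUE)
    n_c[o[seq_len(rem)]] <- n_c[o[seq_len(rem)]] + 1
  }
  n_c
}

#' Generate a synthetic truth set
#'
#' Places `n_per_bin` events per length bin on the genome. Lengths are
#' log-uniform within each bin (the top, open-ended bin is capped at
#' `max_len`); positions are uniform within disjoint slots so that no
#' two events come closer than twice the maximum event length, which
#' rules out matching ambiguity in fixtures. Fully deterministic per
#' seed.
#'
#' @param genome A [genome_model()].
#' @param n_per_bin Events per bin.
#' @param bins A [length_bins()] partition.
#' @param svtype Event type for the whole set.
#' @param seed Integer seed.
#' @param max_len Length cap for the open-ended top bin (default
#'   10000 bp).
#' @return An [sv_callset()] with `caller_id = "truth"`.
#' @export
generate_truth <- function(genome = genome_model(), n_per_bin,
                           bins = length_bins(), svtype = "DEL", seed = 1L,
                           max_len = 10000) {
  stopifnot(n_per_bin >= 0, max_len > bins$edges[n_bins(bins)])
  n <- n_per_bin * n_bins(bins)
  if (n == 0)
    return(sv_callset(caller_id = "truth", organism = "synthetic"))
  gap <- 2 * max_len
  withr::with_seed(seed, {
    lo <- bins$edges
    hi <- c(bins$edges[-1], max_len)
    svlen <- unlist(lapply(seq_len(n_bins(bins)), function(b)
      floor(exp(runif(n_per_bin, log(lo[b]), log(hi[b]))))))
    svlen <- pmin(pmax(svlen, lo[rep(seq_len(n_bins(bins)), each = n_per_bin)]),
                  rep(hi, each = n_per_bin) - 1)
    svlen <- sample(svlen)  # mix bins along the genome
    n_c <- allocate_slots(genome, n)
    k <- 0
    rec <- NULL
    for (c in seq_along(n_c)) {
      if (n_c[c] == 0) next
      w <- genome$chroms[c] / n_c[c]
      lens <- svlen[k + seq_len(n_c[c])]
      room <- w - lens - gap - 1
      if (any(room < 1))
        stop("genome too small to place ", n, " events ", gap,
             " bp apart; enlarge the genome or reduce n_per_bin")
      pos <- floor((seq_len(n_c[c]) - 1) * w + runif(n_c[c]) * room) + 1
      rec <- rbind(rec, data.frame(chrom = names(genome$chroms)[c],
                                   pos = pos, svlen = lens,
                                   stringsAsFactors = FALSE))
      k <- k + n_c[c]
    }
    records <- sv_records(
      chrom = rec$chrom, pos = rec$pos,
      end = if (svtype == "INS") NA else rec$pos + rec$svlen,
      svtype = svtype, svlen = rec$svlen,
      id = sprintf("truth_%05d", seq_len(n)), caller = "truth")
    sv_callset(records, caller_id = "truth", organism = "synthetic")
  })
}

#' Corrupt a truth set into an imperfect caller's output
#'
#' Emits each truth event with its bin's detection probability, jitters
#' the emitted breakpoints with rounded zero-mean Gaussian noise
#' (deletion breakpoints independently, so lengths wobble; insertions
#' jitter position only), and adds Poisson false positives whose
#' lengths are resampled from the truth length distribution so every
#' bin sees false calls. Events are clamped to stay >= 50 bp.
#'
#' @param truth An [sv_callset()] from [generate_truth()].
#' @param model An [error_model()].
#' @param genome The [genome_model()] used for false-positive placement.
#' @param caller_id Label for the simulated caller.
#' @return A sorted [sv_callset()].
#' @export
corrupt <- function(truth, model, genome = genome_model(),
                    caller_id = "sim") {
  stopifnot(inherits(truth, "sv_callset"), inherits(model, "error_model"))
  tru <- truth$records
  withr::with_seed(model$seed, {
    out <- NULL
    if (nrow(tru)) {
      bin <- assign_bin(tru$svlen, model$bins)
      kept <- tru[runif(nrow(tru)) < model$sensitivity[bin + 1L], ,
                  drop = FALSE]
      if (nrow(kept)) {
        jit <- function(n) round(rnorm(n, 0, model$jitter_sd))
        ins <- kept$svtype == "INS"
        kept$pos <- pmax(1, kept$pos + jit(nrow(kept)))
        kept$end[!ins] <- kept$end[!ins] + jit(sum(!ins))
        kept$end[!ins] <- pmax(kept$end[!ins], kept$pos[!ins] + 50)
        kept$svlen[!ins] <- kept$end[!ins] - kept$pos[!ins]
        if (any(ins)) {
          kept$end[ins] <- kept$pos[ins]
          kept$svlen[ins] <- pmax(
            50, kept$svlen[ins] + round(rnorm(sum(ins), 0,
                                              model$length_noise_sd)))
        }
        out <- kept
      }
    }
    n_fp <- rpois(1, model$fp_rate * genome_mb(genome))
    if (n_fp > 0) {
      src_len <- if (nrow(tru)) tru$svlen else
        stop("cannot draw false-positive lengths from an empty truth set")
      svtype <- if (nrow(tru)) tru$svtype[1] else "DEL"
      len <- sample(src_len, n_fp, replace = TRUE)
      chrom_i <- sample(seq_along(genome$chroms), n_fp, replace = TRUE,
                        prob = genome$chroms)
      pos <- floor(runif(n_fp) * (genome$chroms[chrom_i] - len - 1)) + 1
      fp <- data.frame(
        chrom = names(genome$chroms)[chrom_i], pos = pos,
        end = if (svtype == "INS") pos else pos + len,
        svtype = svtype, svlen = len,
        id = sprintf("fp_%05d", seq_len(n_fp)), qual = NA_real_,
        caller = caller_id, src_caller = NA_character_,
        bin = NA_integer_, support = NA_integer_,
        stringsAsFactors = FALSE)
      out <- if (is.null(out)) fp else
        rbind(out[, REC_COLS, drop = FALSE], fp[, REC_COLS, drop = FALSE])
    }
    if (is.null(out))
      return(sv_callset(caller_id = caller_id, organism = truth$organism))
    out$caller <- caller_id
    out$id <- NA_character_
    sv_callset(out, caller_id = caller_id, organism = truth$organism)
  })
}
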