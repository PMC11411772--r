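#' Subsampling fraction to reach a target coverage
#'
#' @param current_coverage Current mean depth in x.
#' @param target_coverage Desired mean depth in x; must not exceed the
#'   current depth.
#' @return `target_coverage / current_coverage`, clipped to `[0, 1]`.
#' @export
fraction_for_target <- function(current_coverage, target_coverage) {
  stopifnot(target_coverage > 0)
  if (target_coverage > current_coverage)
    stop("target coverage (", target_coverage,
         "x) exceeds current coverage (", current_coverage, "x)")
  min(1, target_coverage / current_coverage)
}

#' Downsample an alignment file without stranding mates
#'
#' Generic record-level subsampling splits read pairs, leaving singleton
#' reads whose mates were discarded -- an artifact that distorts
#' discordant-pair evidence downstream. Here the keep/drop decision is
#' made once per read-name group (template), by a seeded hash of the
#' read name, so both mates -- and any secondary or supplementary
#' records of the template -- share one fate. Unpaired reads form
#' groups of one and are sampled at the same rate. Output is
#' deterministic given `(input, fraction, seed)`; the header is passed
#' through with a `@PG` record appended.
#'
#' SAM text is processed natively; `.bam` input/output is converted via
#' Rsamtools when available.
#'
#' @param input Path to a SAM (or BAM) file with a valid header.
#' @param output Path for the downsampled SAM (or BAM) file.
#' @param fraction Probability of keeping each read-name group, in
#'   `[0, 1]`.
#' @param seed Integer seed for the read-name hash.
#' @return Invisibly, a list with counts: records and read-name groups
#'   in and out.
#' @export
downsample_pairs <- function(input, output, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a single value in [0, 1]")
  if (!file.exists(input)) stop("cannot read alignment file: ", input)

  bam_in <- grepl("\\.bam$", input, ignore.case = TRUE)
  bam_out <- grepl("\\.bam$", output, ignore.case = TRUE)
  if (bam_in || bam_out) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("BAM support needs the Rsamtools package; use SAM text instead")
  }
  sam_in <- input
  if (bam_in) {
    sam_in <- tempfile(fileext = ".sam")
    on.exit(unlink(sam_in), add = TRUE)
    Rsamtools::asSam(input, sub("\\.sam$", "", sam_in), overwrite = TRUE)
  }

  lines <- readLines(sam_in)
  is_hdr <- startsWith(lines, "@")
  if (!any(is_hdr) || !is_hdr[1])
    stop("alignment file has no header: ", input)
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  qname <- sub("\t.*$", "", body)
  keep <- hash_unit(qname, as.numeric(seed)) < fraction
  pg <- sprintf(
    "@PG\tID:svconsensus.downsample\tPN:svconsensus\tVN:%s\tCL:downsample_pairs fraction=%g seed=%d",
    as.character(packageVersion("svconsensus")), fraction, as.integer(seed))

  sam_out <- output
  if (bam_out) sam_out <- tempfile(fileext = ".sam")
  writeLines(c(hdr, pg, body[keep]), sam_out)
  if (bam_out) {
    Rsamtools::asBam(sam_out, sub("\\.bam$", "", output), overwrite = TRUE,
                     indexDestination = FALSE)
    unlink(sam_out)
  }

  groups_in <- unique(qname)
  invisible(list(
    n_records_in = length(body), n_records_out = sum(keep),
    n_groups_in = length(groups_in),
    n_groups_kept = length(unique(qname[keep]))
  ))
}
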