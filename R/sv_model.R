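SV_TYPES <- c("DEL", "INS", "DUP", "INV", "OTHER")

REC_COLS <- c("chrom", "pos", "end", "svtype", "svlen", "id", "qual",
              "caller", "src_caller", "bin", "support")

#' Build a table of structural variant records
#'
#' Constructs the validated record table used inside an [sv_callset()].
#' Coordinates are 1-based inclusive, mirroring VCF. For deletions,
#' duplications and inversions the event length is tied to the
#' breakpoints (`svlen == end - pos`); whichever of `end`/`svlen` is
#' missing is reconstructed from the other. Insertions are points
#' (`end == pos`) and `svlen` is the inserted-sequence length.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based start coordinates (left breakpoints).
#' @param end 1-based end coordinates (right breakpoints); may be `NA`
#'   where `svlen` is given (except for insertions, where it is ignored).
#' @param svtype One of `"DEL"`, `"INS"`, `"DUP"`, `"INV"`, `"OTHER"`.
#' @param svlen Event length magnitudes in bp (>= 1); may be `NA` where
#'   `end` is given.
#' @param id,qual Optional record identifiers and quality scores.
#' @param caller Source caller label.
#' @return A `data.frame` with one row per record.
#' @export
sv_records <- function(chrom, pos, end = NA, svtype, svlen = NA,
                       id = NA_character_, qual = NA_real_,
                       caller = NA_character_) {
  n <- length(pos)
  rec <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = as.numeric(pos),
    end = rep_len(as.numeric(end), n),
    svtype = rep_len(as.character(svtype), n),
    svlen = rep_len(as.numeric(svlen), n),
    id = rep_len(as.character(id), n),
    qual = rep_len(as.numeric(qual), n),
    caller = rep_len(as.character(caller), n),
    src_caller = rep(NA_character_, n), bin = rep(NA_integer_, n),
    support = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  normalize_records(rec)
}

# Enforce the coordinate/length invariants; errors on irreparable rows.
normalize_records <- function(rec) {
  if (nrow(rec) == 0) return(rec)
  bad_type <- !rec$svtype %in% SV_TYPES
  if (any(bad_type))
    stop("unknown svtype: ", paste(unique(rec$svtype[bad_type]), collapse = ", "))
  ins <- rec$svtype == "INS"
  rec$end[ins] <- rec$pos[ins]
  span <- !ins
  no_end <- span & is.na(rec$end)
  rec$end[no_end] <- rec$pos[no_end] + rec$svlen[no_end]
  rec$svlen[span] <- rec$end[span] - rec$pos[span]
  if (any(is.na(rec$pos)) || any(is.na(rec$end)) || any(is.na(rec$svlen)))
    stop("records need pos and at least one of end/svlen")
  if (any(rec$pos < 1)) stop("pos must be >= 1")
  if (any(rec$end < rec$pos)) stop("end must be >= pos")
  if (any(rec$svlen < 1)) stop("svlen must be >= 1")
  rec
}

# Total, deterministic record order: (chrom, pos, end, svtype), C locale.
sort_records <- function(rec) {
  o <- order(rec$chrom, rec$pos, rec$end, rec$svtype, method = "radix")
  rec <- rec[o, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Create a call set
#'
#' A call set is the unit the whole package operates on: the sorted SV
#' records of one caller (or of the consensus), tagged with the sample's
#' organism and mean coverage. Records are re-sorted on construction so
#' ordering is total and reproducible.
#'
#' @param records A record table from [sv_records()] (or a compatible
#'   `data.frame`).
#' @param caller_id Label of the producing caller.
#' @param organism Organism tag (e.g. `"human"`, `"mouse"`).
#' @param coverage Mean sequencing depth in x, if known.
#' @return An object of class `sv_callset`.
#' @export
sv_callset <- function(records = sv_records(character(), numeric(),
                                            svtype = character()),
                       caller_id, organism = NA_character_,
                       coverage = NA_real_) {
  stopifnot(is.data.frame(records), is.character(caller_id),
            length(caller_id) == 1L)
  for (col in REC_COLS)
    if (!col %in% names(records)) records[[col]] <- NA
  records <- normalize_records(records[, REC_COLS, drop = FALSE])
  records$caller[is.na(records$caller)] <- caller_id
  structure(list(records = sort_records(records), caller_id = caller_id,
                 organism = as.character(organism),
                 coverage = as.numeric(coverage)),
            class = "sv_callset")
}

#' @export
length.sv_callset <- function(x) nrow(x$records)

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("sv_callset '%s': %d records", x$caller_id, length(x)))
  if (!is.na(x$organism)) cat(sprintf(" | organism %s", x$organism))
  if (!is.na(x$coverage)) cat(sprintf(" | coverage %gx", x$coverage))
  cat("\n")
  if (length(x)) {
    tab <- table(x$records$svtype)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.sv_callset <- function(x, ...) x$records

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info,
                                perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(?:^|;)", key, "="), info, perl = TRUE)
  out[hit] <- sub(paste0("^.*?(?:^|;)", key, "="), "", m)
  out
}

#' Read structural variant calls from a VCF file
#'
#' Parses a VCF 4.x file into an [sv_callset()]. `SVTYPE` is taken from
#' INFO (falling back to a symbolic ALT such as `<DEL>`). Coordinates are
#' authoritative for deletions: when both `END` and `SVLEN` are present
#' and disagree, the length is recomputed as `END - POS`; for insertions
#' `SVLEN` wins. Multi-allelic records are split into one record per ALT.
#' Records with an unknown `SVTYPE`, or missing both `SVLEN` and `END`,
#' are counted and skipped with a message rather than aborting the parse.
#' Genotype columns are ignored: this is a site-level tool.
#'
#' @param path Path to a VCF file (plain or bgzip/gzip compressed).
#' @param caller_id Caller label to attach to every record.
#' @param organism,coverage Optional sample metadata for the call set.
#' @return An [sv_callset()].
#' @export
parse_vcf <- function(path, caller_id, organism = NA_character_,
                      coverage = NA_real_) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- v@fix
  n_meta <- length(v@meta)
  if (nrow(fix) == 0)
    return(sv_callset(caller_id = caller_id, organism = organism,
                      coverage = coverage))
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("malformed VCF '", path, "': non-numeric POS at line ",
         n_meta + 1 + bad)
  }
  info <- fix[, "INFO"]
  alt <- fix[, "ALT"]
  svtype <- info_field(info, "SVTYPE")
  sym <- is.na(svtype) & grepl("^<[A-Z]+", alt)
  svtype[sym] <- sub("^<([A-Z]+).*", "\\1", alt[sym])
  svlen_raw <- info_field(info, "SVLEN")
  end_raw <- suppressWarnings(as.numeric(info_field(info, "END")))

  # split multi-allelic records: one event per ALT (SVLEN may be per-ALT)
  alts <- strsplit(ifelse(is.na(alt), ".", alt), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_along(pos), n_alt)
  which_alt <- sequence(n_alt)
  svlens <- strsplit(ifelse(is.na(svlen_raw), "", svlen_raw), ",", fixed = TRUE)
  svlen <- vapply(seq_along(idx), function(k) {
    sl <- svlens[[idx[k]]]
    if (length(sl) == 0) return(NA_real_)
    j <- if (length(sl) >= which_alt[k]) which_alt[k] else 1L
    suppressWarnings(as.numeric(sl[j]))
  }, numeric(1))
  svlen <- abs(svlen)

  rec <- data.frame(
    chrom = fix[idx, "CHROM"], pos = pos[idx], end = end_raw[idx],
    svtype = svtype[idx], svlen = svlen,
    id = fix[idx, "ID"],
    qual = suppressWarnings(as.numeric(fix[idx, "QUAL"])),
    caller = caller_id,
    src_caller = info_field(info, "SRC_CALLER")[idx],
    bin = suppressWarnings(as.integer(info_field(info, "LEN_BIN")[idx])),
    support = suppressWarnings(as.integer(info_field(info, "SUPPORT")[idx])),
    stringsAsFactors = FALSE
  )
  ok_type <- rec$svtype %in% SV_TYPES
  has_span <- !is.na(rec$end) | !is.na(rec$svlen)
  keep <- ok_type & has_span & !is.na(rec$svtype)
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message(sprintf("parse_vcf: skipped %d record(s) in '%s' (unknown SVTYPE or no SVLEN/END)",
                    n_skip, path))
  rec <- rec[keep, , drop = FALSE]
  # coordinates win for spanning types; SVLEN wins for insertions
  span <- rec$svtype != "INS"
  conflict <- span & !is.na(rec$end) & !is.na(rec$svlen) &
    rec$svlen != (rec$end - rec$pos)
  if (any(conflict))
    message(sprintf("parse_vcf: %d record(s) with SVLEN != END-POS; END kept",
                    sum(conflict)))
  rec$svlen[span & !is.na(rec$end)] <- NA_real_
  sv_callset(rec, caller_id = caller_id, organism = organism,
             coverage = coverage)
}

#' Write a call set to a VCF file
#'
#' Emits valid VCF 4.2 with `SVTYPE`, `SVLEN` and `END` in INFO (plus
#' `SRC_CALLER`, `LEN_BIN` and `SUPPORT` provenance keys where present),
#' symbolic ALT alleles, and records in the call set's sorted order.
#' Deletions are written with negative `SVLEN`, per VCF convention;
#' lengths are stored internally as magnitudes.
#'
#' @param calls An [sv_callset()].
#' @param path Output path for the (uncompressed) VCF text.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  stopifnot(inherits(calls, "sv_callset"))
  rec <- calls$records
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=svconsensus-%s", as.character(packageVersion("svconsensus"))),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant; negative for deletions\">",
    "##INFO=<ID=SRC_CALLER,Number=1,Type=String,Description=\"Caller the consensus record was taken from\">",
    "##INFO=<ID=LEN_BIN,Number=1,Type=Integer,Description=\"Length-bin index the record was routed through\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of distinct callers supporting the record\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(rec)) {
    svlen_out <- ifelse(rec$svtype == "DEL", -rec$svlen, rec$svlen)
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", rec$svtype,
                    as.integer(rec$end), as.integer(svlen_out))
    extra <- function(key, val) ifelse(is.na(val), "",
                                       sprintf(";%s=%s", key, as.character(val)))
    info <- paste0(info, extra("SRC_CALLER", rec$src_caller),
                   extra("LEN_BIN", rec$bin), extra("SUPPORT", rec$support))
    body <- sprintf("%s\t%d\t%s\tN\t<%s>\t%s\tPASS\t%s",
                    rec$chrom, as.integer(rec$pos),
                    ifelse(is.na(rec$id), ".", rec$id),
                    rec$svtype,
                    ifelse(is.na(rec$qual), ".",
                           formatC(rec$qual, format = "g", digits = 6)),
                    info)
  }
  ok <- tryCatch({ writeLines(c(hdr, body), path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write VCF to: ", path)
  invisible(path)
}

#' Drop sub-threshold events
#'
#' Events shorter than 50 bp are not structural variants by the field's
#' definition; truth sets and call sets alike are pre-filtered with this
#' minimum before any training or benchmarking. The cut is strict below
#' the threshold: a 50 bp event is retained.
#'
#' @param calls An [sv_callset()].
#' @param min_len Minimum event length in bp (default 50).
#' @return The filtered [sv_callset()].
#' @export
filter_min_length <- function(calls, min_len = 50) {
  stopifnot(inherits(calls, "sv_callset"))
  calls$records <- calls$records[calls$records$svlen >= min_len, , drop = FALSE]
  rownames(calls$records) <- NULL
  calls
}

#' Load high-confidence regions from a BED file
#'
#' Reads BED intervals (0-based half-open on disk) into a normalized
#' `GRanges` (1-based, per-chromosome intervals merged), for use with
#' [filter_regions()].
#'
#' @param path Path to a BED file.
#' @return A reduced `GRanges` object.
#' @export
read_region_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(gr)
}

#' Restrict a call set to high-confidence regions
#'
#' Benchmarking truth sets are only complete inside their high-confidence
#' regions, so calls are restricted to them before comparison. The
#' default rule requires the whole event to lie inside one interval (the
#' usual convention for high-confidence benchmarking); `rule = "overlap"`
#' keeps any event touching an interval.
#'
#' @param calls An [sv_callset()].
#' @param regions A `GRanges` of regions, e.g. from [read_region_bed()],
#'   normalized (merged) per chromosome.
#' @param rule `"containment"` (default) or `"overlap"`.
#' @return The filtered [sv_callset()].
#' @export
filter_regions <- function(calls, regions, rule = c("containment", "overlap")) {
  stopifnot(inherits(calls, "sv_callset"))
  rule <- match.arg(rule)
  rec <- calls$records
  if (nrow(rec) == 0) return(calls)
  miss <- setdiff(unique(rec$chrom),
                  as.character(GenomicRanges::seqnames(regions)))
  if (length(miss))
    warning("chromosomes absent from region set: ",
            paste(miss, collapse = ", "))
  gr <- GenomicRanges::GRanges(rec$chrom,
                               IRanges::IRanges(rec$pos, rec$end))
  # seqlevel-union warnings are redundant with the explicit check above
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    gr, regions, type = if (rule == "containment") "within" else "any"))
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  calls$records <- rec[keep, , drop = FALSE]
  rownames(calls$records) <- NULL
  calls
}
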