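vcf_fixture <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"l\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body), path)
  path
}

test_that("parsing derives coordinates and lengths per SV type", {
  p <- vcf_fixture(c(
    "chr19\t100\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=300",
    "chr19\t500\t.\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=75"))
  cs <- parse_vcf(p, caller_id = "c")
  del <- cs$records[cs$records$svtype == "DEL", ]
  ins <- cs$records[cs$records$svtype == "INS", ]
  expect_equal(del$pos, 100)
  expect_equal(del$end, 300)
  expect_equal(del$svlen, 200)       # forced by svlen == end - pos
  expect_equal(ins$pos, 500)
  expect_equal(ins$end, 500)         # insertions are points
  expect_equal(ins$svlen, 75)
})

test_that("negative SVLEN is stored as a magnitude and SVTYPE falls back to symbolic ALT", {
  p <- vcf_fixture("chr1\t100\t.\tN\t<DEL>\t.\tPASS\tSVLEN=-150")
  cs <- parse_vcf(p, caller_id = "c")
  expect_equal(cs$records$svtype, "DEL")
  expect_equal(cs$records$svlen, 150)
  expect_equal(cs$records$end, 250)
})

test_that("unusable records are skipped with a message, not fatally", {
  p <- vcf_fixture(c(
    "chr1\t100\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=300",
    "chr1\t200\t.\tN\t<BND>\t.\tPASS\tSVTYPE=BND",
    "chr1\t300\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL"))
  expect_message(cs <- parse_vcf(p, caller_id = "c"), "skipped 2")
  expect_equal(length(cs), 1)
})

test_that("coordinates win over a conflicting SVLEN for deletions", {
  p <- vcf_fixture("chr1\t100\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=300;SVLEN=-999")
  expect_message(cs <- parse_vcf(p, caller_id = "c"), "END kept")
  expect_equal(cs$records$svlen, 200)
})

test_that("multi-allelic records split into one record per ALT", {
  p <- vcf_fixture("chr1\t100\t.\tN\t<INS>,<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=60,90")
  cs <- parse_vcf(p, caller_id = "c")
  expect_equal(length(cs), 2)
  expect_setequal(cs$records$svlen, c(60, 90))
})

test_that("malformed input is a fatal parse error naming the line", {
  expect_error(parse_vcf(tempfile(), "c"), "cannot read")
  p <- vcf_fixture("chr1\tnotanumber\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=300")
  expect_error(parse_vcf(p, "c"), "line 6")
})

test_that("write/parse round-trips a call set exactly", {
  set.seed(11)
  cs <- sv_callset(random_records(100), caller_id = "rt", organism = "human",
                   coverage = 30)
  p <- tempfile(fileext = ".vcf")
  write_vcf(cs, p)
  back <- parse_vcf(p, caller_id = "rt", organism = "human", coverage = 30)
  expect_equal(back$records[, c("chrom", "pos", "end", "svtype", "svlen")],
               cs$records[, c("chrom", "pos", "end", "svtype", "svlen")])
  # and the written body is coordinate-sorted (independent re-sort)
  body <- grep("^#", readLines(p), invert = TRUE, value = TRUE)
  chrom <- sub("\t.*", "", body)
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2))
  expect_equal(order(chrom, pos, method = "radix"), seq_along(body))
})

test_that("an empty call set writes a header-only VCF", {
  p <- tempfile(fileext = ".vcf")
  write_vcf(sv_callset(caller_id = "e"), p)
  expect_true(all(startsWith(readLines(p), "#")))
  expect_equal(length(parse_vcf(p, "e")), 0)
})

test_that("minimum-length filter is strict below the threshold", {
  cs <- del_callset(pos = c(100, 300, 500), end = c(149, 350, 551))
  kept <- filter_min_length(cs)$records$svlen
  expect_setequal(kept, c(50, 51))               # a 50 bp event is an SV
  expect_equal(length(filter_min_length(sv_callset(caller_id = "e"))), 0)
  expect_equal(filter_min_length(cs, 0)$records, cs$records)
  # idempotence
  expect_equal(filter_min_length(filter_min_length(cs))$records,
               filter_min_length(cs)$records)
})

test_that("region filtering honors containment and overlap rules", {
  regions <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 200)))
  cs <- del_callset(pos = 100, end = 300)
  expect_equal(length(filter_regions(cs, regions)), 0)
  expect_equal(length(filter_regions(cs, regions, rule = "overlap")), 1)
  big <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  expect_equal(length(filter_regions(cs, big)), 1)
})

test_that("region filtering warns about chromosomes absent from the BED", {
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  cs <- del_callset(pos = 10, end = 80, chrom = "chrX")
  expect_warning(out <- filter_regions(cs, regions), "chrX")
  expect_equal(length(out), 0)
})

test_that("containment filtering matches a brute-force oracle on random input", {
  set.seed(5)
  cs <- sv_callset(random_records(50, max_pos = 5e4, max_len = 500),
                   caller_id = "r")
  starts <- sort(sample.int(5e4, 8))
  regions <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), 8, TRUE),
    IRanges::IRanges(starts, starts + sample.int(2000, 8))))
  got <- filter_regions(cs, regions)$records
  want <- cs$records[oracle_contained(cs$records, regions), ]
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("BED round-trip through read_region_bed merges intervals", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50\t200", "chr2\t10\t20"), p)
  gr <- read_region_bed(p)
  expect_equal(length(gr), 2)
  expect_equal(GenomicRanges::start(gr), c(1, 11))   # BED is 0-based
  expect_equal(GenomicRanges::end(gr), c(200, 20))
})

test_that("length filter commutes with region filter", {
  set.seed(6)
  cs <- sv_callset(random_records(60, max_pos = 5e4, min_len = 20,
                                  max_len = 400), caller_id = "r")
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3e4))
  suppressWarnings({
    a <- filter_regions(filter_min_length(cs), regions)
    b <- filter_min_length(filter_regions(cs, regions))
  })
  expect_equal(a$records, b$records)
})
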