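# Shared fixtures and independent oracles for the test suite.

# Quick deletion call set from parallel coordinate vectors.
del_callset <- function(pos, end, chrom = "chr1", caller = "x", ...) {
  sv_callset(sv_records(chrom = chrom, pos = pos, end = end,
                        svtype = "DEL", caller = caller),
             caller_id = caller, ...)
}

# Random deletion records on a couple of chromosomes; lengths >= 50.
random_records <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                           min_len = 50, max_len = 2000) {
  pos <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  sv_records(chrom = sample(chroms, n, replace = TRUE), pos = pos,
             end = pos + len, svtype = "DEL")
}

random_callset <- function(n, caller = "x", ...) {
  sv_callset(random_records(n, ...), caller_id = caller)
}

# Full boolean match matrix (truth rows x inferred columns), built with
# whole-matrix outer products -- a different code path from the
# package's windowed scan.
oracle_match_matrix <- function(inferred, truth, tau) {
  inf <- inferred$records
  tru <- truth$records
  outer(tru$chrom, inf$chrom, "==") &
    outer(tru$svtype, inf$svtype, "==") &
    abs(outer(tru$pos, inf$pos, "-")) <= tau &
    abs(outer(tru$end, inf$end, "-")) <= tau
}

# Independent greedy matching oracle: walk truth rows in sorted order,
# pairing each with the first unused inferred column of the matrix.
oracle_greedy_tp <- function(inferred, truth, tau) {
  if (length(inferred) == 0 || length(truth) == 0) return(0L)
  M <- oracle_match_matrix(inferred, truth, tau)
  used <- logical(ncol(M))
  tp <- 0L
  for (t in seq_len(nrow(M))) {
    cand <- which(M[t, ] & !used)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

# Maximum bipartite matching TP count (upper bound for any one-to-one
# pairing), via igraph.
oracle_max_matching_tp <- function(inferred, truth, tau) {
  if (length(inferred) == 0 || length(truth) == 0) return(0L)
  M <- oracle_match_matrix(inferred, truth, tau)
  edges <- which(M, arr.ind = TRUE)
  if (nrow(edges) == 0) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nrow(M)), rep(TRUE, ncol(M))),
    edges = as.vector(t(cbind(edges[, 1], nrow(M) + edges[, 2]))))
  igraph::max_bipartite_match(g)$matching_size
}

# Brute-force region containment: is [pos, end] (1-based) fully inside
# some interval of the region set?
oracle_contained <- function(rec, regions) {
  starts <- GenomicRanges::start(regions)
  ends <- GenomicRanges::end(regions)
  chr <- as.character(GenomicRanges::seqnames(regions))
  vapply(seq_len(nrow(rec)), function(i)
    any(chr == rec$chrom[i] & starts <= rec$pos[i] & rec$end[i] <= ends),
    logical(1))
}

# All-pairs check that no two retained records of the same chrom+type
# are within tau on both breakpoints.
any_tau_duplicates <- function(rec, tau) {
  if (nrow(rec) < 2) return(FALSE)
  for (i in seq_len(nrow(rec) - 1))
    for (j in seq(i + 1, nrow(rec)))
      if (rec$chrom[i] == rec$chrom[j] && rec$svtype[i] == rec$svtype[j] &&
          abs(rec$pos[i] - rec$pos[j]) <= tau &&
          abs(rec$end[i] - rec$end[j]) <= tau)
        return(TRUE)
  FALSE
}

# Every record of `a` has a tau-equivalent record in `b`.
tau_subset <- function(a, b, tau) {
  rec_a <- a$records
  rec_b <- b$records
  if (nrow(rec_a) == 0) return(TRUE)
  if (nrow(rec_b) == 0) return(FALSE)
  all(vapply(seq_len(nrow(rec_a)), function(i)
    any(rec_b$chrom == rec_a$chrom[i] & rec_b$svtype == rec_a$svtype[i] &
        abs(rec_b$pos - rec_a$pos[i]) <= tau &
        abs(rec_b$end - rec_a$end[i]) <= tau), logical(1)))
}

# Paired-end SAM fixture: n_pairs read pairs (+ optional unpaired reads
# and supplementary records), written to a temp file.
write_sam_fixture <- function(path, n_pairs, n_unpaired = 0,
                              n_supplementary = 0, seed = 1) {
  withr::with_seed(seed, {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             "@SQ\tSN:chr1\tLN:1000000",
             "@RG\tID:rg1\tSM:sample1")
    qn <- sprintf("read%06d", seq_len(n_pairs))
    pos1 <- sample.int(9e5, n_pairs, replace = TRUE)
    rec <- function(q, flag, pos)
      sprintf("%s\t%d\tchr1\t%d\t60\t100M\t=\t%d\t200\t%s\t%s", q, flag,
              pos, pos + 100, strrep("A", 10), strrep("I", 10))
    body <- c(rbind(rec(qn, 99L, pos1), rec(qn, 147L, pos1 + 100)))
    if (n_unpaired > 0) {
      uq <- sprintf("single%04d", seq_len(n_unpaired))
      body <- c(body, sprintf("%s\t0\tchr1\t%d\t60\t100M\t*\t0\t0\t%s\t%s",
                              uq, sample.int(9e5, n_unpaired, TRUE),
                              strrep("A", 10), strrep("I", 10)))
    }
    if (n_supplementary > 0) {
      sq <- sample(qn, n_supplementary)
      body <- c(body, rec(sq, 2147L, sample.int(9e5, n_supplementary, TRUE)))
    }
    writeLines(c(hdr, body), path)
  })
  path
}

sam_body <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "@")]
}

sam_qnames <- function(path) sub("\t.*$", "", sam_body(path))

# Paired-flag records whose read name appears only once = stranded mates.
count_singleton_mates <- function(path) {
  body <- sam_body(path)
  qn <- sub("\t.*$", "", body)
  flag <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2))
  paired <- bitwAnd(flag, 1L) == 1L
  sum(table(qn[paired]) == 1)
}
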