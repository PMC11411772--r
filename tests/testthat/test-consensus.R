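test_that("dedupe collapses tau-duplicates and keeps well-separated records", {
  cs <- del_callset(pos = c(100, 100, 150), end = c(300, 300, 350),
                    caller = "d")
  out <- dedupe(cs, tau = 10)
  expect_equal(nrow(out$records), 2)
  expect_setequal(out$records$pos, c(100, 150))    # separation > tau
  expect_equal(dedupe(out, 10)$records, out$records)   # idempotent
})

test_that("dedupe leaves exactly one survivor per jittered event cluster", {
  truth <- generate_truth(n_per_bin = 15, seed = 61)   # 60 events
  dups <- do.call(rbind, lapply(1:4, function(k) {
    r <- truth$records
    withr::with_seed(60 + k, {
      r$pos <- r$pos + sample(-50:50, nrow(r), TRUE)
      r$end <- pmax(r$pos + 50, r$end + sample(-50:50, nrow(r), TRUE))
    })
    r$svlen <- r$end - r$pos
    r
  }))
  cs <- sv_callset(dups, caller_id = "jit")
  out <- dedupe(cs, tau = 100)
  expect_equal(nrow(out$records), length(truth))
  expect_false(any_tau_duplicates(out$records, 100))
})

test_that("no retained pair violates the separation predicate on random input", {
  set.seed(67)
  for (rep in 1:5) {
    cs <- random_callset(60, max_pos = 2e4)
    out <- dedupe(cs, tau = 150)
    expect_false(any_tau_duplicates(out$records, 150))
    expect_true(tau_subset(cs, out, 150))   # nothing lost beyond tau
  }
})

routing_fixture <- function() {
  # callerA: one bin-0 call and one bin-1 call; callerB: bin-1 call
  a <- del_callset(pos = c(1000, 5000), end = c(1080, 5150), caller = "callerA")
  b <- del_callset(pos = 9000, end = 9150, caller = "callerB")
  bw <- list(
    data.frame(caller = c("callerA", "callerB"), rank = 1:2,
               sensitivity = c(0.9, 0.5), precision = c(0.9, 0.5),
               fscore = c(0.9, 0.5), n_tp = 9, n_fp = 1, n_fn = 1),
    data.frame(caller = c("callerB", "callerA"), rank = 1:2,
               sensitivity = c(0.9, 0.5), precision = c(0.9, 0.5),
               fscore = c(0.9, 0.5), n_tp = 9, n_fp = 1, n_fn = 1),
    data.frame(caller = "callerA", rank = 1L, sensitivity = 0.5,
               precision = 0.5, fscore = 0.5, n_tp = 5, n_fp = 5, n_fn = 5),
    data.frame(caller = "callerA", rank = 1L, sensitivity = 0.5,
               precision = 0.5, fscore = 0.5, n_tp = 5, n_fp = 5, n_fn = 5))
  list(profile = caller_profile("human", 30, "DEL", length_bins(), bw),
       callsets = list(a, b))
}

test_that("standard merge routes records through their bin's winner with provenance", {
  fx <- routing_fixture()
  out <- merge_by_profile(fx$profile, fx$callsets)
  rec <- out$records
  expect_equal(out$caller_id, "consensus")
  # callerA's 150 bp call (bin 1) is discarded: callerB wins bin 1
  expect_equal(nrow(rec), 2)
  expect_equal(rec$src_caller[rec$pos == 1000], "callerA")
  expect_equal(rec$bin[rec$pos == 1000], 0L)
  expect_equal(rec$src_caller[rec$pos == 9000], "callerB")
  expect_equal(rec$bin[rec$pos == 9000], 1L)
  expect_false(5000 %in% rec$pos)
})

test_that("merge fails loudly when a bin winner's call set is missing", {
  fx <- routing_fixture()
  expect_error(merge_by_profile(fx$profile, fx$callsets[1]), "callerB")
})

test_that("a single-source profile reduces merging to dedupe", {
  truth <- generate_truth(n_per_bin = 10, seed = 71)
  a <- corrupt(truth, error_model(rep(0.9, 4), fp_rate = 0.1, jitter_sd = 5,
                                  seed = 3), caller_id = "callerA")
  bw <- lapply(1:4, function(b)
    data.frame(caller = "callerA", rank = 1L, sensitivity = 0.9,
               precision = 0.9, fscore = 0.9, n_tp = 9, n_fp = 1, n_fn = 1))
  prof <- caller_profile("synthetic", 30, "DEL", length_bins(), bw)
  out <- merge_by_profile(prof, list(a))
  ded <- dedupe(a, 100)
  cols <- c("chrom", "pos", "end", "svtype", "svlen")
  expect_equal(out$records[, cols], ded$records[, cols])
})

test_that("recall mode is the deduplicated union and dominates input recall", {
  a <- del_callset(pos = c(1000, 3000), end = c(1100, 3200), caller = "a")
  b <- del_callset(pos = c(9000, 12000), end = c(9100, 12300), caller = "b")
  out <- optimize_recall(list(a, b))
  expect_equal(nrow(out$records), 4)          # disjoint inputs: sizes add
  within <- del_callset(pos = c(1005, 3004), end = c(1102, 3203),
                        caller = "sub")       # a within-tau subset of a
  out2 <- optimize_recall(list(within, a))
  expect_equal(nrow(out2$records), 2)
  truth <- del_callset(pos = c(1000, 9000), end = c(1100, 9100),
                       caller = "t")
  r_union <- compute_metrics(match_callset(out, truth, 100))$sensitivity
  for (cs in list(a, b))
    expect_gte(r_union,
               compute_metrics(match_callset(cs, truth, 100))$sensitivity)
})

test_that("precision mode keeps only multi-caller-supported events", {
  shared_a <- del_callset(pos = c(1000, 5000), end = c(1100, 5500),
                          caller = "a")
  shared_b <- del_callset(pos = c(1010, 20000), end = c(1090, 20400),
                          caller = "b")
  out <- optimize_precision(list(shared_a, shared_b),
                            merge_config(mode = "precision"))
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$pos, 1000)          # representative: sort order
  expect_equal(out$records$support, 2L)
  expect_error(optimize_precision(list(shared_a),
                                  merge_config(mode = "precision")),
               "min_support")
})

test_that("min_support = 1 degenerates precision mode to recall mode", {
  set.seed(73)
  sets <- lapply(c("a", "b", "c"), function(id)
    random_callset(25, caller = id, max_pos = 5e5))
  cfg1 <- merge_config(mode = "precision", min_support = 1)
  p1 <- optimize_precision(sets, cfg1)
  r <- optimize_recall(sets, merge_config(mode = "recall"))
  cols <- c("chrom", "pos", "end", "svtype", "svlen")
  expect_equal(p1$records[, cols], r$records[, cols])
})

test_that("support-filtered outputs form a containment chain under tau-equivalence", {
  set.seed(79)
  truth <- generate_truth(n_per_bin = 20, seed = 79)
  sets <- lapply(1:3, function(i)
    corrupt(truth, error_model(rep(0.7, 4), fp_rate = 0.3, jitter_sd = 20,
                               seed = 80 + i),
            caller_id = paste0("c", i)))
  tau <- 100
  rec <- optimize_recall(sets, merge_config(mode = "recall",
                                            dedupe_tau = tau))
  p2 <- optimize_precision(sets, merge_config(mode = "precision",
                                              min_support = 2,
                                              dedupe_tau = tau))
  p3 <- optimize_precision(sets, merge_config(mode = "precision",
                                              min_support = 3,
                                              dedupe_tau = tau))
  expect_true(tau_subset(p3, p2, tau))
  expect_true(tau_subset(p2, rec, tau))
  expect_lte(nrow(rec$records), sum(vapply(sets, length, numeric(1))))
})

test_that("independent false positives are filtered by agreement, raising precision", {
  truth <- generate_truth(n_per_bin = 100, seed = 83)
  sets <- lapply(1:3, function(i)
    corrupt(truth, error_model(rep(0.8, 4), fp_rate = 1.0, jitter_sd = 10,
                               seed = 90 + i),
            caller_id = paste0("c", i)))
  prec_in <- vapply(sets, function(cs)
    compute_metrics(match_callset(cs, truth, 100))$precision, numeric(1))
  rec_in <- vapply(sets, function(cs)
    compute_metrics(match_callset(cs, truth, 100))$sensitivity, numeric(1))
  out <- optimize_precision(sets, merge_config(mode = "precision"))
  uni <- optimize_recall(sets, merge_config(mode = "recall"))
  m_out <- compute_metrics(match_callset(out, truth, 100))
  m_uni <- compute_metrics(match_callset(uni, truth, 100))
  expect_gt(m_out$precision, max(prec_in))
  expect_lt(m_out$sensitivity, m_uni$sensitivity)
})
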