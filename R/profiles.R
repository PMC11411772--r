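#' Length-bin partition for SV stratification
#'
#' Caller accuracy depends strongly on event length, so training and
#' reporting are stratified into half-open length bins
#' `[e1, e2), [e2, e3), ..., [ek, Inf)`. The defaults separate short
#' (50-100 bp), medium (100-500, 500-1000 bp) and long (1000+ bp)
#' events. The boundary value belongs to the upper bin: a 100 bp event
#' is "medium".
#'
#' @param edges Strictly ascending bin edges in bp; the first edge must
#'   be >= 50 (shorter events are not structural variants).
#' @return An object of class `length_bins`.
#' @export
length_bins <- function(edges = c(50, 100, 500, 1000)) {
  edges <- as.numeric(edges)
  stopifnot(length(edges) >= 1, !is.unsorted(edges, strictly = TRUE),
            edges[1] >= 50)
  structure(list(edges = edges), class = "length_bins")
}

#' @export
print.length_bins <- function(x, ...) {
  e <- x$edges
  lab <- c(sprintf("[%g,%g)", e[-length(e)], e[-1]),
           sprintf("[%g,Inf)", e[length(e)]))
  cat("length_bins:", paste(lab, collapse = " "), "\n")
  invisible(x)
}

n_bins <- function(bins) length(bins$edges)

bin_labels <- function(bins) {
  e <- bins$edges
  c(sprintf("[%g,%g)", e[-length(e)], e[-1]), sprintf("[%g,Inf)", e[length(e)]))
}

#' Map event lengths to bin indices
#'
#' @param svlen Event lengths in bp; all must be >= the first bin edge.
#' @param bins A [length_bins()] partition.
#' @return 0-based bin indices, one per length.
#' @export
assign_bin <- function(svlen, bins = length_bins()) {
  if (length(svlen) == 0) return(integer(0))
  if (any(svlen < bins$edges[1]))
    stop("svlen below the first bin edge (", bins$edges[1],
         " bp); filter the call set first")
  findInterval(svlen, bins$edges) - 1L
}

#' Coverage tiers
#'
#' Sequencing depth changes which caller wins, so trained profiles are
#' keyed by coverage tier as well as organism. The default tiers
#' separate the regimes of interest: ultra-low (<0.5x), low (0.5-8x),
#' mid (8-20x) and high (>=20x) depth. Edges are configurable.
#'
#' @param edges Ascending inner tier edges in x.
#' @param labels Tier labels, one more than `edges`.
#' @return A `data.frame` with columns `label`, `lo`, `hi`.
#' @export
coverage_tiers <- function(edges = c(0.5, 8, 20),
                           labels = c("ultra-low", "low", "mid", "high")) {
  stopifnot(length(labels) == length(edges) + 1,
            !is.unsorted(edges, strictly = TRUE))
  data.frame(label = labels, lo = c(0, edges), hi = c(edges, Inf),
             stringsAsFactors = FALSE)
}

#' Find the tier containing a coverage value
#' @param coverage Mean depth in x.
#' @param tiers A tier table from [coverage_tiers()].
#' @return One row of `tiers`.
#' @export
coverage_tier_of <- function(coverage, tiers = coverage_tiers()) {
  i <- findInterval(coverage, c(tiers$lo[1], tiers$hi))
  if (i < 1 || i > nrow(tiers)) stop("coverage outside all tiers: ", coverage)
  tiers[i, , drop = FALSE]
}

#' Construct a trained caller profile
#'
#' The artifact produced by training: for each length bin, the input
#' callers ranked by their training performance, with the full metric
#' rows retained for audit. Profiles are keyed by organism, coverage
#' tier and SV type; deletions and insertions are trained separately.
#'
#' @param organism Organism tag.
#' @param coverage Training mean depth in x.
#' @param svtype SV type the profile applies to.
#' @param bins The [length_bins()] used in training.
#' @param bin_winners A list with one `data.frame` per bin, rows ranked
#'   callers (columns `caller`, `rank`, `sensitivity`, `precision`,
#'   `fscore`, `n_tp`, `n_fp`, `n_fn`).
#' @param tau Breakpoint tolerance used in training (bp).
#' @param metric Ranking metric used.
#' @param tiers Tier table used to label the coverage.
#' @param metadata List of free-form training metadata (dataset name,
#'   date, untrained bins).
#' @return An object of class `caller_profile`.
#' @export
caller_profile <- function(organism, coverage, svtype, bins, bin_winners,
                           tau = 100, metric = "fscore",
                           tiers = coverage_tiers(), metadata = list()) {
  stopifnot(length(bin_winners) == n_bins(bins))
  for (b in seq_along(bin_winners)) {
    w <- bin_winners[[b]]
    if (!is.data.frame(w) || nrow(w) < 1)
      stop("profile bin ", b - 1L, " has no ranked winner")
  }
  tier <- coverage_tier_of(coverage, tiers)
  if (is.null(metadata$date)) metadata$date <- format(Sys.Date())
  structure(list(organism = organism, coverage = coverage,
                 tier = list(label = tier$label, lo = tier$lo, hi = tier$hi),
                 svtype = svtype, tau = tau, metric = metric,
                 bins = bins, bin_winners = bin_winners,
                 metadata = metadata),
            class = "caller_profile")
}

#' @export
print.caller_profile <- function(x, ...) {
  cat(sprintf("caller_profile: %s / %s tier (%gx) / %s, tau = %g bp, by %s\n",
              x$organism, x$tier$label, x$coverage, x$svtype, x$tau, x$metric))
  labs <- bin_labels(x$bins)
  for (b in seq_along(x$bin_winners)) {
    w <- x$bin_winners[[b]][1, ]
    cat(sprintf("  bin %d %-12s -> %s (F = %.3f)\n", b - 1L, labs[b],
                w$caller, w$fscore))
  }
  invisible(x)
}

#' Winning caller per bin
#' @param profile A [caller_profile()].
#' @param rank Which rank to extract (1 = winner).
#' @return Character vector of caller ids, one per bin.
#' @export
bin_winners <- function(profile, rank = 1) {
  vapply(profile$bin_winners, function(w)
    if (nrow(w) >= rank) w$caller[rank] else w$caller[nrow(w)], character(1))
}

#' Select the closest trained profile for a sample
#'
#' Discovery mode needs a profile even when the exact training
#' conditions were never seen. Resolution is: exact organism with a
#' tier containing the sample's coverage; else the same organism's
#' nearest tier by depth midpoint; else the designated default
#' organism's nearest profile (with a warning). Organism closeness is
#' deliberately just tag equality -- no phylogenetic guessing.
#'
#' @param organism Sample organism tag.
#' @param coverage Sample mean depth in x.
#' @param store A list of [caller_profile()] objects.
#' @param default_organism Organism tag to fall back on (default: the
#'   first profile's organism).
#' @return A [caller_profile()].
#' @export
resolve_profile <- function(organism, coverage, store,
                            default_organism = NULL) {
  if (length(store) == 0) stop("profile store is empty")
  orgs <- vapply(store, `[[`, character(1), "organism")
  tier_mid <- vapply(store, function(p) {
    hi <- if (is.finite(p$tier$hi)) p$tier$hi else 2 * max(p$coverage, p$tier$lo)
    (p$tier$lo + hi) / 2
  }, numeric(1))
  pick_nearest <- function(idx) idx[which.min(abs(tier_mid[idx] - coverage))]
  same <- which(orgs == organism)
  if (length(same)) {
    containing <- same[vapply(store[same], function(p)
      coverage >= p$tier$lo && coverage < p$tier$hi, logical(1))]
    if (length(containing)) {
      i <- containing[1]
      message(sprintf("resolve_profile: exact match (%s, %s tier)",
                      organism, store[[i]]$tier$label))
    } else {
      i <- pick_nearest(same)
      message(sprintf("resolve_profile: organism %s, nearest tier %s",
                      organism, store[[i]]$tier$label))
    }
    return(store[[i]])
  }
  if (is.null(default_organism)) default_organism <- orgs[1]
  def <- which(orgs == default_organism)
  if (!length(def)) def <- seq_along(store)
  i <- pick_nearest(def)
  warning(sprintf("no profile for organism '%s'; using default '%s' (%s tier)",
                  organism, store[[i]]$organism, store[[i]]$tier$label))
  store[[i]]
}

#' Save a trained profile to a YAML file
#'
#' Profiles are serialized as human-readable YAML so trained artifacts
#' can be inspected, versioned and shipped. [load_profile()] restores
#' them losslessly.
#'
#' @param profile A [caller_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_profile <- function(profile, path) {
  stopifnot(inherits(profile, "caller_profile"))
  doc <- list(
    organism = profile$organism,
    coverage = profile$coverage,
    tier = profile$tier,
    svtype = profile$svtype,
    tau = profile$tau,
    metric = profile$metric,
    bin_edges = profile$bins$edges,
    bins = lapply(seq_along(profile$bin_winners), function(b) list(
      bin = b - 1L,
      winners = lapply(seq_len(nrow(profile$bin_winners[[b]])), function(r)
        as.list(profile$bin_winners[[b]][r, , drop = FALSE]))
    )),
    metadata = profile$metadata
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Load a trained profile from a YAML file
#'
#' @param path Path to a file written by [save_profile()].
#' @return A [caller_profile()].
#' @export
load_profile <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("organism", "coverage", "svtype", "tau", "metric",
                  "bin_edges", "bins"))
    if (is.null(doc[[field]]))
      stop("profile file '", path, "' is missing field: ", field)
  bins <- length_bins(doc$bin_edges)
  present <- vapply(doc$bins, function(x) as.integer(x$bin), integer(1))
  winners <- vector("list", n_bins(bins))
  for (b in seq_len(n_bins(bins)) - 1L) {
    j <- match(b, present)
    if (is.na(j))
      stop("profile file '", path, "' is missing bin ", b)
    w <- doc$bins[[j]]$winners
    if (length(w) == 0)
      stop("profile file '", path, "' has no winners for bin ", b)
    winners[[b + 1L]] <- do.call(rbind, lapply(w, function(x)
      as.data.frame(x, stringsAsFactors = FALSE)))
  }
  prof <- caller_profile(organism = doc$organism, coverage = doc$coverage,
                         svtype = doc$svtype, bins = bins,
                         bin_winners = winners,
                         tau = doc$tau, metric = doc$metric,
                         metadata = if (is.null(doc$metadata)) list()
                                    else doc$metadata)
  if (!is.null(doc$tier)) prof$tier <- doc$tier   # keep custom tier edges
  prof
}
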