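#' Majority triplet topology
#'
#' Most frequent resolved class; ties are broken lexicographically
#' (RES_AB < RES_AC < RES_BC) and flagged.
#'
#' @param counts Named counts for `RES_AB`, `RES_AC`, `RES_BC`, or a
#'   `triplet_calls` data.frame.
#' @return List with `topology` and logical `tie`.
#' @export
msc_topology <- function(counts) {
  cn <- resolved_counts(counts)
  if (sum(cn) == 0L) stop("no decisive gene")
  top <- names(cn)[which.max(cn)]  # which.max takes the first = lexicographic
  list(topology = top, tie = sum(cn == max(cn)) > 1L)
}

resolved_counts <- function(counts) {
  if (inherits(counts, "data.frame")) counts <- call_counts(counts)
  keys <- c("RES_AB", "RES_AC", "RES_BC")
  if (is.null(names(counts))) names(counts) <- keys[seq_along(counts)]
  cn <- stats::setNames(numeric(3L), keys)
  cn[intersect(names(counts), keys)] <- counts[intersect(names(counts), keys)]
  cn
}

#' Coalescent-unit length of the focal internal branch
#'
#' Under the multispecies coalescent the probability that a gene tree
#' matches the species tree at a triplet branch of length T coalescent
#' units (2N generations) is `1 - (2/3) exp(-T)`; inverting the observed
#' majority frequency `c` gives `T = -log((3/2)(1 - c))` for `c > 1/3`.
#'
#' @inheritParams msc_topology
#' @param T_max Cap applied when the majority class is unanimous
#'   (`c = 1` has no finite solution).
#' @return List with `T_hat`, the majority frequency `c_hat`, and logical
#'   `capped`.
#' @export
msc_branch_length <- function(counts, T_max = 10) {
  cn <- resolved_counts(counts)
  n <- sum(cn)
  stopifnot(n > 0)
  c_hat <- max(cn) / n
  if (c_hat >= 1) return(list(T_hat = T_max, c_hat = c_hat, capped = TRUE))
  T_hat <- if (c_hat > 1 / 3) -log(1.5 * (1 - c_hat)) else 0
  list(T_hat = T_hat, c_hat = c_hat, capped = FALSE)
}

# log integral over the branch-length prior of the probability of the
# observed topology counts when resolution i is the true one:
#   g_i = Int_0^inf lambda e^(-lambda d) theta^(n_i) ((1-theta)/2)^(m-n_i) dd,
# theta(d) = 1 - (2/3) e^(-d).  Evaluated by Laplace-windowed quadrature on
# the log scale so counts in the tens of thousands stay stable.
log_pp_integral <- function(n_i, m, lambda) {
  # log theta = log1p(-(2/3)e^-d); log((1-theta)/2) = -d - log 3, exact at
  # any d (the direct form underflows once theta rounds to 1)
  logf <- function(d) {
    log(lambda) - lambda * d + n_i * log1p(-(2 / 3) * exp(-d)) +
      (m - n_i) * (-d - log(3))
  }
  opt <- stats::optimize(logf, interval = c(0, 60), maximum = TRUE)
  d0 <- opt$maximum
  M <- max(opt$objective, logf(0))
  if (logf(0) > opt$objective) d0 <- 0
  # integration window: where the integrand is within e^-45 of its peak
  w <- 1
  while (d0 + w < 60 && logf(d0 + w) > M - 45) w <- w * 2
  lo <- d0
  while (lo > 0 && logf(max(lo, 0)) > M - 45) lo <- lo - w / 20
  lo <- max(lo, 0)
  val <- stats::integrate(function(d) exp(logf(d) - M), lower = lo,
                          upper = min(d0 + w, 60), rel.tol = 1e-10,
                          subdivisions = 400L)$value
  M + log(val)
}

#' Local posterior probability of each triplet resolution
#'
#' The local posterior used by coalescent species-tree methods: given the
#' multinomial gene-tree counts, each resolution's marginal likelihood
#' integrates the MSC concordance probability `1 - (2/3)e^(-d)` over an
#' exponential (Yule) prior with rate `lambda` on the internal branch
#' length, and the three are normalised.
#'
#' @inheritParams msc_topology
#' @param lambda Yule prior rate on the internal branch length (default
#'   0.5, the convention of coalescent species-tree software).
#' @return Named probabilities `(pp_AB, pp_AC, pp_BC)` summing to 1.
#' @export
local_pp <- function(counts, lambda = 0.5) {
  cn <- resolved_counts(counts)
  m <- sum(cn)
  stopifnot(m > 0, lambda > 0)
  lg <- vapply(cn, log_pp_integral, numeric(1), m = m, lambda = lambda)
  lg <- lg - max(lg)
  pp <- exp(lg) / sum(exp(lg))
  stats::setNames(pp, c("pp_AB", "pp_AC", "pp_BC"))
}

#' Gene-tree bootstrap support for the triplet topology
#'
#' Resamples classified genes with replacement and records which resolution
#' wins the majority in each pseudo-replicate; reported as percentages.
#'
#' @param calls A `triplet_calls` data.frame (or named resolved counts,
#'   which are expanded into pseudo-calls).
#' @param n_reps Number of pseudo-replicates (default 100).
#' @param seed RNG seed.
#' @return Named percentages `bp_AB`, `bp_BC`, `bp_AC` over replicates.
#' @export
genetree_bootstrap <- function(calls, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  cats <- if (inherits(calls, "data.frame")) calls$category
          else rep(names(resolved_counts(calls)), resolved_counts(calls))
  cats <- cats[cats %in% c("RES_AB", "RES_AC", "RES_BC")]
  stopifnot(length(cats) >= 1L)
  set.seed(seed)
  wins <- integer(3L)
  names(wins) <- c("RES_AB", "RES_AC", "RES_BC")
  for (r in seq_len(n_reps)) {
    cn <- table(factor(sample(cats, length(cats), replace = TRUE),
                       levels = names(wins)))
    top <- msc_topology(as.integer(cn))$topology
    wins[top] <- wins[top] + 1L
  }
  stats::setNames(100 * wins / n_reps, c("bp_AB", "bp_AC", "bp_BC"))
}

#' Triplet species-tree summary under the multispecies coalescent
#'
#' Bundles the majority topology, the coalescent-unit internal branch
#' length, the local posterior probabilities, and the gene-tree bootstrap.
#'
#' @inheritParams genetree_bootstrap
#' @param lambda Prior rate for [local_pp()].
#' @param T_max Cap for [msc_branch_length()].
#' @return List of class `triplet_species_tree`.
#' @export
triplet_species_tree <- function(calls, lambda = 0.5, n_reps = 100L,
                                 seed = 1L, T_max = 10) {
  cn <- resolved_counts(calls)
  top <- msc_topology(cn)
  bl <- msc_branch_length(cn, T_max = T_max)
  structure(list(topology = top$topology, tie = top$tie,
                 T_hat = bl$T_hat, c_hat = bl$c_hat, capped = bl$capped,
                 local_pp = local_pp(cn, lambda = lambda),
                 bootstrap_bp = genetree_bootstrap(calls, n_reps = n_reps,
                                                   seed = seed),
                 n_decisive = sum(cn)),
            class = "triplet_species_tree")
}

#' @export
print.triplet_species_tree <- function(x, ...) {
  cat("Triplet species tree:", x$topology,
      if (x$tie) "(tie, lexicographic break)" else "", "\n")
  cat(sprintf("  internal branch %.4f coalescent units%s (c_hat = %.4f, n = %d)\n",
              x$T_hat, if (x$capped) " [capped]" else "", x$c_hat,
              x$n_decisive))
  cat("  local PP:",
      paste(sprintf("%s %.3f", names(x$local_pp), x$local_pp), collapse = ", "),
      "\n")
  cat("  gene-tree bootstrap:",
      paste(sprintf("%s %.1f%%", names(x$bootstrap_bp), x$bootstrap_bp),
            collapse = ", "), "\n")
  invisible(x)
}
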