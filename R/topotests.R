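NUC <- c("A", "C", "G", "T")

#' Nucleotide substitution models for the likelihood engine
#'
#' Time-reversible models with branch lengths in expected substitutions per
#' site: JC69 (equal rates/frequencies), K80 (transition/transversion ratio
#' `kappa`), HKY85 (`kappa` plus arbitrary base frequencies). An optional
#' discrete-gamma rate heterogeneity with `ncat` equal-probability
#' categories (mean rate per category, mean 1 overall) can be attached to
#' any of them.
#'
#' @param kappa Transition/transversion rate ratio.
#' @param pi Base frequencies in A, C, G, T order (must sum to 1).
#' @param gamma_alpha Shape of the gamma rate distribution, or `NULL` for
#'   rate homogeneity.
#' @param ncat Number of discrete gamma categories.
#' @return A `subst_model` object with a spectral decomposition of the rate
#'   matrix, used by [site_loglik()].
#' @export
subst_model <- function(kappa = 1, pi = rep(0.25, 4), gamma_alpha = NULL,
                        ncat = 4L) {
  stopifnot(length(pi) == 4L, abs(sum(pi) - 1) < 1e-8, all(pi > 0), kappa > 0)
  names(pi) <- NUC
  Q <- matrix(1, 4L, 4L, dimnames = list(NUC, NUC))
  Q["A", "G"] <- Q["G", "A"] <- Q["C", "T"] <- Q["T", "C"] <- kappa
  Q <- sweep(Q, 2L, pi, "*")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)          # one expected substitution per unit
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp) # symmetric similar matrix
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  rates <- if (is.null(gamma_alpha)) 1 else {
    # mean rate per equal-probability category (Yang's discrete gamma)
    a <- gamma_alpha
    q <- stats::qgamma(seq_len(ncat - 1L) / ncat, shape = a, rate = a)
    cum <- c(0, stats::pgamma(q, shape = a + 1, rate = a), 1)
    ncat * diff(cum)
  }
  structure(list(kappa = kappa, pi = pi, values = eg$values,
                 right = diag(1 / sp) %*% eg$vectors,
                 left = t(eg$vectors) %*% diag(sp),
                 gamma_alpha = gamma_alpha, rates = rates),
            class = "subst_model")
}

#' @rdname subst_model
#' @export
model_jc69 <- function(gamma_alpha = NULL, ncat = 4L)
  subst_model(1, rep(0.25, 4), gamma_alpha, ncat)

#' @rdname subst_model
#' @export
model_k80 <- function(kappa = 2, gamma_alpha = NULL, ncat = 4L)
  subst_model(kappa, rep(0.25, 4), gamma_alpha, ncat)

#' @rdname subst_model
#' @export
model_hky85 <- function(kappa = 2, pi = rep(0.25, 4), gamma_alpha = NULL,
                        ncat = 4L)
  subst_model(kappa, pi, gamma_alpha, ncat)

pmat <- function(model, t) {
  model$right %*% (exp(model$values * t) * model$left)
}

# fast column maxima for matrices with few rows
colmax <- function(M) {
  do.call(pmax, lapply(seq_len(nrow(M)), function(i) M[i, ]))
}

tip_partials <- function(mat, taxa) {
  S <- ncol(mat)
  out <- vector("list", length(taxa))
  for (i in seq_along(taxa)) {
    L <- matrix(0, 4L, S)
    s <- mat[taxa[i], ]
    for (k in 1:4) L[k, ] <- as.numeric(s == NUC[k])
    L[, !(s %in% NUC)] <- 1     # gap/N: missing data
    out[[i]] <- L
  }
  names(out) <- taxa
  out
}

prune_loglik <- function(phy, tips, model, lengths = phy$edge.length) {
  S <- ncol(tips[[1L]])
  ntip <- length(phy$tip.label)
  eo <- ape::postorder(phy)
  per_cat <- vector("list", length(model$rates))
  for (ci in seq_along(model$rates)) {
    r <- model$rates[ci]
    L <- vector("list", ntip + phy$Nnode)
    logsc <- numeric(S)
    for (i in seq_len(ntip)) L[[i]] <- tips[[phy$tip.label[i]]]
    for (e in eo) {
      par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      contrib <- pmat(model, lengths[e] * r) %*% L[[ch]]
      if (is.null(L[[par]])) L[[par]] <- contrib
      else L[[par]] <- L[[par]] * contrib
      mx <- colmax(L[[par]])             # rescale against underflow
      if (any(mx < 1e-80)) {
        mx <- pmax(mx, 1e-300)
        L[[par]] <- sweep(L[[par]], 2L, mx, "/")
        logsc <- logsc + log(mx)
      }
    }
    root <- phy$edge[eo[length(eo)], 1L]
    lik <- as.vector(model$pi %*% L[[root]])
    per_cat[[ci]] <- log(pmax(lik, 1e-300)) + logsc
  }
  if (length(per_cat) == 1L) return(per_cat[[1L]])
  M <- do.call(rbind, per_cat)
  mx <- colmax(M)
  mx + log(colMeans(exp(sweep(M, 2L, mx))))
}

#' Per-site log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein pruning with the chosen substitution model. Gaps and N are
#' treated as missing data (all states equally likely); multifurcating
#' trees are handled natively, so the star "polytomy" tree needs no special
#' casing.
#'
#' @param aln A `codon_alignment` (used as plain nucleotides).
#' @param phy An `ape::phylo` with non-negative branch lengths; its tip set
#'   must be contained in the alignment rows.
#' @param model A [subst_model()].
#' @return Numeric vector of natural-log site likelihoods.
#' @export
site_loglik <- function(aln, phy, model = model_jc69()) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(phy, "phylo"),
            inherits(model, "subst_model"))
  missing <- setdiff(phy$tip.label, rownames(aln$mat))
  if (length(missing) > 0L)
    stop("taxon missing from alignment: ", missing[1L], call. = FALSE)
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths")
  stopifnot(all(phy$edge.length >= 0))
  tips <- tip_partials(aln$mat, phy$tip.label)
  prune_loglik(phy, tips, model)
}

#' Optimise branch lengths on a fixed topology
#'
#' Coordinate-wise bracketed scalar optimisation of each branch in turn,
#' cycling until the total log-likelihood improves by less than `tol_round`
#' or `max_rounds` is reached. Lengths are clamped to `[1e-9, 10]`.
#'
#' @param aln A `codon_alignment`.
#' @param topology `ape::phylo`; existing branch lengths are used as the
#'   start, otherwise every branch starts at `init`.
#' @param model A [subst_model()].
#' @param init Starting branch length.
#' @param max_rounds,tol_round Convergence controls.
#' @return List: `phy` (optimised lengths), `lnL`, `site_lnl`, `converged`.
#' @export
optimize_branch_lengths <- function(aln, topology, model = model_jc69(),
                                    init = 0.05, max_rounds = 50L,
                                    tol_round = 1e-4) {
  phy <- topology
  nb <- nrow(phy$edge)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(init, nb)
  phy$edge.length <- pmin(pmax(phy$edge.length, 1e-9), 10)
  missing <- setdiff(phy$tip.label, rownames(aln$mat))
  if (length(missing) > 0L)
    stop("taxon missing from alignment: ", missing[1L], call. = FALSE)
  tips <- tip_partials(aln$mat, phy$tip.label)
  lens <- phy$edge.length
  total <- function(l) sum(prune_loglik(phy, tips, model, lengths = l))
  cur <- total(lens)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    for (b in seq_len(nb)) {
      f <- function(x) {
        l <- lens; l[b] <- x
        total(l)
      }
      op <- stats::optimize(f, interval = c(1e-9, 10), maximum = TRUE,
                            tol = 1e-6)
      if (op$objective > cur) {
        lens[b] <- op$maximum
        cur <- op$objective
      }
    }
    new <- total(lens)
    if (new - cur > 0) cur <- new
    if (round > 1L && new - prev < tol_round) { converged <- TRUE; break }
    prev <- new
    if (round == 1L) prev <- new
  }
  phy$edge.length <- lens
  list(phy = phy, lnL = cur,
       site_lnl = prune_loglik(phy, tips, model, lengths = lens),
       converged = converged)
}

# lnL totals agreeing within tol are treated as tied (differences that
# small are optimiser noise, not signal)
col_shares_of_max <- function(T, tol = 1e-3) {
  mx <- colmax(T)
  ismax <- sweep(T, 2L, mx - tol, ">=")
  sweep(ismax, 2L, colSums(ismax), "/")
}

#' RELL-family topology tests
#'
#' Bootstrap over per-site log-likelihoods without re-optimising (RELL):
#' bootstrap proportion (ties split equally), the Kishino-Hasegawa and
#' Shimodaira-Hasegawa tests, their weighted variants (standardised by the
#' replicate's own resampled site variance), and expected likelihood
#' weights. `comparison = "vs_polytomy"` pairs each tree against the
#' reference tree (the polytomy) for the KH-type tests;
#' `comparison = "vs_best"` pairs each tree against the maximum-likelihood
#' tree.
#'
#' @param m Matrix of per-site log-likelihoods (trees x sites) or a
#'   `sitelh` object.
#' @param n_boot Number of RELL replicates (default 10000).
#' @param seed RNG seed; results are reproducible given (seed, n_boot).
#' @param comparison Pairing rule for the KH-type tests.
#' @param reference Row index of the reference (polytomy) tree.
#' @return List with `bp_RELL`, `p_KH`, `p_WKH`, `p_SH`, `p_WSH`, `c_ELW`,
#'   `lnL` (observed totals), `delta` (lnL minus reference lnL).
#' @export
rell_suite <- function(m, n_boot = 10000L, seed = 1L,
                       comparison = c("vs_polytomy", "vs_best"),
                       reference = 1L) {
  comparison <- match.arg(comparison)
  if (inherits(m, "sitelh")) m <- m$lnl
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 1L, n_boot >= 1L)
  nt <- nrow(m); S <- ncol(m)
  obs <- rowSums(m)
  set.seed(seed)
  W <- stats::rmultinom(n_boot, S, rep(1 / S, S))
  TT <- m %*% W
  bp <- rowMeans(col_shares_of_max(TT))
  elw_w <- exp(sweep(TT, 2L, colmax(TT)))
  c_ELW <- rowMeans(sweep(elw_w, 2L, colSums(elw_w), "/"))
  ref_for <- function(i) {
    if (comparison == "vs_polytomy") {
      if (i == reference) return(NA_integer_)
      reference
    } else {
      best <- which.max(obs)
      if (i != best) best else order(obs, decreasing = TRUE)[2L]
    }
  }
  eps <- 1e-2   # lnL differences below this carry no topological signal
  p_KH <- p_WKH <- rep(NA_real_, nt)
  for (i in seq_len(nt)) {
    r <- ref_for(i)
    if (is.na(r)) next
    d <- m[i, ] - m[r, ]                # positive: tree i better
    d_obs <- sum(d)
    s_obs <- sqrt(S * stats::var(d))
    if (abs(d_obs) < eps && s_obs < eps) {
      # the two fits are numerically the same model
      p_KH[i] <- p_WKH[i] <- 1
      next
    }
    db <- as.vector(d %*% W)
    dc <- db - mean(db)
    p_KH[i] <- mean(abs(dc) >= abs(d_obs))
    # weighted: studentise by each replicate's resampled site variance
    m2 <- as.vector(d^2 %*% W)
    vb <- pmax((m2 / S - (db / S)^2) * S / (S - 1), 0)
    sb <- sqrt(S * vb)
    if (s_obs == 0) { p_WKH[i] <- 1 } else {
      zb <- ifelse(sb > 0, dc / sb, 0)
      p_WKH[i] <- mean(abs(zb) >= abs(d_obs / s_obs))
    }
  }
  # SH: per-tree centring, max statistic over the candidate set
  ctr <- TT - rowMeans(TT)
  stat_obs <- max(obs) - obs
  p_SH <- numeric(nt)
  cmx <- colmax(ctr)
  for (i in seq_len(nt)) {
    p_SH[i] <- if (stat_obs[i] < eps) 1
               else mean(cmx - ctr[i, ] >= stat_obs[i])
  }
  # WSH: as SH with every pairwise difference studentised
  p_WSH <- numeric(nt)
  for (i in seq_len(nt)) {
    zo <- -Inf; zb <- rep(-Inf, n_boot)
    any_pair <- FALSE
    for (j in seq_len(nt)) {
      if (j == i) next
      d <- m[j, ] - m[i, ]
      s_obs <- sqrt(S * stats::var(d))
      if (s_obs == 0 || (s_obs < eps && abs(sum(d)) < eps)) next
      any_pair <- TRUE
      db <- as.vector(d %*% W)
      m2 <- as.vector(d^2 %*% W)
      vb <- pmax((m2 / S - (db / S)^2) * S / (S - 1), 0)
      sb <- sqrt(S * vb)
      zo <- max(zo, sum(d) / s_obs)
      zb <- pmax(zb, ifelse(sb > 0, (db - mean(db)) / sb, 0))
    }
    p_WSH[i] <- if (!any_pair) 1 else mean(zb >= zo)
  }
  nm <- rownames(m) %||% paste0("tree", seq_len(nt))
  named <- function(x) stats::setNames(x, nm)
  list(bp_RELL = named(bp), p_KH = named(p_KH), p_WKH = named(p_WKH),
       p_SH = named(p_SH), p_WSH = named(p_WSH), c_ELW = named(c_ELW),
       lnL = named(obs),
       delta = named(obs - obs[reference]))
}

#' Approximately unbiased (AU) topology test
#'
#' Multiscale RELL bootstrap: bootstrap proportions are computed at several
#' resampling sizes `r * n_sites`, transformed to normal quantiles, and a
#' signed distance `d` and curvature `c` are fitted by weighted least
#' squares to `z(r) = d*sqrt(r) + c/sqrt(r)`; the AU p-value is
#' `1 - pnorm(d - c)`. Scales with degenerate bootstrap proportions are
#' dropped; with fewer than two usable scales the plain bootstrap
#' proportion at `r = 1` is returned with a flag.
#'
#' @inheritParams rell_suite
#' @param scales Resampling-fraction grid.
#' @param n_boot Replicates per scale.
#' @return Named vector of AU p-values with attribute `flag` (per-tree:
#'   `"ok"`, `"fallback_bp"`, `"degenerate"`).
#' @export
au_test <- function(m, scales = seq(0.5, 1.4, by = 0.1), n_boot = 2000L,
                    seed = 1L) {
  if (inherits(m, "sitelh")) m <- m$lnl
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  nt <- nrow(m); S <- ncol(m)
  set.seed(seed)
  bp <- matrix(NA_real_, nt, length(scales))
  for (k in seq_along(scales)) {
    nk <- max(1L, round(scales[k] * S))
    W <- stats::rmultinom(n_boot, nk, rep(1 / S, S))
    bp[, k] <- rowMeans(col_shares_of_max(m %*% W))
  }
  r1 <- which.min(abs(scales - 1))
  p <- numeric(nt)
  flag <- character(nt)
  for (i in seq_len(nt)) {
    use <- bp[i, ] > 0 & bp[i, ] < 1
    if (sum(use) < 2L) {
      p[i] <- bp[i, r1]
      flag[i] <- if (all(bp[i, ] %in% c(0, 1))) "degenerate" else "fallback_bp"
      next
    }
    r <- scales[use]; b <- bp[i, use]
    z <- stats::qnorm(1 - b)
    X <- cbind(sqrt(r), 1 / sqrt(r))
    w <- n_boot * stats::dnorm(stats::qnorm(b))^2 / (b * (1 - b))
    cf <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * z)),
                   error = function(e) NULL)
    if (is.null(cf)) {
      p[i] <- bp[i, r1]; flag[i] <- "fallback_bp"; next
    }
    p[i] <- 1 - stats::pnorm(cf[1L] - cf[2L])
    flag[i] <- "ok"
  }
  nm <- rownames(m) %||% paste0("tree", seq_len(nt))
  structure(stats::setNames(p, nm), flag = stats::setNames(flag, nm))
}

#' Fit the polytomy and the three resolved quartets to one gene
#'
#' Optimises the star (polytomy) quartet first, then seeds each resolved
#' tree's pendant branches from the star's fit with the internal branch
#' collapsed to the lower clamp; since coordinate ascent only ever accepts
#' improvements, the nesting `lnL(polytomy) <= lnL(resolution)` holds by
#' construction up to the clamp's effect (< 1e-6 log-likelihood units).
#'
#' @param aln A `codon_alignment`.
#' @param a,b,c,o Representative taxon labels for the three focal lineages
#'   and the outgroup.
#' @param model A [subst_model()].
#' @return Named list of four fits (see [optimize_branch_lengths()]), in
#'   the order polytomy, RES_AB, RES_AC, RES_BC.
#' @export
fit_candidate_set <- function(aln, a, b, c, o, model = model_jc69()) {
  cand <- candidate_quartets(a, b, c, o)
  fits <- vector("list", length(cand))
  names(fits) <- names(cand)
  fits[[1L]] <- optimize_branch_lengths(aln, cand[[1L]], model = model)
  poly_fit <- fits[[1L]]$phy
  poly_tip_len <- stats::setNames(
    poly_fit$edge.length[match(seq_along(poly_fit$tip.label),
                               poly_fit$edge[, 2L])],
    poly_fit$tip.label)
  for (k in 2:length(cand)) {
    ph <- cand[[k]]
    ph$edge.length <- rep(1e-9, nrow(ph$edge))
    tip_edge <- match(seq_along(ph$tip.label), ph$edge[, 2L])
    ph$edge.length[tip_edge] <- poly_tip_len[ph$tip.label]
    fits[[k]] <- optimize_branch_lengths(aln, ph, model = model)
  }
  fits
}

candidate_quartets <- function(a, b, c, o) {
  nwk <- c(
    polytomy = sprintf("(%s,%s,%s,%s);", a, b, c, o),
    RES_AB = sprintf("((%s,%s),%s,%s);", a, b, c, o),
    RES_AC = sprintf("((%s,%s),%s,%s);", a, c, b, o),
    RES_BC = sprintf("((%s,%s),%s,%s);", b, c, a, o))
  lapply(nwk, function(s) ape::read.tree(text = s))
}

#' Per-gene polytomy topology test
#'
#' Builds the four candidate quartets on one representative per focal
#' lineage plus the outgroup representative (the polytomy is the species
#' tree with the focal branch collapsed), optimises branch lengths on each,
#' and runs the RELL family plus the AU test with the polytomy as the
#' reference. The polytomy is nested in every resolution, so each
#' likelihood difference `deltaL` is non-negative up to optimiser
#' tolerance; the polytomy is rejected when some resolved tree's
#' improvement is significant.
#'
#' @param aln A `codon_alignment`.
#' @param map A [lineage_map()].
#' @param model A [subst_model()].
#' @param n_boot RELL replicates.
#' @param au_n_boot Replicates per AU scale.
#' @param seed RNG seed.
#' @param alpha Rejection level.
#' @return One-row data.frame (class `topo_test_result`), or `NULL` with a
#'   warning when the gene lacks a lineage (non-decisive).
#' @export
polytomy_test_gene <- function(aln, map, model = model_jc69(),
                               n_boot = 10000L, au_n_boot = 2000L,
                               seed = 1L, alpha = 0.05) {
  rn <- rownames(aln$mat)
  reps <- vapply(list(map$A, map$B, map$C), function(s) {
    pr <- intersect(s, rn)
    if (length(pr)) pr[1L] else NA_character_
  }, character(1))
  o <- intersect(map$outgroup_priority, rn)
  o <- if (length(o)) o[1L] else NA_character_
  if (anyNA(c(reps, o))) {
    warning("gene ", aln$gene_id, " lacks a focal lineage or outgroup; ",
            "skipped (non-decisive)", call. = FALSE)
    return(NULL)
  }
  fits <- fit_candidate_set(aln, reps[1L], reps[2L], reps[3L], o,
                            model = model)
  cand <- candidate_quartets(reps[1L], reps[2L], reps[3L], o)
  mlnl <- do.call(rbind, lapply(fits, `[[`, "site_lnl"))
  rownames(mlnl) <- names(cand)
  rs <- rell_suite(mlnl, n_boot = n_boot, seed = seed,
                   comparison = "vs_polytomy", reference = 1L)
  au <- au_test(mlnl, n_boot = au_n_boot, seed = seed)
  resolved <- c("RES_AB", "RES_AC", "RES_BC")
  out <- data.frame(gene_id = aln$gene_id,
                    lnL_polytomy = rs$lnL[["polytomy"]],
                    stringsAsFactors = FALSE)
  for (tr in resolved) {
    sfx <- sub("RES_", "", tr)
    out[[paste0("lnL_", sfx)]] <- rs$lnL[[tr]]
    out[[paste0("deltaL_", sfx)]] <- rs$delta[[tr]]
    out[[paste0("p_KH_", sfx)]] <- rs$p_KH[[tr]]
    out[[paste0("p_WKH_", sfx)]] <- rs$p_WKH[[tr]]
  }
  for (tr in names(cand)) {
    sfx <- if (tr == "polytomy") "poly" else sub("RES_", "", tr)
    out[[paste0("p_SH_", sfx)]] <- rs$p_SH[[tr]]
    out[[paste0("p_WSH_", sfx)]] <- rs$p_WSH[[tr]]
    out[[paste0("p_AU_", sfx)]] <- au[[tr]]
    out[[paste0("c_ELW_", sfx)]] <- rs$c_ELW[[tr]]
    out[[paste0("bp_RELL_", sfx)]] <- rs$bp_RELL[[tr]]
  }
  out$reject_polytomy <- min(out$p_KH_AB, out$p_KH_AC, out$p_KH_BC) <= alpha
  class(out) <- c("topo_test_result", "data.frame")
  out
}

#' Summarise polytomy rejections across genes
#'
#' Per-test percentage of genes whose best resolved tree significantly
#' improves on the polytomy, plus median/IQR of the likelihood improvement
#' per resolution. For the p-value tests a gene rejects when the minimum
#' over resolved trees is at most `alpha`; for the weight summaries (ELW,
#' RELL bootstrap proportion) when the polytomy's weight is at most
#' `alpha`.
#'
#' @param results data.frame of stacked [polytomy_test_gene()] rows.
#' @param alpha Rejection level.
#' @return List with `percent_reject` (per test), `n`, `deltaL_summary`.
#' @export
summarize_rejections <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) >= 1L)
  res <- c("AB", "AC", "BC")
  min_over <- function(prefix)
    do.call(pmin, c(lapply(res, function(s) results[[paste0(prefix, s)]]),
                    list(na.rm = TRUE)))
  pr <- c(
    KH = mean(min_over("p_KH_") <= alpha),
    WKH = mean(min_over("p_WKH_") <= alpha),
    SH = mean(do.call(pmin, lapply(res, function(s)
      results[[paste0("p_SH_", s)]])) <= alpha),
    WSH = mean(do.call(pmin, lapply(res, function(s)
      results[[paste0("p_WSH_", s)]])) <= alpha),
    AU = mean(do.call(pmin, lapply(res, function(s)
      results[[paste0("p_AU_", s)]])) <= alpha),
    ELW = mean(results$c_ELW_poly <= alpha),
    BP = mean(results$bp_RELL_poly <= alpha))
  dsum <- lapply(stats::setNames(res, paste0("deltaL_", res)), function(s) {
    v <- results[[paste0("deltaL_", s)]]
    c(median = stats::median(v), q1 = unname(stats::quantile(v, 0.25)),
      q3 = unname(stats::quantile(v, 0.75)))
  })
  list(percent_reject = 100 * pr, n = nrow(results), alpha = alpha,
       deltaL_summary = dsum)
}
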