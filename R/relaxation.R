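#' Relaxation prefilter configuration
#'
#' Parameters of the neighborhood-support relaxation that scores every
#' putative correspondence by how consistently its neighbours move between
#' the two images, and of the rule that extracts the reduced high-confidence
#' set E from the initial set P.
#'
#' @param q_max Iteration cap for the relaxation sweeps (default 60).
#' @param neighborhood_radius Pixels; matches farther apart than this in
#'   image 1 lend each other no support. Default `NULL` means 1/8 of the
#'   image-1 diagonal, falling back to 100 px when the image size is unset.
#' @param epsilon_r Relative-distance tolerance: a pair supports itself only
#'   when the relative length distortion between the two images is below this
#'   (default 0.3, dimensionless).
#' @param convergence_tol Stop early when the maximum absolute change of the
#'   normalized strengths falls below this (default 1e-4).
#' @param selection Rule for building E: `"mean"` keeps matches with strength
#'   strictly above the mean strength of P; `"top_k"` keeps the `top_k`
#'   strongest; `"absolute"` keeps strengths above `abs_threshold`.
#' @param top_k,abs_threshold Parameters of the alternative selection rules.
#' @return A list of class `relaxation_config`.
#' @export
relaxation_config <- function(q_max = 60, neighborhood_radius = NULL,
                              epsilon_r = 0.3, convergence_tol = 1e-4,
                              selection = c("mean", "top_k", "absolute"),
                              top_k = NULL, abs_threshold = NULL) {
  stopifnot(q_max >= 1, epsilon_r > 0, convergence_tol > 0,
            is.null(neighborhood_radius) || neighborhood_radius > 0)
  structure(list(q_max = as.integer(q_max),
                 neighborhood_radius = neighborhood_radius,
                 epsilon_r = epsilon_r, convergence_tol = convergence_tol,
                 selection = match.arg(selection), top_k = top_k,
                 abs_threshold = abs_threshold),
            class = "relaxation_config")
}

effective_radius <- function(m, cfg) {
  if (!is.null(cfg$neighborhood_radius)) return(cfg$neighborhood_radius)
  if (!is.null(m$image1_size)) return(sqrt(sum(m$image1_size^2)) / 8)
  100
}

#' Pairwise support between two correspondences
#'
#' The support a correspondence `d` lends to `c` under the distance-consistency
#' model: with `d1` the distance between the image-1 points, `d2` the distance
#' between the image-2 points, and relative distortion `r` equal to
#' `|d1 - d2| / mean(d1, d2)`, the support is
#' `exp(-r / epsilon_r) / (1 + d1 / R)` when `r` is below `epsilon_r` and `d1 <= R`
#' (the neighborhood radius), else 0. Pairs with coincident points (zero mean
#' distance) get support 0. The measure is symmetric in `(c, d)`.
#'
#' @param c,d Numeric vectors `c(x1, y1, x2, y2)` (or single-row data.frames
#'   with those columns).
#' @param cfg A [relaxation_config()].
#' @param radius Neighborhood radius in pixels (default 100, the unset-image
#'   fallback).
#' @return A nonnegative scalar.
#' @export
pair_support <- function(c, d, cfg = relaxation_config(), radius = 100) {
  cv <- as.numeric(if (is.data.frame(c)) c[1, c("x1", "y1", "x2", "y2")] else c[1:4])
  dv <- as.numeric(if (is.data.frame(d)) d[1, c("x1", "y1", "x2", "y2")] else d[1:4])
  d1 <- sqrt(sum((cv[1:2] - dv[1:2])^2))
  d2 <- sqrt(sum((cv[3:4] - dv[3:4])^2))
  md <- (d1 + d2) / 2
  if (md <= 0) return(0)
  r <- abs(d1 - d2) / md
  if (r >= cfg$epsilon_r || d1 > radius) return(0)
  exp(-r / cfg$epsilon_r) / (1 + d1 / radius)
}

# Dense n x n support matrix (zero diagonal); the relaxation iteration is a
# repeated matrix-vector product with this matrix.
support_matrix <- function(m, cfg) {
  R <- effective_radius(m, cfg)
  D1 <- as.matrix(dist(coords1(m)))
  D2 <- as.matrix(dist(coords2(m)))
  md <- (D1 + D2) / 2
  r <- abs(D1 - D2) / ifelse(md > 0, md, 1)
  W <- exp(-r / cfg$epsilon_r) / (1 + D1 / R)
  W[r >= cfg$epsilon_r | D1 > R | md <= 0] <- 0
  diag(W) <- 0
  W
}

#' Relaxation strengths of a putative match set
#'
#' Iteratively re-scores every correspondence by the support of its
#' neighbours: the initial strength is the plain sum of pairwise supports,
#' and each sweep replaces it with the support sum weighted by the neighbours'
#' current (max-normalized) strengths, so that matches backed by other
#' well-supported matches gain weight while isolated or inconsistent ones
#' decay. Stops after `q_max` sweeps or when the normalized strengths change
#' by less than `convergence_tol`. Deterministic.
#'
#' @param P A [match_set] with at least 2 correspondences.
#' @param cfg A [relaxation_config()].
#' @return Numeric vector of normalized strengths in `[0, 1]`, aligned with
#'   `P`.
#' @export
relax <- function(P, cfg = relaxation_config()) {
  n <- n_matches(P)
  if (n < 2) {
    stop_rr("relaxransac_too_few_matches",
            "relaxation needs at least 2 correspondences")
  }
  W <- support_matrix(P, cfg)
  normalize <- function(s) {
    mx <- max(s)
    if (mx > 0) s / mx else s
  }
  shat <- normalize(rowSums(W))
  for (k in seq_len(cfg$q_max)) {
    shat_new <- normalize(as.numeric(W %*% shat))
    delta <- max(abs(shat_new - shat))
    shat <- shat_new
    if (delta < cfg$convergence_tol) break
  }
  shat
}

#' Extract the reduced high-confidence set E
#'
#' Applies the configured selection rule to the relaxation strengths and
#' returns the reduced set E (role `"E"`, order preserved, strengths
#' attached). When the selection would leave fewer than `s_min`
#' correspondences (too few to hypothesize a model), a
#' `relaxransac_selection_fallback` message is signalled and E falls back to
#' the whole of P, so preprocessing never makes the pipeline fail where plain
#' RANSAC would succeed.
#'
#' @param P A [match_set].
#' @param strengths Numeric vector from [relax()], aligned with `P`.
#' @param cfg A [relaxation_config()].
#' @param s_min Minimal usable size of E (the minimal sample size of the
#'   model to be estimated; default 8).
#' @return A [match_set] with role `"E"`.
#' @export
select_reduced_set <- function(P, strengths, cfg = relaxation_config(),
                               s_min = 8) {
  stopifnot(length(strengths) == n_matches(P))
  keep <- switch(cfg$selection,
    mean = strengths > mean(strengths),
    top_k = {
      k <- min(cfg$top_k %||% s_min, length(strengths))
      rank(-strengths, ties.method = "first") <= k
    },
    absolute = strengths > (cfg$abs_threshold %||% 0)
  )
  if (sum(keep) < s_min) {
    signal_rr("relaxransac_selection_fallback",
              sprintf("selection kept %d < %d matches; falling back to E = P",
                      sum(keep), s_min))
    keep <- rep(TRUE, n_matches(P))
  }
  E <- ms_subset(P, keep, role = "E")
  E$df$strength <- strengths[keep]
  E
}

`%||%` <- function(a, b) if (is.null(a)) b else a
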