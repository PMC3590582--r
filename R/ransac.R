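#' RANSAC configuration
#'
#' @param p Confidence that at least one all-inlier minimal sample is drawn
#'   (in (0,1); default 0.95).
#' @param model_kind `"fundamental"` (minimal sample size 8) or
#'   `"homography"` (minimal sample size 4).
#' @param s Minimal sample size; defaults to 8 or 4 by `model_kind`.
#' @param inlier_threshold Residual threshold in pixels (default 1.5; Sampson
#'   distance for F, symmetric transfer error for H).
#' @param n_max Hard iteration cap guaranteeing termination (default 10000).
#' @param sampler `"bucketed"` (minimal samples from mutually distinct
#'   spatial buckets) or `"uniform"`.
#' @param buckets_b Buckets per side of the sampling grid (default 8).
#' @param seed Integer seed; every run of [ransac()] or
#'   [preprocessed_ransac()] starts from it.
#' @return A list of class `ransac_config`.
#' @export
ransac_config <- function(p = 0.95, model_kind = c("fundamental", "homography"),
                          s = NULL, inlier_threshold = 1.5, n_max = 10000,
                          sampler = c("bucketed", "uniform"), buckets_b = 8,
                          seed = 0) {
  model_kind <- match.arg(model_kind)
  sampler <- match.arg(sampler)
  if (is.null(s)) s <- if (model_kind == "fundamental") 8L else 4L
  stopifnot(p > 0, p < 1, s %in% c(4L, 8L), inlier_threshold > 0,
            n_max >= 1, buckets_b >= 1)
  structure(list(p = p, s = as.integer(s), inlier_threshold = inlier_threshold,
                 n_max = as.integer(n_max), model_kind = model_kind,
                 sampler = sampler, buckets_b = as.integer(buckets_b),
                 seed = as.integer(seed)),
            class = "ransac_config")
}

#' Adaptive RANSAC iteration bound
#'
#' The number of minimal samples needed so that with confidence `p` at least
#' one of them is all-inlier when each point is an inlier with probability
#' `phi`: `N = ceil(log(1 - p) / log(1 - phi^s))`, clamped to `[1, n_max]`
#' (`phi = 0` gives `n_max`, `phi = 1` gives 1).
#'
#' @param p Confidence in (0, 1).
#' @param phi Inlier ratio in `[0, 1]` (vectorized).
#' @param s Minimal sample size (>= 1).
#' @param n_max Clamp for the bound.
#' @return Integer vector of iteration bounds.
#' @export
required_iterations <- function(p, phi, s, n_max = 10000L) {
  stopifnot(p > 0, p < 1, all(phi >= 0), all(phi <= 1), s >= 1)
  vapply(phi, function(f) .req_iters_cpp(p, f, as.integer(s), as.integer(n_max)),
         integer(1))
}

#' Confidence achieved by N iterations at a given inlier ratio
#'
#' The probability `p = 1 - (1 - phi_red^s)^N` that at least one of `N`
#' minimal samples is all-inlier; the inverse view of
#' [required_iterations()].
#'
#' @param phi_red Inlier ratio of the sampled set, in `[0, 1]`.
#' @param s Minimal sample size.
#' @param N Number of iterations.
#' @return Probability in `[0, 1]`.
#' @export
achieved_confidence <- function(phi_red, s, N) {
  stopifnot(all(phi_red >= 0), all(phi_red <= 1), s >= 1, all(N >= 0))
  -expm1(N * log1p(-phi_red^s))
}

# Run the hypothesize-and-verify loop on match set M using the current RNG
# stream. Returns the raw C++ result plus the sampled set.
ransac_run <- function(M, cfg) {
  n <- n_matches(M)
  if (n < cfg$s) {
    stop_rr("relaxransac_too_few_matches",
            sprintf("need at least %d correspondences, got %d", cfg$s, n))
  }
  buckets <- list()
  if (cfg$sampler == "bucketed") {
    grid <- build_bucket_grid(M, cfg$buckets_b)
    # C++ wants 1-based row positions, members hold ids
    buckets <- lapply(grid$members, function(ids) match(ids, M$df$id))
  }
  raw <- .ransac_loop_cpp(coords1(M), coords2(M), cfg$model_kind, cfg$s,
                          cfg$p, cfg$inlier_threshold, cfg$n_max, buckets)
  if (isTRUE(raw$bucket_fallback)) {
    signal_rr("relaxransac_bucket_fallback",
              "fewer non-empty buckets than the sample size; uniform sampling used")
  }
  if (!isTRUE(raw$found) || raw$count < cfg$s) {
    stop_rr("relaxransac_no_consensus",
            sprintf("no model with >= %d inliers found within %d iterations",
                    cfg$s, raw$iterations),
            data = raw)
  }
  raw
}

model_class <- function(kind) {
  if (kind == "fundamental") "fundamental_matrix" else "homography"
}

new_ransac_result <- function(model, mask_E, mask_P, iterations, N_final,
                              cfg, n_P) {
  support <- sum(mask_P)
  structure(list(model = model,
                 inlier_mask_E = mask_E, inlier_mask_P = mask_P,
                 iterations_used = iterations, N_final = N_final,
                 phi_red = mean(mask_E), phi_P = mean(mask_P),
                 support_P = support,
                 report = sprintf("%d/%d", support, n_P),
                 config = cfg),
            class = "ransac_result")
}

#' @export
print.ransac_result <- function(x, ...) {
  cat(sprintf("<ransac_result %s: %s inliers, %d iterations (bound %d), phi_red = %.3f>\n",
              x$config$model_kind, x$report, x$iterations_used, x$N_final,
              x$phi_red))
  invisible(x)
}

#' Robust model estimation by adaptive RANSAC
#'
#' The hypothesize-and-verify loop: draw a minimal sample (bucketed or
#' uniform), estimate the model (degenerate samples are skipped but consume
#' an iteration), score it by its number of inliers on `M`, and keep the best
#' model (ties keep the earlier one). After every improvement the iteration
#' bound is recomputed by [required_iterations()] from the best inlier ratio
#' seen so far; the loop stops at `min(N, n_max)` iterations. The winning
#' model is refit by the same solver on all of its inliers (when at least `s`
#' of them) and the inlier mask recomputed.
#'
#' @param M A [match_set] with at least `cfg$s` correspondences.
#' @param cfg A [ransac_config()].
#' @return A `ransac_result`: `model`, inlier masks, `iterations_used`,
#'   `N_final`, inlier ratios `phi_red` / `phi_P` (both on `M` here),
#'   `support_P` and the `"k/n"` report string.
#' @export
ransac <- function(M, cfg = ransac_config()) {
  set.seed(cfg$seed)
  raw <- ransac_run(M, cfg)
  model <- new_model(raw$model, model_class(cfg$model_kind))
  mask <- as.logical(raw$mask)
  new_ransac_result(model, mask, mask, raw$iterations, raw$N_final, cfg,
                    n_matches(M))
}

#' Preprocessed RANSAC: relax, reduce, estimate, verify on the full set
#'
#' The two-stage framework: (1) score the putative set P by neighborhood
#' relaxation ([relax()]) and extract the reduced high-confidence subset E
#' ([select_reduced_set()]); (2) run adaptive RANSAC on E only (bucketed
#' sampling by default, grid built from E's image-1 points); (3) compute the
#' winning model's support on the whole of P with the same residual threshold
#' and report it as `"k/n"`. Because E has a higher inlier ratio than P, the
#' iteration bound on E is reached much sooner when P's inlier ratio is low.
#'
#' @param P The initial putative [match_set].
#' @param rcfg A [relaxation_config()].
#' @param cfg A [ransac_config()].
#' @return A `ransac_result` with `inlier_mask_E` on E, `inlier_mask_P` and
#'   `support_P` on P, `phi_red` the inlier ratio on E, plus the selected set
#'   in `$E` and its strengths in `$strengths`.
#' @export
preprocessed_ransac <- function(P, rcfg = relaxation_config(),
                                cfg = ransac_config()) {
  if (n_matches(P) < cfg$s) {
    stop_rr("relaxransac_too_few_matches",
            sprintf("need at least %d correspondences, got %d", cfg$s,
                    n_matches(P)))
  }
  set.seed(cfg$seed)
  strengths <- relax(P, rcfg)
  E <- select_reduced_set(P, strengths, rcfg, s_min = cfg$s)
  raw <- ransac_run(E, cfg)
  model <- new_model(raw$model, model_class(cfg$model_kind))
  mask_E <- as.logical(raw$mask)
  mask_P <- withCallingHandlers(
    classify_inliers(model, P, cfg$inlier_threshold),
    relaxransac_undefined_residual_outlier = function(c) invokeRestart("muffleMessage"))
  out <- new_ransac_result(model, mask_E, mask_P, raw$iterations, raw$N_final,
                           cfg, n_matches(P))
  out$E <- E
  out$strengths <- strengths
  out
}

#' Paired benchmark of plain vs preprocessed RANSAC on synthetic scenes
#'
#' For every combination of inlier ratio `phi` and seed, generates a
#' synthetic fundamental-matrix scene, runs plain RANSAC on the full putative
#' set and the preprocessed pipeline, and records iteration counts, the
#' enriched inlier ratio of E, and precision/recall of the preprocessed
#' pipeline's inlier classification against the generator's ground truth.
#'
#' @param phis Numeric vector of inlier ratios to simulate.
#' @param seeds Integer vector of scene seeds.
#' @param n Correspondences per scene (default 300).
#' @param sigma Inlier noise standard deviation in pixels (default 0.5).
#' @param cfg A [ransac_config()] (its `seed` is overridden per run).
#' @param rcfg A [relaxation_config()].
#' @return A data.frame with one row per (phi, seed): `iters_plain`,
#'   `iters_pre`, `phi_E`, `size_E`, `precision`, `recall`.
#' @export
benchmark_ransac <- function(phis, seeds, n = 300, sigma = 0.5,
                             cfg = ransac_config(), rcfg = relaxation_config()) {
  rows <- lapply(phis, function(phi) {
    per_seed <- lapply(seeds, function(sd) {
      sc <- generate_f_scene(n = n, phi = phi, sigma = sigma, seed = sd,
                             inlier_threshold = cfg$inlier_threshold)
      cfg_run <- cfg
      cfg_run$seed <- as.integer(sd)
      # the traditional-RANSAC arm samples uniformly (no bucketing)
      cfg_plain <- cfg_run
      cfg_plain$sampler <- "uniform"
      plain <- suppressMessages(ransac(sc$matches, cfg_plain))
      pre <- suppressMessages(preprocessed_ransac(sc$matches, rcfg, cfg_run))
      tp <- sum(pre$inlier_mask_P & sc$true_inlier_mask)
      data.frame(phi = phi, seed = sd,
                 iters_plain = plain$iterations_used,
                 iters_pre = pre$iterations_used,
                 phi_E = mean(sc$true_inlier_mask[match(pre$E$df$id, sc$matches$df$id)]),
                 size_E = n_matches(pre$E),
                 precision = if (sum(pre$inlier_mask_P) > 0) tp / sum(pre$inlier_mask_P) else NA_real_,
                 recall = tp / sum(sc$true_inlier_mask))
    })
    do.call(rbind, per_seed)
  })
  do.call(rbind, rows)
}
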