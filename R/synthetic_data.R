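# Seeded synthetic cohorts with the statistical structure the pipeline
# assumes: two outcome classes at a fixed prevalence, a subset of
# class-informative features (standardized mean shift), equicorrelated
# feature blocks, and optionally two "platform" views of one latent signal
# for cross-platform transfer experiments.

#' Synthetic cohort configuration
#'
#' Defaults emulate a mid-sized transcriptomics cohort with a 4:1 class
#' imbalance: 200 samples, 1000 features of which 100 carry a one-standard-
#' deviation class shift, correlated feature blocks (equicorrelation 0.6
#' within each of 10 blocks) and unit noise.
#'
#' @param n_samples,n_features cohort dimensions.
#' @param n_informative number of features whose mean differs between
#'   classes (must be <= `n_features`).
#' @param effect_size standardized mean shift of informative features
#'   between classes, in units of `noise_sd`.
#' @param class_prevalence positive-class proportion in (0, 1); the positive
#'   count is `round(prevalence * n_samples)` exactly.
#' @param n_blocks number of equicorrelated feature blocks.
#' @param block_rho within-block feature correlation in `[0, 1)`,
#'   implemented through one shared latent factor per block.
#' @param noise_sd marginal noise standard deviation (> 0).
#' @param seed integer seed; the generator is a pure function of the config.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 200, n_features = 1000,
                          n_informative = 100, effect_size = 1,
                          class_prevalence = 0.2, n_blocks = 10,
                          block_rho = 0.6, noise_sd = 1, seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_features = as.integer(n_features),
              n_informative = as.integer(n_informative),
              effect_size = effect_size,
              class_prevalence = class_prevalence,
              n_blocks = as.integer(n_blocks), block_rho = block_rho,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_informative > cfg$n_features)
    stop("n_informative must be <= n_features")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) stop("block_rho must be in [0, 1)")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$class_prevalence <= 0 || cfg$class_prevalence >= 1)
    stop("class_prevalence must be in (0, 1)")
  n_pos <- round(cfg$class_prevalence * cfg$n_samples)
  if (n_pos < 2 || cfg$n_samples - n_pos < 2)
    stop("infeasible prevalence: need at least 2 samples per class")
  structure(cfg, class = "cohort_config")
}

# evaluate `expr` under a private RNG stream, restoring global RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# latent signal (features x samples) + labels, before any platform view
cohort_latent <- function(config) {
  n <- config$n_samples; p <- config$n_features
  n_pos <- round(config$class_prevalence * n)
  y <- integer(n)
  y[sample.int(n, n_pos)] <- 1L
  block_of <- rep(seq_len(config$n_blocks), length.out = p)
  block_of <- sort(block_of)  # contiguous blocks
  factors <- matrix(rnorm(config$n_blocks * n), config$n_blocks, n)
  eps <- matrix(rnorm(p * n), p, n)
  rho <- config$block_rho
  m <- sqrt(rho) * factors[block_of, , drop = FALSE] + sqrt(1 - rho) * eps
  m <- m * config$noise_sd
  if (config$n_informative > 0) {
    shift <- config$effect_size * config$noise_sd
    m[seq_len(config$n_informative), y == 1L] <-
      m[seq_len(config$n_informative), y == 1L] + shift
  }
  dimnames(m) <- list(sprintf("feat_%04d", seq_len(p)),
                      sprintf("sample_%03d", seq_len(n)))
  list(values = m, y = setNames(y, colnames(m)))
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param platform_tag tag recorded on the expression matrix.
#' @return list with elements `expression` ([expression_matrix()]) and
#'   `outcomes` ([outcome_table()] with a single outcome `"event"`).
#' @export
generate_cohort <- function(config, platform_tag = "synthetic") {
  stopifnot(inherits(config, "cohort_config"))
  lat <- with_seed(config$seed, cohort_latent(config))
  list(expression = expression_matrix(lat$values, platform_tag = platform_tag),
       outcomes = outcome_table(names(lat$y), list(event = unname(lat$y))))
}

#' Generate two platform views of one latent cohort
#'
#' Both views derive from the same latent signal matrix (hence share sample
#' ids and labels); view A adds independent noise, view B additionally
#' applies a per-feature distortion — affine (`a * x + b`, slope in
#' `[0.5, 2]`) or rank-monotone (a strictly increasing nonlinearity, here
#' `x^3` or `exp(x)` per feature) — emulating the same biology measured by
#' two technologies (e.g. microarray vs RNA-seq).
#'
#' @param config a [cohort_config()].
#' @param distortion `"affine"` or `"rank-monotone"`.
#' @param view_noise_sd standard deviation of the per-view independent
#'   noise, in units of the latent signal's `noise_sd`.
#' @return list with `view_a`, `view_b` ([expression_matrix()]s) and
#'   `outcomes` ([outcome_table()]).
#' @export
generate_platform_pair <- function(config,
                                   distortion = c("affine", "rank-monotone"),
                                   view_noise_sd = 0.3) {
  stopifnot(inherits(config, "cohort_config"))
  distortion <- match.arg(distortion)
  out <- with_seed(config$seed, {
    lat <- cohort_latent(config)
    p <- nrow(lat$values); n <- ncol(lat$values)
    sdv <- view_noise_sd * config$noise_sd
    a_vals <- lat$values + matrix(rnorm(p * n, sd = sdv), p, n)
    if (distortion == "affine") {
      slope <- runif(p, 0.5, 2)
      inter <- rnorm(p)
      b_core <- lat$values * slope + inter
    } else {
      # strictly increasing per-feature transforms of the standardized signal
      z <- (lat$values - rowMeans(lat$values)) /
        apply(lat$values, 1, sd)
      pick <- sample(c("cube", "exp"), p, replace = TRUE)
      b_core <- z
      b_core[pick == "cube", ] <- z[pick == "cube", ]^3
      b_core[pick == "exp", ] <- exp(z[pick == "exp", ])
    }
    b_vals <- b_core + matrix(rnorm(p * n, sd = sdv), p, n)
    dimnames(b_vals) <- dimnames(a_vals) <- dimnames(lat$values)
    list(a = a_vals, b = b_vals, y = lat$y)
  })
  list(view_a = expression_matrix(out$a, platform_tag = "platform_A"),
       view_b = expression_matrix(out$b, platform_tag = "platform_B"),
       outcomes = outcome_table(names(out$y), list(event = unname(out$y))))
}
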