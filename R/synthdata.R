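#' Generate omics-like classification data with known informative features
#'
#' Emulates the "many features, few samples" regime of transcriptomics:
#' a small set of informative features carries class-dependent Gaussian
#' mean shifts while all remaining features are pure noise. With
#' `positive = TRUE` values are exponentiated to a log-normal,
#' expression-like positive scale (class separation is preserved on the
#' log scale).
#'
#' @param n_samples Number of samples (>= 2 per class).
#' @param n_features Total number of features.
#' @param n_informative Number of informative features (<= n_features).
#' @param n_classes Number of classes (balanced).
#' @param separation Distance between consecutive class means on
#'   informative features, in units of `noise_sd`.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param positive Exponentiate to a positive, log-normal-like scale.
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return An [mo_dataset()] with a `class` outcome and attribute
#'   `informative` listing the informative feature indices.
#' @export
generate_classification <- function(n_samples = 60, n_features = 500,
                                    n_informative = 3, n_classes = 2,
                                    separation = 2, noise_sd = 1,
                                    positive = FALSE, seed = 1) {
  stopifnot(n_informative <= n_features, n_samples >= 2 * n_classes,
            noise_sd > 0)
  withr::with_seed(seed, {
    y <- factor(rep_len(paste0("c", seq_len(n_classes)), n_samples))
    x <- matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
                n_samples, n_features)
    if (n_informative > 0) {
      shift <- (as.integer(y) - (n_classes + 1) / 2) * separation * noise_sd
      for (j in seq_len(n_informative)) {
        x[, j] <- x[, j] + shift
      }
    }
    if (positive) x <- exp(x)
    colnames(x) <- paste0("g", seq_len(n_features))
    rownames(x) <- paste0("s", seq_len(n_samples))
  })
  out <- mo_dataset(x, class = y)
  attr(out, "informative") <- seq_len(n_informative)
  out
}

#' Generate survival data with a linear log-hazard in informative features
#'
#' Event times are exponential with a log-hazard linear in the informative
#' features (Cox-compatible); censoring times are independent uniform on
#' `[0, c_max]` with `c_max` calibrated so the expected censoring fraction
#' matches `censoring`.
#'
#' @inheritParams generate_classification
#' @param effect_size Log-hazard coefficient shared by the informative
#'   features.
#' @param baseline_rate Baseline hazard rate of the exponential times.
#' @param censoring Target censoring fraction in `[0, 1)`.
#' @return An [mo_dataset()] with `time`/`event` outcomes, attribute
#'   `informative`, and attribute `true_risk` (the generating linear
#'   predictor).
#' @export
generate_survival <- function(n_samples = 60, n_features = 500,
                              n_informative = 3, effect_size = 1,
                              baseline_rate = 0.1, censoring = 0.3,
                              noise_sd = 1, seed = 1) {
  stopifnot(n_informative <= n_features, censoring >= 0, censoring < 1)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
                n_samples, n_features)
    colnames(x) <- paste0("g", seq_len(n_features))
    rownames(x) <- paste0("s", seq_len(n_samples))
    lp <- if (n_informative > 0) {
      drop(x[, seq_len(n_informative), drop = FALSE] %*%
             rep(effect_size, n_informative))
    } else {
      rep(0, n_samples)
    }
    rate <- baseline_rate * exp(lp)
    t_event <- stats::rexp(n_samples, rate)
    if (censoring > 0) {
      # E[censored] = mean over subjects of P(T_i > C), C ~ U(0, c_max)
      cens_frac <- function(c_max) {
        mean((1 - exp(-rate * c_max)) / (rate * c_max))
      }
      c_max <- stats::uniroot(function(cm) cens_frac(cm) - censoring,
                              lower = 1e-6, upper = 1e6, tol = 1e-8)$root
      t_cens <- stats::runif(n_samples, 0, c_max)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n_samples)
    }
  })
  out <- mo_dataset(x, time = time, event = event)
  attr(out, "informative") <- seq_len(n_informative)
  attr(out, "true_risk") <- lp
  out
}
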