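#' Generate a bank of spike waveform templates
#'
#' Builds `n_classes` canonical single-unit spike shapes, each normalized to
#' unit peak absolute amplitude. A template is biphasic: a sharp Gaussian
#' depolarization lobe followed by a broader opposite-sign after-wave, with
#' per-class peak latency, lobe widths and trough ratio. Difficulty controls
#' how alike the classes look:
#'
#' * `"easy"` draws well-separated parameters and rejection-samples until
#'   every pairwise peak-aligned correlation is at most `easy_max_cor`;
#' * `"difficult"` perturbs one base shape by a few percent until every
#'   pairwise correlation is at least `difficult_min_cor`, emulating the
#'   nearly identical waveforms of the hard benchmark datasets.
#'
#' @param n_classes Number of units (at least 2; the simulated benchmark
#'   uses 3).
#' @param n_samples Samples per template (at least 16; 64 at 24 kHz).
#' @param difficulty `"easy"` or `"difficult"`.
#' @param seed Integer seed; the bank is a deterministic function of the
#'   arguments.
#' @param easy_max_cor,difficult_min_cor Correlation bounds enforced by
#'   construction.
#' @param max_tries Rejection-sampling budget before giving up.
#' @return A `template_bank`: list with `templates` (`n_classes` x
#'   `n_samples` matrix, unit peak), `difficulty`, `seed` and the realized
#'   pairwise `correlations`.
#' @examples
#' bank <- make_templates(3, 64, "easy", seed = 1)
#' range(abs(bank$templates))
#' @export
make_templates <- function(n_classes = 3L, n_samples = 64L,
                           difficulty = c("easy", "difficult"), seed = 1L,
                           easy_max_cor = 0.7, difficult_min_cor = 0.9,
                           max_tries = 200L) {
  difficulty <- match.arg(difficulty)
  if (n_classes < 2L) abort("n_classes must be at least 2")
  if (n_samples < 16L) abort("n_samples must be at least 16")

  out <- local_seeded(seed, {
    if (difficulty == "easy") {
      # greedy construction: accept each candidate only if it decorrelates
      # from every template already in the bank (scales to many classes);
      # a dead end late in the bank triggers a whole-bank restart, since
      # feasibility depends on the early picks
      build_bank <- function() {
        tpl <- matrix(0, n_classes, n_samples)
        tpl[1L, ] <- draw_biphasic(n_samples)
        worst <- Inf
        for (k in seq_len(n_classes)[-1L]) {
          placed <- FALSE
          for (try in seq_len(max_tries)) {
            cand <- draw_biphasic(n_samples)
            cc <- vapply(seq_len(k - 1L), function(j)
              peak_aligned_cor(tpl[j, ], cand), numeric(1))
            worst <- min(worst, max(cc))
            if (max(cc) <= easy_max_cor) { tpl[k, ] <- cand; placed <- TRUE; break }
          }
          if (!placed) return(list(tpl = NULL, worst = worst))
        }
        list(tpl = tpl, worst = worst)
      }
      res <- NULL
      worst <- Inf
      for (restart in seq_len(20L)) {
        res <- build_bank()
        worst <- min(worst, res$worst)
        if (!is.null(res$tpl)) break
      }
      if (is.null(res$tpl)) {
        abort(sprintf("could not construct %d dissimilar easy-mode templates (best achieved max correlation: %.3f)",
                      n_classes, worst))
      }
      list(tpl = res$tpl, cors = pairwise_peak_cor(res$tpl))
    } else {
      best <- NULL
      best_score <- Inf
      for (try in seq_len(max_tries)) {
        base <- biphasic_params(n_samples)
        tpl <- t(replicate(n_classes, {
          p <- lapply(base, function(v) v * (1 + runif(1, -0.03, 0.03)))
          do.call(biphasic_shape, c(list(n = n_samples), p))
        }))
        cors <- pairwise_peak_cor(tpl)
        if (-min(cors) < best_score) {
          best <- list(tpl = tpl, cors = cors)
          best_score <- -min(cors)
        }
        if (min(cors) >= difficult_min_cor) break
      }
      if (min(best$cors) < difficult_min_cor) {
        abort(sprintf("could not construct difficult-mode templates in %d tries (achieved pairwise correlations: %s)",
                      max_tries,
                      paste(sprintf("%.3f", best$cors), collapse = ", ")))
      }
      best
    }
  })
  structure(list(templates = out$tpl, difficulty = difficulty, seed = seed,
                 correlations = out$cors),
            class = "template_bank")
}

# evaluate seeded code without disturbing the caller's RNG stream
local_seeded <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

biphasic_shape <- function(n, mu1, w1, lag, w2, ratio) {
  t <- seq_len(n) - 1
  v <- exp(-((t - mu1)^2) / (2 * w1^2)) -
    ratio * exp(-((t - mu1 - lag)^2) / (2 * w2^2))
  v / max(abs(v))
}

biphasic_params <- function(n) {
  list(mu1 = runif(1, 0.25 * n, 0.45 * n),
       w1 = runif(1, 0.02 * n, 0.07 * n),
       lag = runif(1, 0.06 * n, 0.22 * n),
       w2 = runif(1, 0.05 * n, 0.18 * n),
       ratio = runif(1, 0.25, 1.2))
}

draw_biphasic <- function(n) {
  do.call(biphasic_shape, c(list(n = n), biphasic_params(n)))
}

#' Peak-aligned correlation between two waveforms
#'
#' Shifts `b` so that its absolute-amplitude peak coincides with the peak of
#' `a`, then returns the Pearson correlation over the overlapping samples.
#' Used to quantify how confusable two spike templates are regardless of
#' latency differences.
#'
#' @param a,b Numeric waveforms of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
peak_aligned_cor <- function(a, b) {
  stopifnot(length(a) == length(b))
  sh <- which.max(abs(b)) - which.max(abs(a))
  i <- seq_along(a)
  keep <- i + sh >= 1L & i + sh <= length(a)
  cor(a[keep], b[i[keep] + sh])
}

pairwise_peak_cor <- function(tpl) {
  k <- nrow(tpl)
  pairs <- utils::combn(k, 2L)
  as.vector(apply(pairs, 2L, function(ij)
    peak_aligned_cor(tpl[ij[1L], ], tpl[ij[2L], ])))
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d classes x %d samples, %s mode (seed %d)\n",
              nrow(x$templates), ncol(x$templates), x$difficulty, x$seed))
  cat(sprintf("  pairwise peak-aligned correlations: %s\n",
              paste(sprintf("%.3f", x$correlations), collapse = ", ")))
  invisible(x)
}

#' @rdname make_templates
#' @param object A `template_bank`.
#' @param ... Unused.
#' @export
autoplot.template_bank <- function(object, ...) {
  df <- tibble::as_tibble(t(object$templates), .name_repair = ~ paste0("c", seq_len(nrow(object$templates))))
  df$sample <- seq_len(ncol(object$templates)) - 1L
  long <- tidyr::pivot_longer(df, -"sample", names_to = "class",
                              names_prefix = "c", values_to = "amplitude")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$amplitude,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample", y = "amplitude (peak-normalized)",
                  colour = "cluster",
                  title = sprintf("Spike templates (%s mode)", object$difficulty)) +
    ggplot2::theme_minimal()
}
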