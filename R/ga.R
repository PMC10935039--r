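#' Genetic-algorithm configuration for VMD parameter search
#'
#' Defaults follow the search conditions used for mode-count/penalty
#' optimisation: k in 2--10, alpha in 100--5000, population 10, 30
#' generations. Chromosomes are binary: 4 bits encode k across `k_range`,
#' 12 bits encode alpha linearly across `alpha_range`.
#'
#' @param pop_size Individuals per generation (>= 2).
#' @param n_iter Generations.
#' @param k_range Integer interval `c(lo, hi)` for the mode count.
#' @param alpha_range Real interval for the penalty factor.
#' @param p_crossover One-point crossover probability.
#' @param p_mutation Per-bit flip probability.
#' @param elitism Number of best individuals copied unchanged.
#' @param tournament Tournament size for selection.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(pop_size = 10, n_iter = 30, k_range = c(2, 10),
                      alpha_range = c(100, 5000), p_crossover = 0.8,
                      p_mutation = 0.05, elitism = 1, tournament = 2) {
  if (pop_size < 2) abort("pop_size must be >= 2.")
  if (k_range[1] > k_range[2] || alpha_range[1] > alpha_range[2]) {
    abort("Parameter ranges must be non-empty.")
  }
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1) {
    abort("Probabilities must lie in [0, 1].")
  }
  structure(list(pop_size = pop_size, n_iter = n_iter, k_range = k_range,
                 alpha_range = alpha_range, p_crossover = p_crossover,
                 p_mutation = p_mutation, elitism = elitism,
                 tournament = tournament, k_bits = 4, alpha_bits = 12),
            class = "ga_config")
}

decode_chromosome <- function(bits, cfg) {
  kb <- bits[seq_len(cfg$k_bits)]
  ab <- bits[cfg$k_bits + seq_len(cfg$alpha_bits)]
  k_int <- sum(kb * 2^(seq_along(kb) - 1))
  a_int <- sum(ab * 2^(seq_along(ab) - 1))
  k <- cfg$k_range[1] +
    round(k_int / (2^cfg$k_bits - 1) * diff(cfg$k_range))
  alpha <- cfg$alpha_range[1] +
    a_int / (2^cfg$alpha_bits - 1) * diff(cfg$alpha_range)
  list(k = as.integer(k), alpha = alpha)
}

#' ApEn-based fitness of a VMD parameter pair
#'
#' Decomposes the segment with the candidate `(k, alpha)` and returns the
#' minimum (default) or mean approximate entropy across the modes. Lower
#' is better: a very regular mode is one in which the stereotyped ocular
#' waveform has been concentrated, which is exactly what the downstream
#' source rejection needs.
#'
#' @param x Segment samples.
#' @param fs Sampling rate, Hz.
#' @param k,alpha VMD parameters.
#' @param agg `"min"` or `"mean"` aggregation over modes.
#' @return Scalar fitness (lower = better).
#' @export
vmd_fitness <- function(x, fs, k, alpha, agg = c("min", "mean")) {
  agg <- match.arg(agg)
  res <- vmd_decompose(x, fs, k = k, alpha = alpha)
  ae <- apply(res$modes, 1, approximate_entropy)
  if (agg == "min") min(ae) else mean(ae)
}

#' Genetic-algorithm search over VMD parameters
#'
#' Binary-coded GA with tournament selection, one-point crossover,
#' per-bit mutation and elitism. Deterministic for a fixed seed. The
#' fitness function is minimised.
#'
#' @param x Segment samples (passed to `fitness_fn`).
#' @param fs Sampling rate (passed to `fitness_fn`).
#' @param cfg A [ga_config()].
#' @param fitness_fn Function `(x, fs, k, alpha) -> scalar`; defaults to
#'   [vmd_fitness()].
#' @param seed RNG seed for reproducibility.
#' @return Object of class `ga_result`: list with `best_k`, `best_alpha`,
#'   `best_fitness` and `fitness_history` (tibble: `generation`,
#'   `best`, `mean`), where `best` is the running best (non-increasing).
#' @export
ga_optimize <- function(x, fs, cfg = ga_config(), fitness_fn = vmd_fitness,
                        seed = NULL) {
  n_bits <- cfg$k_bits + cfg$alpha_bits
  with_seed(seed, {
    pop <- matrix(sample(0:1, cfg$pop_size * n_bits, replace = TRUE),
                  nrow = cfg$pop_size)
    evaluate <- function(P) {
      apply(P, 1, function(b) {
        d <- decode_chromosome(b, cfg)
        fitness_fn(x, fs, d$k, d$alpha)
      })
    }
    fit <- evaluate(pop)
    best_bits <- pop[which.min(fit), ]
    best_fit <- min(fit)
    hist <- tibble(generation = 0L, best = best_fit, mean = mean(fit))
    for (g in seq_len(cfg$n_iter)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
      n_child <- cfg$pop_size - cfg$elitism
      children <- matrix(0L, n_child, n_bits)
      for (i in seq_len(n_child)) {
        pick <- function() {
          cand <- sample.int(cfg$pop_size, cfg$tournament)
          cand[which.min(fit[cand])]
        }
        p1 <- pop[pick(), ]
        p2 <- pop[pick(), ]
        child <- p1
        if (runif(1) < cfg$p_crossover) {
          cut <- sample.int(n_bits - 1, 1)
          child <- c(p1[seq_len(cut)], p2[(cut + 1):n_bits])
        }
        flip <- runif(n_bits) < cfg$p_mutation
        child[flip] <- 1L - child[flip]
        children[i, ] <- child
      }
      pop <- rbind(elite, children)
      fit <- evaluate(pop)
      if (min(fit) < best_fit) {
        best_fit <- min(fit)
        best_bits <- pop[which.min(fit), ]
      }
      hist <- dplyr::bind_rows(hist, tibble(generation = g, best = best_fit,
                                            mean = mean(fit)))
    }
    d <- decode_chromosome(best_bits, cfg)
    res <- list(best_k = d$k, best_alpha = d$alpha, best_fitness = best_fit,
                fitness_history = hist)
    class(res) <- "ga_result"
    res
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best (k, alpha) = (%d, %.1f), fitness %.5f after %d generations\n",
              x$best_k, x$best_alpha, x$best_fitness,
              max(x$fitness_history$generation)))
  invisible(x)
}

#' @rdname ga_optimize
#' @export
tidy.ga_result <- function(x, ...) x$fitness_history

#' @rdname ga_optimize
#' @export
glance.ga_result <- function(x, ...) {
  tibble(best_k = x$best_k, best_alpha = x$best_alpha,
         best_fitness = x$best_fitness,
         n_generations = max(x$fitness_history$generation))
}
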