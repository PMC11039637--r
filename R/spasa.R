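# Sparrow search algorithm (SpaSA) over bounded real/integer gene
# vectors, maximising a pluggable objective -- here typically the
# smoothed-Jaccard segmentation fitness.
#
# The canonical producer/scrounger/scout update rules are used:
# producers either drift multiplicatively (no alarm) or take a Gaussian
# step (alarm raised); scroungers in the worse half jump towards the
# origin-scaled worst position while the better half move around the
# best producer; a random fraction of scouts take danger-response steps
# relative to the global best and worst.  Elitism is enforced by
# recording the best position ever evaluated.

#' Optimizer configuration for the sparrow search
#'
#' @param population_size number of sparrows (>= 4).
#' @param iterations update iterations.
#' @param producer_fraction fraction of the population acting as
#'   producers, in (0, 1).
#' @param scout_fraction fraction taking scout (danger-aware) steps,
#'   in \[0, 1).
#' @param safety_threshold alarm threshold ST in \[0.5, 1\]; below it
#'   producers drift, above it they take Gaussian steps.
#' @param seed RNG seed; (seed, config, objective) fully determine a run.
#' @return an `optimizer_config`.
#' @export
optimizer_config <- function(population_size = 10L, iterations = 10L,
                             producer_fraction = 0.2, scout_fraction = 0.1,
                             safety_threshold = 0.8, seed = 1L) {
  lf_check(is_count(population_size, 4), "population_size",
           "must be an integer >= 4")
  lf_check(is_count(iterations, 0), "iterations", "must be >= 0")
  lf_check(
    is_scalar_num(producer_fraction) && producer_fraction > 0 &&
      producer_fraction < 1,
    "producer_fraction", "must lie in (0, 1)"
  )
  lf_check(
    is_scalar_num(scout_fraction) && scout_fraction >= 0 && scout_fraction < 1,
    "scout_fraction", "must lie in [0, 1)"
  )
  lf_check(
    is_scalar_num(safety_threshold) && safety_threshold >= 0.5 &&
      safety_threshold <= 1,
    "safety_threshold", "must lie in [0.5, 1]"
  )
  structure(
    list(population_size = as.integer(population_size),
         iterations = as.integer(iterations),
         producer_fraction = producer_fraction,
         scout_fraction = scout_fraction,
         safety_threshold = safety_threshold, seed = as.integer(seed)),
    class = "optimizer_config"
  )
}

#' Initialize a sparrow population uniformly within bounds
#'
#' @param space a [fcedn_search_space()]-style data.frame with `lower`,
#'   `upper` columns.
#' @param cfg an [optimizer_config()].
#' @return a `spasa_population`: positions matrix (one row per sparrow),
#'   fitness vector (NA until evaluated), elitist best record.
#' @export
initialize_population <- function(space, cfg = optimizer_config()) {
  k <- nrow(space)
  pos <- with_seed(cfg$seed, {
    matrix(runif(cfg$population_size * k), cfg$population_size, k)
  })
  pos <- sweep(sweep(pos, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  structure(
    list(positions = pos, fitness = rep(NA_real_, cfg$population_size),
         best_position = NULL, best_fitness = -Inf, iteration = 0L),
    class = "spasa_population"
  )
}

#' @export
print.spasa_population <- function(x, ...) {
  cat(sprintf(
    "spasa_population: %d sparrows, %d genes, iteration %d, best fitness %s\n",
    nrow(x$positions), ncol(x$positions), x$iteration,
    format(x$best_fitness, digits = 6)
  ))
  invisible(x)
}

clip_positions <- function(pos, space) {
  for (j in seq_len(ncol(pos))) {
    pos[, j] <- clip(pos[, j], space$lower[j], space$upper[j])
  }
  pos
}

# The update rules act on per-gene normalized coordinates in [0, 1] so
# step sizes are scale-free across genes with very different ranges
# (kernel counts span 180 units, drop rates 0.2).  Mapping back clips
# to the gene bounds.
normalize_positions <- function(pos, space) {
  sweep(sweep(pos, 2, space$lower), 2, space$upper - space$lower, "/")
}

denormalize_positions <- function(z, space) {
  z <- pmin(pmax(z, 0), 1)
  sweep(sweep(z, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
}

# anchor for follower moves: the elitist best-ever position when one
# has been recorded, otherwise the current rank-1 sparrow
anchor_position <- function(pop, space, ranks) {
  if (!is.null(pop$best_position)) {
    as.vector(normalize_positions(matrix(pop$best_position, 1), space))
  } else {
    normalize_positions(pop$positions, space)[which.min(ranks), ]
  }
}

safe_objective <- function(objective) {
  function(x) {
    v <- tryCatch(objective(x), error = function(e) -Inf)
    if (!is.finite(v)) -Inf else v
  }
}

# ranks: 1 = fittest; unevaluated (NA) or -Inf fitness sorts last.
fitness_ranks <- function(fitness) {
  fitness[is.na(fitness)] <- -Inf
  rank(-fitness, ties.method = "first")
}

#' Producer update rule
#'
#' The fittest `producer_fraction` of sparrows move: with no alarm
#' (random value below the safety threshold) they drift by the
#' rank-dependent exponential factor `exp(-i / (alpha * iter_max))`;
#' otherwise they take a Gaussian step.  Positions are clipped to
#' bounds.  Uses the current RNG stream; wrap in a seeded context for
#' reproducibility.
#'
#' @param pop a `spasa_population` with evaluated fitness.
#' @param cfg an [optimizer_config()].
#' @param space the search space.
#' @param iter_max horizon used by the drift schedule (default the
#'   config's iteration count).
#' @return the updated population (fitness left as last evaluated;
#'   ranks are always computed from the most recent evaluation).
#' @export
producer_update <- function(pop, cfg, space, iter_max = cfg$iterations) {
  n <- nrow(pop$positions)
  ranks <- fitness_ranks(pop$fitness)
  n_prod <- max(1L, round(cfg$producer_fraction * n))
  r2 <- runif(1)
  alpha <- runif(1, 0.01, 1)
  z <- normalize_positions(pop$positions, space)
  for (i in which(ranks <= n_prod)) {
    if (r2 < cfg$safety_threshold) {
      z[i, ] <- z[i, ] * exp(-ranks[i] / (alpha * max(iter_max, 1)))
    } else {
      z[i, ] <- z[i, ] + rnorm(ncol(z))
    }
  }
  pop$positions <- denormalize_positions(z, space)
  pop
}

#' Scrounger update rule
#'
#' Non-producers follow the best producer: the worse half jump towards
#' its area by `X_P + Q . |X_i - X_P| . exp((X_worst - X_i) / i^2)` with
#' per-gene Gaussian `Q`, while the better half contract to
#' `X_P + |X_i - X_P| . A / 2` with sparse random signs `A`.
#'
#' @inheritParams producer_update
#' @return the updated population.
#' @export
scrounger_update <- function(pop, cfg, space, iter_max = cfg$iterations) {
  n <- nrow(pop$positions)
  d <- ncol(pop$positions)
  ranks <- fitness_ranks(pop$fitness)
  n_prod <- max(1L, round(cfg$producer_fraction * n))
  z <- normalize_positions(pop$positions, space)
  zp <- anchor_position(pop, space, ranks)         # best producer (elitist)
  zw <- z[which.max(ranks), ]                      # worst sparrow
  for (i in which(ranks > n_prod)) {
    if (ranks[i] > n / 2) {
      # hungry scroungers fly towards the producer's area: Gaussian
      # per-gene magnitudes of the current offset, modulated by the
      # distance to the worst position
      z[i, ] <- zp + rnorm(d) * abs(z[i, ] - zp) *
        exp((zw - z[i, ]) / ranks[i]^2)
    } else {
      # sparse sign pattern: inactive genes copy the anchor exactly, so
      # single-gene refinements are possible without disturbing the rest
      a <- sample(c(-1, 1), d, replace = TRUE) * (runif(d) < runif(1, 1 / d, 1))
      z[i, ] <- zp + abs(z[i, ] - zp) * a / 2
    }
  }
  pop$positions <- denormalize_positions(z, space)
  pop
}

#' Scout (danger-response) update rule
#'
#' A random `scout_fraction` of sparrows react to danger: sparrows away
#' from the global best step towards it scaled by a Gaussian factor;
#' a sparrow at the best position steps relative to the worst.
#'
#' @inheritParams producer_update
#' @return the updated population.
#' @export
scout_update <- function(pop, cfg, space, iter_max = cfg$iterations) {
  n <- nrow(pop$positions)
  n_scout <- round(cfg$scout_fraction * n)
  if (n_scout < 1) return(pop)
  d <- ncol(pop$positions)
  ranks <- fitness_ranks(pop$fitness)
  z <- normalize_positions(pop$positions, space)
  zb <- anchor_position(pop, space, ranks)
  zw <- z[which.max(ranks), ]
  fit <- pop$fitness
  fit[is.na(fit)] <- -Inf
  fb <- max(fit); fw <- min(fit)
  rng <- space$upper - space$lower
  is_int <- if (is.null(space$integer)) rep(FALSE, d) else space$integer
  scouts <- sample(n, n_scout)
  for (i in scouts) {
    if (fit[i] < fb) {
      if (any(is_int) && runif(1) < 0.5) {
        # mixed-integer adaptation: probe a lattice neighbour of the
        # best position (+-1 unit in one integer gene)
        j <- sample(d, 1)
        step <- if (is_int[j]) 1 / rng[j] else 10^runif(1, -3, -1)
        z[i, ] <- zb
        z[i, j] <- zb[j] + sample(c(-1, 1), 1) * step
      } else {
        act <- runif(d) < runif(1, 1 / d, 1)
        z[i, ] <- zb + rnorm(d) * abs(z[i, ] - zb) * act
      }
    } else {
      k <- runif(1, -1, 1)
      z[i, ] <- z[i, ] + k * abs(z[i, ] - zw) / (abs(fb - fw) + 1e-50)
    }
  }
  pop$positions <- denormalize_positions(z, space)
  pop
}

evaluate_population <- function(pop, objective) {
  for (i in seq_len(nrow(pop$positions))) {
    pop$fitness[i] <- objective(pop$positions[i, ])
  }
  ix <- which.max(pop$fitness)
  if (length(ix) && pop$fitness[ix] > pop$best_fitness) {
    pop$best_fitness <- pop$fitness[ix]
    pop$best_position <- pop$positions[ix, ]
  }
  pop
}

#' Sparrow search optimisation
#'
#' Maximises `objective` over the bounded `space`: initialise uniformly,
#' then iterate producer, scrounger and scout updates, re-evaluating
#' after each full sweep.  The best-so-far record is elitist, so the
#' returned trace is monotone non-decreasing.  An objective that errors
#' or returns a non-finite value scores `-Inf` and the run continues.
#'
#' @param objective function(gene vector) -> fitness to maximise.
#' @param space a data.frame with `lower`/`upper` (and optionally
#'   `integer`) per gene, e.g. [fcedn_search_space()].
#' @param cfg an [optimizer_config()].
#' @return a `spasa_fit`: `best_position`, `best_fitness`, `trace`
#'   (best fitness per iteration, element 0 = after initialisation),
#'   final `population`, `evaluations` count.
#' @examples
#' space <- data.frame(lower = rep(-5, 5), upper = rep(5, 5))
#' fit <- spasa(function(x) -sum(x^2), space,
#'              optimizer_config(population_size = 20, iterations = 30))
#' fit$best_fitness
#' @export
spasa <- function(objective, space, cfg = optimizer_config()) {
  obj <- safe_objective(objective)
  n_eval <- 0L
  counting_obj <- function(x) {
    n_eval <<- n_eval + 1L
    obj(x)
  }
  pop <- initialize_population(space, cfg)
  trace <- numeric(cfg$iterations + 1L)
  with_seed(derive_seed(cfg$seed, 1L), {
    pop <- evaluate_population(pop, counting_obj)
    trace[1] <- pop$best_fitness
    for (it in seq_len(cfg$iterations)) {
      pop <- producer_update(pop, cfg, space)
      pop <- scrounger_update(pop, cfg, space)
      pop <- scout_update(pop, cfg, space)
      pop <- evaluate_population(pop, counting_obj)
      # elitist reinsertion: the best-ever position replaces the worst
      if (!is.null(pop$best_position)) {
        worst <- which.min(pop$fitness)
        pop$positions[worst, ] <- pop$best_position
        pop$fitness[worst] <- pop$best_fitness
      }
      pop$iteration <- it
      trace[it + 1L] <- pop$best_fitness
    }
  })
  structure(
    list(best_position = pop$best_position, best_fitness = pop$best_fitness,
         trace = trace, population = pop, evaluations = n_eval, config = cfg),
    class = "spasa_fit"
  )
}

#' @export
print.spasa_fit <- function(x, ...) {
  cat(sprintf(
    "spasa fit: best fitness %s after %d iterations (%d evaluations)\n",
    format(x$best_fitness, digits = 6), x$config$iterations, x$evaluations
  ))
  invisible(x)
}

#' @export
plot.spasa_fit <- function(x, ...) {
  graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "s",
                 xlab = "iteration", ylab = "best fitness",
                 main = "sparrow search convergence", ...)
  invisible(x)
}

#' Fitness context for architecture search
#'
#' Bundles the data and training settings used by [evaluate_fitness()]:
#' candidate networks are trained on `train_images` and scored on
#' `eval_images` by the sum of per-image smoothed Jaccard coefficients.
#'
#' @param train_images,eval_images lists of masked `lesion_image`s.
#' @param train_cfg a [train_config()] for the per-candidate training.
#' @param epsilon positive smoothing constant of the fitness.
#' @param cache logical: memoise fitness by the rounded integer genome
#'   so identical architectures are not retrained.
#' @return a `fitness_context`.
#' @export
fitness_context <- function(train_images, eval_images,
                            train_cfg = train_config(epochs = 5L,
                                                     max_images = 12L),
                            epsilon = 1, cache = TRUE) {
  lf_check(is_scalar_num(epsilon) && epsilon > 0, "epsilon", "must be > 0")
  lf_check(length(train_images) >= 1, "train_images", "must be nonempty")
  lf_check(length(eval_images) >= 1, "eval_images", "must be nonempty")
  structure(
    list(train_images = train_images, eval_images = eval_images,
         train_cfg = train_cfg, epsilon = epsilon,
         cache = if (cache) new.env(parent = emptyenv()) else NULL),
    class = "fitness_context"
  )
}

# Project pool/unpool genes to the nearest spatially feasible
# configuration: products must match and divide the input size.
# Candidate products are enumerated over the [2,3] pool range.
project_feasible <- function(genes, layout, input_size) {
  pool_ix <- which(layout$field == "pool_size" & layout$role == "max_pool")
  unpool_ix <- which(layout$field == "pool_size" & layout$role == "unpool")
  cand <- expand.grid(p1 = 2:3, p2 = 2:3)
  cand <- cand[(input_size %% (cand$p1 * cand$p2)) == 0, , drop = FALSE]
  if (nrow(cand) == 0) lf_stop(sprintf(
    "no feasible pooling configuration for input size %d", input_size
  ))
  cur <- round(genes[c(pool_ix, unpool_ix)])
  dists <- apply(cand, 1, function(r) sum((cur - rep(c(r[1], r[2]), 2))^2))
  best <- cand[which.min(dists), ]
  genes[pool_ix] <- c(best$p1, best$p2)
  genes[unpool_ix] <- c(best$p1, best$p2)
  genes
}

#' Smoothed-Jaccard fitness of one hyperparameter vector
#'
#' Decodes the genome, builds and trains the FCEDN on the context's
#' training images, then returns the sum over evaluation images of the
#' smoothed Jaccard between predicted and true masks:
#' `sum_m (eps + |I_m|) / (eps + |truth_m| + |pred_m| - |I_m|)`.
#' Pool/unpool genes are first projected to the nearest spatially
#' feasible configuration for the image size (constraint handling).
#'
#' @param position numeric gene vector.
#' @param ctx a [fitness_context()].
#' @param layout the gene layout (default [default_layout()]).
#' @return fitness in (0, number of evaluation images\].
#' @export
evaluate_fitness <- function(position, ctx, layout = default_layout()) {
  h <- dim(ctx$train_images[[1]]$pixels)[1]
  w <- dim(ctx$train_images[[1]]$pixels)[2]
  space <- fcedn_search_space(layout)
  genes <- repair_genes(position, space)
  genes <- project_feasible(genes, layout, min(h, w))
  key <- paste(signif(genes, 8), collapse = ",")
  if (!is.null(ctx$cache) && !is.null(ctx$cache[[key]])) {
    return(ctx$cache[[key]])
  }
  spec <- decode_network(genes, space, layout, input_height = h,
                         input_width = w)
  model <- build_network(spec, seed = ctx$train_cfg$seed, eps = ctx$epsilon)
  model <- train_network(model, ctx$train_images, ctx$train_cfg)
  fit <- sum(vapply(ctx$eval_images, function(im) {
    pred <- predict_mask(model, im)
    jaccard(pred, im$mask, eps = ctx$epsilon)
  }, numeric(1)))
  if (!is.null(ctx$cache)) ctx$cache[[key]] <- fit
  fit
}
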