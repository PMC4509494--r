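# Swarm core: discrete particle swarm over K-subsets of SNP indices, with
# opposition-based learning, counter-driven dynamic inertia, and an
# exhaustive post-search over the most visited SNPs.

#' Swarm configuration
#'
#' Collects the optimizer's tunables. Defaults follow the published PSO
#' practice for this problem: 100 particles, 100 iterations, acceleration
#' factors C1 = C2 = 2, static inertia 0.65 (used throughout by the plain
#' `pso` variant and as the degenerate-counter fallback of the dynamic
#' weight), and a post-search over the 10 most visited SNPs.
#'
#' @param particles Number of particles P (>= 1).
#' @param iterations Number of iterations T (>= 1); initialization counts as
#'   iteration 1.
#' @param order Interaction order K (number of SNPs per particle).
#' @param c1,c2 Acceleration factors weighting the pull toward the particle's
#'   own best and the swarm best.
#' @param inertia Static inertia weight W.
#' @param top_n Number of top-ranked SNPs searched exhaustively by the
#'   post-procedure (must be >= `order`).
#' @param variant `"oblpso"` (opposition-based learning, dynamic inertia,
#'   post-search) or `"pso"` (plain baseline: static inertia, no opposition,
#'   no post-search).
#' @param seed Optional integer seed for the single RNG stream driving
#'   initialization, velocity draws, range resampling and duplicate
#'   resolution.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(particles = 100, iterations = 100, order = 2,
                         c1 = 2, c2 = 2, inertia = 0.65, top_n = 10,
                         variant = c("oblpso", "pso"), seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(particles >= 1, iterations >= 1, order >= 1,
            c1 >= 0, c2 >= 0, top_n >= order)
  structure(
    list(particles = as.integer(particles),
         iterations = as.integer(iterations),
         order = as.integer(order), c1 = c1, c2 = c2,
         inertia = inertia, top_n = as.integer(top_n),
         variant = variant, seed = seed),
    class = "swarm_config"
  )
}

#' Dynamic inertia weight from pbest occupancy counters
#'
#' W = (max(count) - count\[snp\]) / (max(count) - min(count)): a SNP that
#' appears often in personal bests (a suspected signal SNP) gets a small
#' weight, so its particle exploits locally; a rarely seen SNP gets a weight
#' near 1 and keeps exploring. When all counters are equal the ratio is
#' undefined and the static `fallback` inertia is returned.
#'
#' @param count Integer vector of cumulative pbest occurrence counts, one
#'   per SNP.
#' @param snp 1-based index of the SNP in the particle's pbest.
#' @param fallback Static inertia used when max(count) == min(count).
#' @return A weight in \[0, 1\] (or `fallback`).
#' @export
dynamic_inertia <- function(count, snp, fallback = 0.65) {
  if (any(snp < 1L | snp > length(count))) {
    stop("snp index out of range", call. = FALSE)
  }
  mx <- max(count)
  mn <- min(count)
  if (mx == mn) return(rep(fallback, length(snp))[seq_along(snp)])
  (mx - count[snp]) / (mx - mn)
}

#' Velocity update
#'
#' Per dimension k: v' = W_k v_k + C1 r1 (pbest_k - position_k) +
#' C2 r2 (gbest_k - position_k), with r1, r2 fresh uniform(0, 1) draws per
#' dimension. Any component falling outside the velocity domain
#' \[1 - M, M - 1\] is replaced by a uniform draw from that interval.
#'
#' @param position,pbest,gbest Integer vectors of K SNP indices.
#' @param velocity Numeric vector of K current velocities.
#' @param weights Inertia weight(s), recycled over dimensions.
#' @param c1,c2 Acceleration factors.
#' @param m Number of SNPs M (defines the velocity domain).
#' @param r1,r2 Optional fixed random factors (recycled over dimensions);
#'   by default drawn fresh from U(0, 1) per dimension.
#' @return Numeric vector of K updated velocities, all within
#'   \[1 - M, M - 1\].
#' @export
update_velocity <- function(position, velocity, pbest, gbest, weights,
                            c1 = 2, c2 = 2, m, r1 = NULL, r2 = NULL) {
  k <- length(position)
  if (is.null(r1)) r1 <- runif(k)
  if (is.null(r2)) r2 <- runif(k)
  v <- weights * velocity +
    c1 * r1 * (pbest - position) +
    c2 * r2 * (gbest - position)
  lo <- 1 - m
  hi <- m - 1
  bad <- which(v < lo | v > hi)
  if (length(bad)) v[bad] <- runif(length(bad), lo, hi)
  v
}

#' Position update
#'
#' Per dimension: the provisional index is position_k + v_k, truncated
#' toward zero if it lies in \[1, M\], otherwise replaced by a uniform random
#' integer in \[1, M\]. Dimensions that collide on the same SNP afterwards are
#' resampled uniformly from the SNPs not already present, so the returned
#' position always holds K distinct indices.
#'
#' @param position Integer vector of K distinct SNP indices.
#' @param velocity Numeric vector of K velocities (already range-checked).
#' @param m Number of SNPs M.
#' @return Integer vector of K distinct indices in \[1, M\].
#' @export
update_position <- function(position, velocity, m) {
  s <- position + velocity
  out <- integer(length(s))
  for (k in seq_along(s)) {
    out[k] <- if (s[k] >= 1 && s[k] <= m) {
      as.integer(trunc(s[k]))
    } else {
      sample.int(m, 1L)
    }
  }
  resolve_duplicates(out, m)
}

# Internal: resample duplicated dimensions from the unused indices.
resolve_duplicates <- function(position, m) {
  while (anyDuplicated(position)) {
    k <- which(duplicated(position))[1L]
    free <- setdiff(seq_len(m), position)
    position[k] <- free[sample.int(length(free), 1L)]
  }
  position
}

#' Opposite position
#'
#' Opposition-based learning maps each selected index to its mirror in the
#' SNP index range: 1 + M - position_k per dimension. The map is an
#' involution, so distinct indices stay distinct.
#'
#' @param position Integer vector of SNP indices.
#' @param m Number of SNPs M.
#' @return Integer vector of mirrored indices.
#' @export
#' @examples
#' opposite_position(c(3, 97), m = 100)  # 98, 4
opposite_position <- function(position, m) {
  as.integer(1L + m - position)
}

#' Initialize a swarm
#'
#' Positions are uniform random K-subsets of \[1, M\]; velocities are uniform
#' in \[1 - M, M - 1\]; each particle's pbest is its initial position with its
#' evaluated MI; gbest is the best pbest (first on ties); the per-SNP
#' occupancy counters tally the initial pbests (iteration 1's increment).
#'
#' @param data A SNP dataset tibble.
#' @param config A [swarm_config()]; its `seed`, if set, seeds the stream.
#' @return A list of class `swarm_state`: integer matrices `position`,
#'   `pbest` (P x K), numeric matrix `velocity`, vector `pbest_mi`, `gbest`,
#'   `gbest_mi`, integer `count` (length M), `iteration` (= 1), and `trace`
#'   (gbest MI per iteration so far).
#' @export
initialize_swarm <- function(data, config = swarm_config()) {
  data <- validate_snp_data(data)
  .initialize_swarm(geno_matrix(data), data$phenotype, config)
}

.initialize_swarm <- function(geno, pheno, config, cache = NULL) {
  m <- ncol(geno)
  p <- config$particles
  k <- config$order
  if (k >= m) stop("interaction order K must be below the SNP count M",
                   call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  position <- do.call(rbind, lapply(seq_len(p), function(i) sample.int(m, k)))
  velocity <- matrix(runif(p * k, 1 - m, m - 1), nrow = p)
  pbest_mi <- vapply(seq_len(p), function(i) {
    swarm_mi(geno, pheno, position[i, ], cache)
  }, numeric(1))
  best <- which.max(pbest_mi)
  state <- list(
    position = position, velocity = velocity,
    pbest = position, pbest_mi = pbest_mi,
    gbest = position[best, ], gbest_mi = pbest_mi[best],
    count = tabulate(position, nbins = m),
    iteration = 1L, trace = pbest_mi[best]
  )
  class(state) <- "swarm_state"
  state
}

# Internal: MI with per-run memoisation (positions recur heavily late in a
# run; the cache is keyed by the sorted index set).
swarm_mi <- function(geno, pheno, idx, cache = NULL) {
  if (is.null(cache)) {
    return(mi_from_counts(cell_counts(geno, pheno, idx)))
  }
  key <- paste(sort.int(idx), collapse = ":")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- mi_from_counts(cell_counts(geno, pheno, idx))
  cache[[key]] <- val
  val
}

#' Advance a swarm by one iteration
#'
#' One full update: per particle, inertia weights (dynamic for the `oblpso`
#' variant, static for `pso`), velocity and position updates, then the pbest
#' update — against the new position and, for `oblpso`, its opposite — with
#' ties retaining the previous pbest (then preferring the position over its
#' opposite). Afterwards gbest is replaced only by a strictly better pbest,
#' the occupancy counters accrue every SNP occurrence in every pbest, and
#' the iteration counter and gbest trace advance.
#'
#' @param state A `swarm_state`.
#' @param data The SNP dataset the swarm is searching.
#' @param config The [swarm_config()] in force.
#' @return The updated `swarm_state`.
#' @export
step_swarm <- function(state, data, config = swarm_config()) {
  data <- validate_snp_data(data)
  .step_swarm(state, geno_matrix(data), data$phenotype, config)
}

.step_swarm <- function(state, geno, pheno, config, cache = NULL) {
  m <- ncol(geno)
  p <- config$particles
  k <- config$order
  opp <- config$variant == "oblpso"
  for (i in seq_len(p)) {
    w <- if (opp) {
      dynamic_inertia(state$count, state$pbest[i, ], fallback = config$inertia)
    } else {
      rep(config$inertia, k)
    }
    v <- update_velocity(state$position[i, ], state$velocity[i, ],
                         state$pbest[i, ], state$gbest, w,
                         c1 = config$c1, c2 = config$c2, m = m)
    pos <- update_position(state$position[i, ], v, m)
    state$velocity[i, ] <- v
    state$position[i, ] <- pos
    upd <- pbest_challenge(geno, pheno, pos, state$pbest[i, ],
                           state$pbest_mi[i], m, opposition = opp,
                           cache = cache)
    state$pbest[i, ] <- upd$pbest
    state$pbest_mi[i] <- upd$mi
  }
  best <- which.max(state$pbest_mi)
  if (state$pbest_mi[best] > state$gbest_mi) {
    state$gbest <- state$pbest[best, ]
    state$gbest_mi <- state$pbest_mi[best]
  }
  state$count <- state$count + tabulate(state$pbest, nbins = m)
  state$iteration <- state$iteration + 1L
  state$trace <- c(state$trace, state$gbest_mi)
  state
}

#' Challenge a particle's personal best
#'
#' Sets pbest to the fittest of the current position, its opposite (when
#' opposition-based learning is on), and the previous pbest. Exact ties keep
#' the previous pbest; between the position and its opposite, the position
#' wins.
#'
#' @param data The SNP dataset.
#' @param position Current position (K distinct indices).
#' @param pbest Previous personal best.
#' @param pbest_mi Its MI, if already known (avoids re-evaluation).
#' @param opposition Evaluate the opposite position too?
#' @return A list with elements `pbest` and `mi`.
#' @export
update_pbest <- function(data, position, pbest, pbest_mi = NULL,
                         opposition = TRUE) {
  data <- validate_snp_data(data)
  geno <- geno_matrix(data)
  if (is.null(pbest_mi)) pbest_mi <- swarm_mi(geno, data$phenotype, pbest)
  pbest_challenge(geno, data$phenotype, position, pbest, pbest_mi,
                  ncol(geno), opposition = opposition)
}

pbest_challenge <- function(geno, pheno, position, pbest, pbest_mi, m,
                            opposition = TRUE, cache = NULL) {
  mi_pos <- swarm_mi(geno, pheno, position, cache)
  mi_opp <- if (opposition) {
    swarm_mi(geno, pheno, opposite_position(position, m), cache)
  } else {
    -Inf
  }
  val <- max(mi_pos, mi_opp, pbest_mi)
  if (pbest_mi >= val) {
    list(pbest = pbest, mi = pbest_mi)
  } else if (mi_pos >= val) {
    list(pbest = position, mi = mi_pos)
  } else {
    list(pbest = opposite_position(position, m), mi = mi_opp)
  }
}

#' Update the swarm best from the personal bests
#'
#' Replaces gbest by the fittest pbest only when its MI strictly exceeds the
#' current gbest MI (ties keep gbest), then accrues the occupancy counters
#' with every SNP occurrence in every pbest. Exposed for stepwise use;
#' [step_swarm()] already performs it.
#'
#' @param state A `swarm_state` whose pbests are up to date.
#' @return The updated `swarm_state` (gbest, counters).
#' @export
update_gbest <- function(state) {
  best <- which.max(state$pbest_mi)
  if (state$pbest_mi[best] > state$gbest_mi) {
    state$gbest <- state$pbest[best, ]
    state$gbest_mi <- state$pbest_mi[best]
  }
  state$count <- state$count + tabulate(state$pbest, nbins = length(state$count))
  state
}

#' Exhaustive post-search over the most visited SNPs
#'
#' Ranks all SNPs by their cumulative pbest occupancy counter (ties broken by
#' ascending index), takes the `top_n` most visited as the highly suspected
#' set, evaluates every K-subset of it, and returns the swarm best unless
#' some subset attains strictly higher MI — in which case the best such
#' subset (first encountered on ties) becomes the answer. The result can
#' therefore never have lower MI than the swarm best.
#'
#' @param state A finished `swarm_state`.
#' @param data The SNP dataset.
#' @param config The [swarm_config()] in force (supplies `top_n` and
#'   `order`).
#' @return A list with `snp_set` (K sorted indices), `mi`, `improved`
#'   (logical: did the post-search beat the swarm best?), and `ranking`
#'   (integer vector of all SNPs ordered by decreasing counter).
#' @export
postprocess_swarm <- function(state, data, config = swarm_config()) {
  data <- validate_snp_data(data)
  .postprocess_swarm(state, geno_matrix(data), data$phenotype, config)
}

.postprocess_swarm <- function(state, geno, pheno, config, cache = NULL) {
  m <- length(state$count)
  k <- config$order
  if (config$top_n < k) stop("top_n must be at least the order K",
                             call. = FALSE)
  ranking <- order(-state$count, seq_len(m))
  top <- ranking[seq_len(min(config$top_n, m))]
  sets <- combn(top, k)
  best_set <- state$gbest
  best_mi <- state$gbest_mi
  improved <- FALSE
  for (j in seq_len(ncol(sets))) {
    mi <- swarm_mi(geno, pheno, sets[, j], cache)
    if (mi > best_mi) {
      best_mi <- mi
      best_set <- sets[, j]
      improved <- TRUE
    }
  }
  list(snp_set = sort.int(best_set), mi = best_mi, improved = improved,
       ranking = ranking)
}
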