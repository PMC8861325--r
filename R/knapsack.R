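#' Build a 0/1 knapsack instance from SDFMs
#'
#' Motif selection is cast as a 0/1 knapsack: maximize total value
#' `V = sum v_i x_i` subject to `W = sum w_i x_i <= C`, `x_i` binary. By
#' default a module's value is the number of its targets annotated in the
#' disease-gene table (strategy `"disease_count"`; alternative
#' `"relevance_sum"` sums the relevance scores of annotated targets), its
#' weight is its node count, and the capacity is `capacity_frac` times the
#' total weight. All choices are recorded in the instance's `provenance`.
#'
#' @param sdfms an `sdfm_table` (see [module_significance()]).
#' @param disease disease-gene data.frame (`gene`, `relevance_score`,
#'   `n_evidence`).
#' @param strategy `"disease_count"` or `"relevance_sum"`.
#' @param capacity_frac fraction of total weight in (0, 1] (default 0.5).
#' @return list of class `knapsack_instance`: `items` (data.frame `module`,
#'   `value`, `weight`), `capacity`, `n`, `provenance`.
#' @export
build_instance <- function(sdfms, disease,
                           strategy = c("disease_count", "relevance_sum"),
                           capacity_frac = 0.5) {
  stopifnot(inherits(sdfms, "sdfm_table"))
  strategy <- match.arg(strategy)
  if (nrow(sdfms) == 0L) stop("no SDFMs to build an instance from")
  if (!is.numeric(capacity_frac) || capacity_frac <= 0 || capacity_frac > 1) {
    stop("capacity_frac must lie in (0, 1]")
  }
  if (nrow(disease) == 0L) stop("empty disease table")
  validate_disease_table(disease)
  members <- attr(sdfms, "members")
  value <- vapply(members, function(mod) {
    hit <- mod$targets %in% disease$gene
    if (strategy == "disease_count") {
      sum(hit)
    } else {
      sum(disease$relevance_score[match(mod$targets[hit], disease$gene)])
    }
  }, numeric(1))
  weight <- vapply(members, function(mod) {
    length(mod$components) + length(mod$targets)
  }, numeric(1))
  capacity <- capacity_frac * sum(weight)
  structure(
    list(
      items = data.frame(module = sdfms$module, value = value,
                         weight = weight),
      capacity = capacity, n = nrow(sdfms),
      provenance = list(value_strategy = strategy,
                        weight_strategy = "node_count",
                        capacity_frac = capacity_frac)
    ),
    class = "knapsack_instance"
  )
}

#' Construct a knapsack instance from raw vectors
#'
#' @param value,weight aligned numeric vectors (`value >= 0`, `weight > 0`).
#' @param capacity positive capacity.
#' @return a `knapsack_instance`.
#' @export
knapsack_instance <- function(value, weight, capacity) {
  stopifnot(length(value) == length(weight), length(value) >= 1L)
  if (any(value < 0)) stop("values must be non-negative")
  if (any(weight <= 0)) stop("weights must be positive")
  if (capacity <= 0) stop("capacity must be positive")
  structure(
    list(items = data.frame(module = seq_along(value), value = value,
                            weight = weight),
         capacity = capacity, n = length(value),
         provenance = list(value_strategy = "raw")),
    class = "knapsack_instance"
  )
}

knapsack_solution <- function(inst, x) {
  x <- as.integer(x)
  V <- sum(inst$items$value * x)
  W <- sum(inst$items$weight * x)
  if (W > inst$capacity + 1e-9) stop("internal error: infeasible solution")
  structure(list(x = x, V = V, W = W, capacity = inst$capacity),
            class = "knapsack_solution")
}

#' Exact 0/1 knapsack solver (test oracle)
#'
#' Dynamic programming over integer weights; weights that are integral
#' within 1e-6 are rounded, otherwise the solver enumerates all subsets
#' (refused above n = 20 non-integral items — the oracle is meant for small
#' instances).
#'
#' @param inst a `knapsack_instance`.
#' @return a `knapsack_solution` with provably optimal `V`.
#' @export
solve_exact <- function(inst) {
  stopifnot(inherits(inst, "knapsack_instance"))
  v <- inst$items$value
  w <- inst$items$weight
  n <- inst$n
  integral <- all(abs(w - round(w)) < 1e-6) &&
    abs(inst$capacity - floor(inst$capacity + 1e-9)) < 1 # cap floor is fine
  if (integral && sum(round(w)) < 1e7) {
    wi <- as.integer(round(w))
    C <- as.integer(floor(inst$capacity + 1e-9))
    best <- matrix(0, nrow = n + 1L, ncol = C + 1L)
    for (i in seq_len(n)) {
      prev <- best[i, ]
      cur <- prev
      if (wi[i] <= C) {
        take_idx <- (wi[i] + 1L):(C + 1L)
        cand <- prev[take_idx - wi[i]] + v[i]
        cur[take_idx] <- pmax(prev[take_idx], cand)
      }
      best[i + 1L, ] <- cur
    }
    # backtrack
    x <- integer(n)
    cap <- C + 1L
    for (i in n:1) {
      if (best[i + 1L, cap] > best[i, cap] + 1e-12) {
        x[i] <- 1L
        cap <- cap - wi[i]
      }
    }
    return(knapsack_solution(inst, x))
  }
  if (n > 20L) stop("exact solver refuses n > 20 with non-integral weights")
  best_V <- -Inf
  best_x <- integer(n)
  for (mask in 0:(2^n - 1)) {
    x <- as.integer(bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L))
    W <- sum(w * x)
    if (W > inst$capacity + 1e-12) next
    V <- sum(v * x)
    if (V > best_V + 1e-12) {
      best_V <- V
      best_x <- x
    }
  }
  knapsack_solution(inst, best_x)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow common GA practice for 0/1 knapsacks: binary
#' chromosomes, roulette-wheel (fitness-proportional) selection, two-point
#' crossover with probability 0.8, per-bit mutation at rate 1/n, one elite
#' individual carried over each generation.
#'
#' @param population_size even population size (default 100).
#' @param generations generation budget (default 200).
#' @param crossover_prob two-point crossover probability (default 0.8).
#' @param mutation_prob per-bit mutation probability; `NULL` means 1/n.
#' @param elitism number of elites preserved (default 1).
#' @param stagnation stop after this many generations without improvement
#'   (default 50).
#' @param seed integer RNG seed.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = 100L, generations = 200L,
                      crossover_prob = 0.8, mutation_prob = NULL,
                      elitism = 1L, stagnation = 50L, seed = 1L) {
  if (population_size %% 2L != 0L) stop("population_size must be even")
  if (crossover_prob < 0 || crossover_prob > 1) stop("crossover_prob in [0,1]")
  if (!is.null(mutation_prob) && (mutation_prob < 0 || mutation_prob > 1)) {
    stop("mutation_prob in [0,1]")
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism = as.integer(elitism),
                 stagnation = as.integer(stagnation),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Remove randomly chosen selected items until the chromosome is feasible.
repair_chromosome <- function(x, w, capacity) {
  W <- sum(w * x)
  while (W > capacity + 1e-12) {
    sel <- which(x == 1L)
    drop <- if (length(sel) == 1L) sel else sel[sample.int(length(sel), 1L)]
    x[drop] <- 0L
    W <- W - w[drop]
  }
  x
}

#' Solve a knapsack instance with a genetic algorithm
#'
#' Chromosomes are binary selection vectors. Each generation: fitness =
#' total value of the (repaired) selection; roulette-wheel selection;
#' two-point crossover; per-bit mutation; infeasible offspring repaired by
#' randomly removing selected items until the capacity holds; the best
#' individual is carried over unchanged (elitism), so the best value is
#' non-decreasing across generations. Stops at the generation budget or
#' after `stagnation` generations without improvement. Deterministic for a
#' fixed seed. The returned solution is always feasible, with `V` and `W`
#' recomputed from the selection vector.
#'
#' @param inst a `knapsack_instance`.
#' @param cfg a [ga_config()].
#' @return a `knapsack_solution`.
#' @export
solve_ga <- function(inst, cfg = ga_config()) {
  stopifnot(inherits(inst, "knapsack_instance"), inherits(cfg, "ga_config"))
  v <- inst$items$value
  w <- inst$items$weight
  n <- inst$n
  C <- inst$capacity
  pmut <- if (is.null(cfg$mutation_prob)) 1 / n else cfg$mutation_prob
  set.seed(cfg$seed)

  pop <- matrix(stats::rbinom(cfg$population_size * n, 1L, 0.5),
                nrow = cfg$population_size)
  for (i in seq_len(cfg$population_size)) {
    pop[i, ] <- repair_chromosome(pop[i, ], w, C)
  }
  fitness <- as.numeric(pop %*% v)
  best_i <- which.max(fitness)
  best_x <- pop[best_i, ]
  best_V <- fitness[best_i]
  stale <- 0L

  for (gen in seq_len(cfg$generations)) {
    # roulette selection (uniform fallback when all fitness is zero)
    probs <- if (sum(fitness) > 0) fitness / sum(fitness) else NULL
    idx <- sample.int(cfg$population_size, cfg$population_size,
                      replace = TRUE, prob = probs)
    newpop <- pop[idx, , drop = FALSE]
    # two-point crossover on consecutive pairs
    for (k in seq(1L, cfg$population_size - 1L, by = 2L)) {
      if (stats::runif(1) < cfg$crossover_prob && n >= 2L) {
        pts <- sort(sample.int(n, 2L))
        seg <- pts[1L]:pts[2L]
        tmp <- newpop[k, seg]
        newpop[k, seg] <- newpop[k + 1L, seg]
        newpop[k + 1L, seg] <- tmp
      }
    }
    # per-bit mutation
    flips <- matrix(stats::runif(cfg$population_size * n) < pmut,
                    nrow = cfg$population_size)
    newpop[flips] <- 1L - newpop[flips]
    # repair and evaluate
    for (i in seq_len(cfg$population_size)) {
      newpop[i, ] <- repair_chromosome(newpop[i, ], w, C)
    }
    fit_new <- as.numeric(newpop %*% v)
    # elitism: overwrite the worst with the best-ever
    if (cfg$elitism > 0L) {
      worst <- order(fit_new)[seq_len(cfg$elitism)]
      for (e in worst) {
        newpop[e, ] <- best_x
        fit_new[e] <- best_V
      }
    }
    pop <- newpop
    fitness <- fit_new
    gen_best <- which.max(fitness)
    if (fitness[gen_best] > best_V + 1e-12) {
      best_V <- fitness[gen_best]
      best_x <- pop[gen_best, ]
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$stagnation) break
    }
  }
  knapsack_solution(inst, best_x)
}

#' Promote selected SDFMs to functional response motifs (FRMs)
#'
#' @param sdfms the `sdfm_table` the instance was built from.
#' @param sol a `knapsack_solution` over the same modules.
#' @return the selected rows as an `sdfm_table` (members carried over),
#'   with a `provenance` attribute naming the selection. Warns when the
#'   selection is empty.
#' @export
frms_from_solution <- function(sdfms, sol) {
  stopifnot(inherits(sdfms, "sdfm_table"), inherits(sol, "knapsack_solution"))
  if (length(sol$x) != nrow(sdfms)) stop("solution does not match SDFM table")
  keep <- which(sol$x == 1L)
  if (length(keep) == 0L) warning("knapsack selected no module")
  out <- sdfms[keep, , drop = FALSE]
  attr(out, "members") <- attr(sdfms, "members")[keep]
  attr(out, "provenance") <- list(V = sol$V, W = sol$W,
                                  capacity = sol$capacity)
  class(out) <- c("sdfm_table", "data.frame")
  rownames(out) <- NULL
  out
}
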