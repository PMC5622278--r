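#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` iff `a` is at least as good in every objective (per its
#' sense) and strictly better in at least one.
#'
#' @param a,b numeric objective vectors of equal length
#' @param senses character vector, "max" or "min" per objective
#' @return logical
#' @export
dominates <- function(a, b, senses) {
  if (length(a) != length(b) || length(a) != length(senses)) {
    stop("objective dimension mismatch")
  }
  sgn <- ifelse(senses == "max", 1, -1)
  d <- sgn * (a - b)
  all(d >= 0) && any(d > 0)
}

#' Non-dominated sorting
#'
#' Assigns every population member a front rank: rank 0 is the
#' non-dominated set; fronts are peeled iteratively.
#'
#' @param objectives matrix, one row per solution
#' @param senses per-column optimisation senses
#' @return integer vector of ranks (0-based)
#' @export
non_dominated_sort <- function(objectives, senses) {
  n <- nrow(objectives)
  if (n == 0) stop("empty population")
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  level <- 0L
  while (length(remaining) > 0) {
    front <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && dominates(objectives[j, ], objectives[i, ], senses)
      }, TRUE))
    }, TRUE)]
    rank[front] <- level
    remaining <- setdiff(remaining, front)
    level <- level + 1L
  }
  rank
}

# crowding distance within one front (larger = more isolated)
crowding_distance <- function(objectives) {
  n <- nrow(objectives)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        d[ord[i]] <- d[ord[i]] + (o[ord[i + 1]] - o[ord[i - 1]]) / rng
      }
    }
  }
  d
}

#' One differential-evolution generation (rand/1/bin)
#'
#' For each parent, three distinct other members form the mutant
#' `x_r1 + F (x_r2 - x_r3)`; binomial crossover with rate `CR` (one
#' coordinate always taken from the mutant) forms the offspring;
#' out-of-bounds coordinates are reflected back into range.
#'
#' @param population matrix, one row per member
#' @param f differential weight
#' @param cr crossover rate
#' @param bounds 2-row matrix (lower; upper) per decision variable
#' @return offspring matrix of the same shape
#' @export
de_generation <- function(population, f, cr, bounds) {
  np <- nrow(population)
  d <- ncol(population)
  if (np < 4) stop("differential evolution needs a population of at least 4")
  off <- population
  for (i in seq_len(np)) {
    r <- sample(setdiff(seq_len(np), i), 3)
    mutant <- population[r[1], ] + f * (population[r[2], ] - population[r[3], ])
    jr <- sample.int(d, 1)
    cross <- stats::runif(d) < cr
    cross[jr] <- TRUE
    child <- ifelse(cross, mutant, population[i, ])
    # reflect into bounds
    for (j in seq_len(d)) {
      lo <- bounds[1, j]; hi <- bounds[2, j]
      span <- hi - lo
      x <- child[j]
      if (span <= 0) { child[j] <- lo; next }
      while (x < lo || x > hi) {
        if (x < lo) x <- lo + (lo - x)
        if (x > hi) x <- hi - (x - hi)
      }
      child[j] <- x
    }
    off[i, ] <- child
  }
  off
}

#' Hypervolume dominated by a front
#'
#' Exact hypervolume with respect to a reference point, for 2 or 3
#' objectives (internally converted to minimisation).
#'
#' @param objectives matrix of front members (rows)
#' @param senses per-column senses
#' @param ref reference point (same orientation as `objectives`)
#' @return scalar hypervolume
#' @export
hypervolume <- function(objectives, senses, ref) {
  sgn <- ifelse(senses == "max", -1, 1)
  pts <- sweep(objectives, 2, sgn, `*`)
  r <- ref * sgn
  pts <- pts[apply(pts, 1, function(p) all(p < r)), , drop = FALSE]
  if (nrow(pts) == 0) return(0)
  d <- ncol(pts)
  if (d == 2) return(hv2(pts, r))
  if (d == 3) {
    z <- sort(unique(pts[, 3]))
    hv <- 0
    zs <- c(z, r[3])
    for (k in seq_along(z)) {
      active <- pts[pts[, 3] <= z[k], 1:2, drop = FALSE]
      hv <- hv + hv2(active, r[1:2]) * (zs[k + 1] - zs[k])
    }
    return(hv)
  }
  stop("hypervolume implemented for 2 or 3 objectives")
}

# 2-D hypervolume (minimisation, all points strictly inside ref)
hv2 <- function(pts, r) {
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  hv <- 0
  best2 <- r[2]
  for (i in seq_len(nrow(pts))) {
    if (pts[i, 2] < best2) {
      hv <- hv + (r[1] - pts[i, 1]) * (best2 - pts[i, 2])
      best2 <- pts[i, 2]
    }
  }
  hv
}

#' Multi-objective optimisation of management decisions
#'
#' Couples non-dominated sorting with differential evolution: each
#' generation's offspring join the parents, the combined population is
#' sorted into fronts, and the next generation is filled front by front with
#' crowding-distance tie-breaks.  The search stops when the front
#' hypervolume changes by less than `tol` (relative) over five consecutive
#' generations, or at the generation budget.
#'
#' @param evaluate function(decision vector) -> numeric objective vector;
#'   must be deterministic
#' @param bounds 2-row matrix (lower; upper) per decision variable, with
#'   column names naming the variables
#' @param senses per-objective "max"/"min"
#' @param pop_size population size (default 40)
#' @param generations generation budget (default 60)
#' @param f,cr differential-evolution weight and crossover rate
#' @param seed RNG seed
#' @param tol relative hypervolume stability tolerance
#' @return list: `front` (data.frame of decisions + objectives, rank 0),
#'   `ranks`, `population`, `objectives`, `generations_run`, `hypervolume`
#' @export
optimise_pareto <- function(evaluate, bounds, senses, pop_size = 40,
                            generations = 60, f = 0.7, cr = 0.9, seed = 1,
                            tol = 1e-3) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  d <- ncol(bounds)
  pop <- sapply(seq_len(d), function(j)
    stats::runif(pop_size, bounds[1, j], bounds[2, j]))
  pop <- matrix(pop, nrow = pop_size)
  colnames(pop) <- colnames(bounds)
  obj <- t(apply(pop, 1, evaluate))
  ref <- ref_point(obj, senses)
  hv_hist <- numeric(0)
  gens <- 0
  for (g in seq_len(generations)) {
    gens <- g
    off <- de_generation(pop, f, cr, bounds)
    obj_off <- t(apply(off, 1, evaluate))
    all_pop <- rbind(pop, off)
    all_obj <- rbind(obj, obj_off)
    rk <- non_dominated_sort(all_obj, senses)
    keep <- integer(0)
    lvl <- 0
    while (length(keep) < pop_size) {
      idx <- which(rk == lvl)
      if (length(keep) + length(idx) <= pop_size) {
        keep <- c(keep, idx)
      } else {
        cd <- crowding_distance(all_obj[idx, , drop = FALSE])
        keep <- c(keep, idx[order(-cd)][seq_len(pop_size - length(keep))])
      }
      lvl <- lvl + 1
    }
    pop <- all_pop[keep, , drop = FALSE]
    obj <- all_obj[keep, , drop = FALSE]
    front_idx <- which(non_dominated_sort(obj, senses) == 0)
    hv <- hypervolume(obj[front_idx, , drop = FALSE], senses, ref)
    hv_hist <- c(hv_hist, hv)
    if (length(hv_hist) >= 6) {
      recent <- utils::tail(hv_hist, 6)
      if (max(abs(diff(recent))) < tol * max(recent, 1e-12)) break
    }
  }
  rk <- non_dominated_sort(obj, senses)
  front_idx <- which(rk == 0)
  front <- data.frame(pop[front_idx, , drop = FALSE],
                      obj[front_idx, , drop = FALSE])
  names(front) <- c(colnames(bounds) %||% paste0("x", seq_len(d)),
                    paste0("obj", seq_len(ncol(obj))))
  list(front = front, ranks = rk, population = pop, objectives = obj,
       generations_run = gens,
       hypervolume = utils::tail(hv_hist, 1))
}

# reference point just outside the worst observed objective values
ref_point <- function(obj, senses) {
  vapply(seq_len(ncol(obj)), function(m) {
    rng <- range(obj[, m])
    pad <- 0.1 * max(diff(rng), 1e-9)
    if (senses[m] == "max") rng[1] - pad else rng[2] + pad
  }, 0)
}

#' Pareto trade-off search over fertiliser management
#'
#' Wraps [optimise_pareto()] around the simulator: the decision variables
#' are the day-of-year and amount of a single fertiliser N application; the
#' objectives are mean annual wheat yield (maximised) and mean annual
#' nitrate leaching and N2O emission (minimised), evaluated over a fixed
#' multi-year weather sample so the surface is deterministic.
#'
#' @param weather weather data.frame (fixed sample)
#' @param base_farm fixture list from [build_fixture_farm()]; its
#'   fertilise_N events are replaced by the decision vector
#' @param bounds 2-row matrix with columns `fert_day` (day of year) and
#'   `fert_amount` (kg N ha-1)
#' @param ... passed to [optimise_pareto()]
#' @return as [optimise_pareto()]
#' @export
optimise_fertiliser <- function(weather, base_farm,
                                bounds = rbind(c(60, 0), c(180, 300)),
                                ...) {
  colnames(bounds) <- c("fert_day", "fert_amount")
  years <- unique(as.integer(format(weather$date, "%Y")))
  evaluate <- function(x) {
    mg <- base_farm$management
    mg <- mg[mg$kind != "fertilise_N", ]
    if (x[2] > 0.5) {
      fert <- data.frame(
        date = as.Date(sprintf("%d-01-01", years)) + round(unname(x[1])) - 1,
        kind = "fertilise_N", amount = unname(x[2]),
        n_form = "ammonium_nitrate", animal = NA, stocking = NA, crop = NA)
      mg <- rbind(mg, fert)
      mg <- mg[order(mg$date), ]
    }
    sim <- run_simulation(base_farm$grid, weather, mg, base_farm$params)
    ny <- length(years)
    c(yield = sum(sim$fluxes$yield) / ny,
      leach = sum(sim$fluxes$n_leached) / ny,
      n2o = sum(sim$fluxes$n2o) / ny)
  }
  optimise_pareto(evaluate, bounds, senses = c("max", "min", "min"), ...)
}
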