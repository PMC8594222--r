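# Genetic-algorithm engines: a real-coded GA for parameter estimation and an
# integer GA for injection-day schedules. Both are elitist (the best evaluated
# individual is never lost) and deterministic given the RNG state.

# Minimize fn over the box [lower, upper] (real-coded, normalized genes).
# SBX-style blend crossover, tournament selection (k = 2), per-gene Gaussian
# mutation, elitism 1. fn receives the de-normalized parameter vector.
.ga_real <- function(fn, lower, upper, pop = 60, generations = 120,
                     pcross = 0.9, pmut = 0.1, log_scale = TRUE) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  lo <- if (log_scale) log10(lower) else lower
  hi <- if (log_scale) log10(upper) else upper
  denorm <- function(g) {
    x <- lo + g * (hi - lo)
    if (log_scale) 10^x else x
  }
  evalg <- function(g) {
    v <- tryCatch(fn(denorm(g)), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  genes <- matrix(stats::runif(pop * d), nrow = pop)
  fit <- apply(genes, 1L, evalg)
  best_i <- which.min(fit)
  best <- list(g = genes[best_i, ], f = fit[best_i])
  trace <- numeric(generations + 1L)
  trace[1L] <- best$f

  for (gen in seq_len(generations)) {
    idx1 <- sample.int(pop, pop, replace = TRUE)
    idx2 <- sample.int(pop, pop, replace = TRUE)
    parents <- ifelse(fit[idx1] <= fit[idx2], idx1, idx2)
    childs <- genes[parents, , drop = FALSE]
    # blend crossover on consecutive pairs
    for (i in seq(1L, pop - 1L, by = 2L)) {
      if (stats::runif(1) < pcross) {
        a <- stats::runif(d, -0.25, 1.25)
        g1 <- childs[i, ]; g2 <- childs[i + 1L, ]
        childs[i, ]      <- a * g1 + (1 - a) * g2
        childs[i + 1L, ] <- a * g2 + (1 - a) * g1
      }
    }
    mut <- matrix(stats::runif(pop * d) < pmut, nrow = pop)
    childs[mut] <- childs[mut] + stats::rnorm(sum(mut), sd = 0.15)
    childs <- pmin(pmax(childs, 0), 1)
    childs[1L, ] <- best$g  # elitism
    fit <- apply(childs, 1L, evalg)
    genes <- childs
    gi <- which.min(fit)
    if (fit[gi] < best$f) best <- list(g = genes[gi, ], f = fit[gi])
    trace[gen + 1L] <- best$f
  }
  list(par = denorm(best$g), value = best$f, trace = trace)
}

# Minimize fn over integer-day genomes. genome_lengths gives the number of
# genes per group (e.g. doses per drug); each gene is an integer day in
# [day_min, day_max]; at most cap genes of one group may share a day
# (violations repaired by resampling). Candidates are canonicalized sorted
# within groups, and evaluations are memoized on the canonical key.
.ga_integer <- function(fn, genome_lengths, day_min, day_max, cap = 2,
                        pop = 40, generations = 80, pcross = 0.9,
                        pmut = 0.15, init = NULL) {
  n_gene <- sum(genome_lengths)
  grp <- rep(seq_along(genome_lengths), genome_lengths)
  days <- seq.int(day_min, day_max)
  if (any(genome_lengths > length(days) * cap)) {
    stop("infeasible bounds: not enough day slots for the dose counts")
  }
  # sample from the day set itself (sample() on a scalar would expand it)
  draw_days <- function(k) days[sample.int(length(days), k, replace = TRUE)]

  repair <- function(g) {
    for (k in seq_along(genome_lengths)) {
      sel <- which(grp == k)
      repeat {
        tab <- table(g[sel])
        bad <- names(tab)[tab > cap]
        if (!length(bad)) break
        for (b in bad) {
          over <- which(g[sel] == as.integer(b))
          n_fix <- length(over) - cap
          g[sel[over[seq_len(n_fix)]]] <- draw_days(n_fix)
        }
      }
      g[sel] <- sort(g[sel])
    }
    g
  }
  cache <- new.env(parent = emptyenv())
  evalg <- function(g) {
    key <- paste(g, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- tryCatch(fn(g), error = function(e) Inf)
    if (!is.finite(v)) v <- Inf
    cache[[key]] <- v
    v
  }

  genes <- t(replicate(pop, repair(draw_days(n_gene))))
  if (!is.null(init)) {
    init <- t(apply(init, 1L, repair))
    n_init <- min(nrow(init), pop)
    genes[seq_len(n_init), ] <- init[seq_len(n_init), , drop = FALSE]
  }
  fit <- apply(genes, 1L, evalg)
  bi <- which.min(fit)
  best <- list(g = genes[bi, ], f = fit[bi])
  trace <- numeric(generations + 1L)
  trace[1L] <- best$f

  for (gen in seq_len(generations)) {
    idx1 <- sample.int(pop, pop, replace = TRUE)
    idx2 <- sample.int(pop, pop, replace = TRUE)
    parents <- ifelse(fit[idx1] <= fit[idx2], idx1, idx2)
    childs <- genes[parents, , drop = FALSE]
    for (i in seq(1L, pop - 1L, by = 2L)) {
      if (stats::runif(1) < pcross) {
        m <- stats::runif(n_gene) < 0.5
        tmp <- childs[i, m]
        childs[i, m] <- childs[i + 1L, m]
        childs[i + 1L, m] <- tmp
      }
    }
    mut <- matrix(stats::runif(pop * n_gene) < pmut, nrow = pop)
    childs[mut] <- draw_days(sum(mut))
    childs <- t(apply(childs, 1L, repair))
    childs[1L, ] <- best$g
    fit <- apply(childs, 1L, evalg)
    genes <- childs
    gi <- which.min(fit)
    if (fit[gi] < best$f) best <- list(g = genes[gi, ], f = fit[gi])
    trace[gen + 1L] <- best$f
  }
  split_par <- split(best$g, grp)
  names(split_par) <- names(genome_lengths)
  list(par = split_par, value = best$f, trace = trace,
       n_evaluated = length(ls(cache)))
}
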