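#' Settings for the evolutionary network search
#'
#' The published optimization is an elitist genetic algorithm: a population
#' of 100 candidate three-oscillator networks, the 5 fittest carried over
#' unchanged each generation, the remaining 95 formed by recombining two
#' parents drawn from the 40 fittest and then mutating, for 500 generations.
#' Mutation perturbs each numeric parameter independently (Gaussian, sd =
#' `mutation_scale` times the parameter's admissible width, clipped to
#' bounds) and flips the role of oscillator 2 with `role_flip_prob`.
#'
#' @param population Population size (default 100).
#' @param elite Number of top networks copied unchanged (default 5).
#' @param parent_pool Number of top networks parents are drawn from
#'   (default 40).
#' @param generations Number of evolutionary steps (default 500).
#' @param mutation_prob Per-parameter mutation probability.
#' @param mutation_scale Mutation sd as a fraction of the parameter's
#'   admissible width.
#' @param role_flip_prob Probability of flipping oscillator 2 between input
#'   and normal.
#' @param bounds Named list of ranges for `t_max`, `alpha`, `beta`; switch
#'   times and map endpoints are bounded by `[0, t_max]` of the individual.
#' @param seed Optional RNG seed recorded with the result.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 100, elite = 5, parent_pool = 40,
                      generations = 500, mutation_prob = 0.2,
                      mutation_scale = 0.1, role_flip_prob = 0.1,
                      bounds = list(t_max = c(10, 80), alpha = c(0, 1),
                                    beta = c(0, 0.2)),
                      seed = NULL) {
  stopifnot(population > elite, elite >= 1, parent_pool <= population,
            generations >= 1, mutation_prob >= 0, mutation_prob <= 1)
  structure(
    list(population = population, elite = elite, parent_pool = parent_pool,
         offspring = population - elite, generations = generations,
         mutation_prob = mutation_prob, mutation_scale = mutation_scale,
         role_flip_prob = role_flip_prob, bounds = bounds, seed = seed),
    class = "ga_config"
  )
}

# The search operates on the 3-oscillator family: oscillator 1 is input,
# oscillator 3 normal, oscillator 2's role is optimized. A latent switch
# time for oscillator 2 is kept even while it is an input, so recombination
# and mutation act on a fixed-length genome.
genome_of <- function(cfg) {
  till_normal <- cfg$t_illum_normal
  role2 <- cfg$roles[2]
  till2 <- if (role2 == "normal") till_normal[1] else
    attr(cfg, "latent_till2") %||% runif(1, 0, cfg$t_max)
  till3 <- till_normal[length(till_normal)]
  list(t_max = cfg$t_max, t_start = cfg$t_start, t_end = cfg$t_end,
       alpha = cfg$alpha, beta = cfg$beta, role2 = role2,
       till2 = till2, till3 = till3, gene = cfg$input_gene)
}

config_of <- function(g) {
  roles <- c("input", g$role2, "normal")
  till <- if (g$role2 == "normal") c(g$till2, g$till3) else g$till3
  cfg <- network_config(roles = roles, input_gene = g$gene,
                        t_max = g$t_max, t_start = g$t_start,
                        t_end = g$t_end, alpha = g$alpha, beta = g$beta,
                        t_illum_normal = till)
  attr(cfg, "latent_till2") <- g$till2
  cfg
}

genome_key <- function(g) {
  # the latent oscillator-2 switch time is phenotypically inert while the
  # oscillator is an input, so it is excluded from the cache key then
  till2 <- if (g$role2 == "normal") g$till2 else -1
  paste(formatC(c(g$t_max, g$t_start, g$t_end, g$alpha, g$beta, till2,
                  g$till3), format = "g", digits = 17),
        g$role2, collapse = "|")
}

#' Draw a random candidate network
#'
#' Every parameter is uniform within its bounds (`t_start`, `t_end` and the
#' switch times uniform in `[0, t_max]`); the role of oscillator 2 is
#' uniform over input/normal.
#'
#' @param gene Gene index the network will read.
#' @param ga A [ga_config()] supplying the parameter bounds.
#' @return A `network_config` from the 3-oscillator family.
#' @export
random_network <- function(gene, ga = ga_config()) {
  b <- ga$bounds
  t_max <- runif(1, b$t_max[1], b$t_max[2])
  config_of(list(
    t_max = t_max,
    t_start = runif(1, 0, t_max), t_end = runif(1, 0, t_max),
    alpha = runif(1, b$alpha[1], b$alpha[2]),
    beta = runif(1, b$beta[1], b$beta[2]),
    role2 = sample(c("input", "normal"), 1),
    till2 = runif(1, 0, t_max), till3 = runif(1, 0, t_max),
    gene = gene
  ))
}

#' Recombine two candidate networks
#'
#' Each genome entry (including the role of oscillator 2) is inherited from
#' either parent with equal probability.
#'
#' @param a,b `network_config` objects from the same 3-oscillator family and
#'   gene.
#' @return A child `network_config`.
#' @export
recombine_networks <- function(a, b) {
  ga <- genome_of(a); gb <- genome_of(b)
  stopifnot(ga$gene == gb$gene)
  child <- ga
  for (nm in c("t_max", "t_start", "t_end", "alpha", "beta", "role2",
               "till2", "till3")) {
    if (runif(1) < 0.5) child[[nm]] <- gb[[nm]]
  }
  # A switch time beyond the inherited t_max is legal: that oscillator is
  # simply never released within the observation window.
  config_of(child)
}

#' Mutate a candidate network
#'
#' Each numeric parameter is independently perturbed with probability
#' `mutation_prob` by a Gaussian of sd `mutation_scale` times the
#' parameter's admissible width, then clipped to bounds; oscillator 2's role
#' flips with `role_flip_prob`.
#'
#' @param net A `network_config`.
#' @param ga A [ga_config()].
#' @return The mutated `network_config`.
#' @export
mutate_network <- function(net, ga = ga_config()) {
  g <- genome_of(net)
  b <- ga$bounds
  perturb <- function(x, lo, hi) {
    if (runif(1) < ga$mutation_prob)
      x <- x + rnorm(1, 0, ga$mutation_scale * (hi - lo))
    min(max(x, lo), hi)
  }
  g$t_max <- perturb(g$t_max, b$t_max[1], b$t_max[2])
  g$alpha <- perturb(g$alpha, b$alpha[1], b$alpha[2])
  g$beta <- perturb(g$beta, b$beta[1], b$beta[2])
  for (nm in c("t_start", "t_end", "till2", "till3"))
    g[[nm]] <- perturb(g[[nm]], 0, g$t_max)
  if (runif(1) < ga$role_flip_prob)
    g$role2 <- if (g$role2 == "input") "normal" else "input"
  config_of(g)
}

#' Evolve a single-gene classifier network
#'
#' Runs the elitist genetic algorithm against a training table. The fitness
#' of a candidate network is the training accuracy of the best
#' count-to-class rule over all of its oscillators ([induce_rule()]), so a
#' network is scored by the most informative readout it can offer.
#'
#' @param data Training patient tibble (columns `gene_01`..`gene_15`,
#'   `outcome`).
#' @param gene Gene index to train on.
#' @param ga A [ga_config()].
#' @param params [oscillator_params()] used for all integrations; coarser
#'   `dt` speeds up exploratory runs.
#' @param stats Normalization ranges (default [gene_ranges]).
#' @param verbose Print a per-generation progress line.
#' @return An object of class `osc_evolution`: a list with `best_network`
#'   (output oscillator filled in), `best_rule`, `best_fitness`, `trace` (a
#'   tibble with `generation`, `best_fitness`, `mean_fitness`), `ga`, and
#'   `seed`.
#' @examples
#' \donttest{
#' tab <- synthesize_patients(60, overlap = 0.3, seed = 1)
#' fit <- evolve_network(tab, gene = 1,
#'                       ga = ga_config(generations = 3, seed = 1,
#'                                      bounds = list(t_max = c(10, 20),
#'                                                    alpha = c(0, 1),
#'                                                    beta = c(0, 0.2))),
#'                       params = oscillator_params(dt = 0.01))
#' fit$trace
#' }
#' @export
evolve_network <- function(data, gene, ga = ga_config(),
                           params = oscillator_params(),
                           stats = concilium::gene_ranges, verbose = FALSE) {
  stopifnot(nrow(data) >= 1)
  gene <- as.integer(gene)
  if (!is.null(ga$seed)) set.seed(ga$seed)
  p <- normalize_expression(gene_column(data, gene), gene, stats)
  labels <- as.integer(data$outcome)

  cache <- new.env(parent = emptyenv())
  fitness_of <- function(cfg) {
    key <- genome_key(genome_of(cfg))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    counts <- simulate_network(cfg, p, params)
    rule <- induce_rule(counts, labels, gene = gene)
    res <- list(fitness = attr(rule, "training_accuracy"), rule = rule)
    cache[[key]] <- res
    res
  }

  pop <- replicate(ga$population, random_network(gene, ga), simplify = FALSE)
  best <- NULL
  best_fit <- -Inf
  trace <- vector("list", ga$generations)

  for (gen in seq_len(ga$generations)) {
    evals <- lapply(pop, fitness_of)
    fits <- map_dbl(evals, "fitness")
    ord <- order(fits, decreasing = TRUE)
    if (fits[ord[1]] > best_fit) {
      best_fit <- fits[ord[1]]
      best <- list(network = pop[[ord[1]]], rule = evals[[ord[1]]]$rule)
    }
    trace[[gen]] <- tibble(generation = gen, best_fitness = max(fits),
                           mean_fitness = mean(fits))
    if (verbose)
      message(sprintf("generation %d: best %.3f, mean %.3f", gen,
                      max(fits), mean(fits)))
    if (gen == ga$generations) break
    elite <- pop[ord[seq_len(ga$elite)]]
    pool <- pop[ord[seq_len(min(ga$parent_pool, length(pop)))]]
    children <- replicate(ga$offspring, {
      pair <- sample.int(length(pool), 2, replace = FALSE)
      mutate_network(recombine_networks(pool[[pair[1]]], pool[[pair[2]]]), ga)
    }, simplify = FALSE)
    pop <- c(elite, children)
  }

  net <- best$network
  net$output_oscillator <- best$rule$output_oscillator
  structure(
    list(best_network = net, best_rule = best$rule, best_fitness = best_fit,
         trace = list_rbind(trace), ga = ga, seed = ga$seed, gene = gene),
    class = "osc_evolution"
  )
}

#' @export
print.osc_evolution <- function(x, ...) {
  cat(sprintf("<osc_evolution> gene %d, %d generations\n", x$gene,
              nrow(x$trace)))
  cat(sprintf("  best training accuracy: %.3f (output oscillator %d)\n",
              x$best_fitness, x$best_rule$output_oscillator))
  invisible(x)
}
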