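#' Generate a random mass-action reaction network
#'
#' Builds a synthetic benchmark model of `n_reactions` reactions over
#' `n_species` species. Each reaction draws one or two reactant molecules
#' and one or two product molecules, species chosen uniformly with
#' replacement (so dimerizations like `2A ->` are possible); null reactions
#' (identical reactant and product sides) are resampled. A post-pass
#' attaches any species left out of every reaction as a product of a
#' randomly chosen reaction, so each species takes part in the network.
#'
#' Initial concentrations are sampled uniformly in `[0, 1)` and kinetic
#' constants log-uniformly in `[1e-8, 1)` (i.e. `k = 10^(-8 U)` with
#' `U ~ Uniform(0, 1]`). Sampling instants are `n_samples` points evenly
#' spaced over `[0, t_max]`. The whole draw is governed by a single seeded
#' Mersenne-Twister stream, so a given seed reproduces the model exactly;
#' the seed is recorded in the model's `generator_seed` field.
#'
#' @param n_reactions number of reactions M.
#' @param n_species number of species N.
#' @param seed integer seed.
#' @param t_max simulation horizon (default 50).
#' @param n_samples number of sampling instants including `t = 0`
#'   (default 10).
#' @param conc_range half-open interval for initial concentrations.
#' @param logk_range half-open interval for `log10` of the kinetic
#'   constants.
#' @return a `reaction_model` passing [validate_model()] with no
#'   violations.
#' @examples
#' m <- generate_random_model(64, 64, seed = 42)
#' range(m$kinetic_constants)
#' @export
generate_random_model <- function(n_reactions, n_species, seed = 1,
                                  t_max = 50, n_samples = 10,
                                  conc_range = c(0, 1),
                                  logk_range = c(-8, 0)) {
  M <- as.integer(n_reactions)
  N <- as.integer(n_species)
  if (is.na(M) || is.na(N) || M < 1 || N < 1) {
    stop("n_reactions and n_species must be positive integers", call. = FALSE)
  }
  # a reaction touches at most 4 species slots (2 reactants + 2 products)
  if (4L * M < N) {
    stop(sprintf(
      "infeasible size: %d reactions cannot involve all %d species", M, N),
      call. = FALSE)
  }
  stopifnot(length(conc_range) == 2, conc_range[2] > conc_range[1],
            length(logk_range) == 2, logk_range[2] > logk_range[1],
            t_max > 0, n_samples >= 1)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")

  # reactions are held as multisets of species indices (length 1 or 2) and
  # only assembled into dense matrices at the end, so large models stay cheap
  reactants <- vector("list", M)
  products <- vector("list", M)
  for (i in seq_len(M)) {
    repeat {
      a <- sort(sample.int(N, sample.int(2L, 1L), replace = TRUE))
      b <- sort(sample.int(N, sample.int(2L, 1L), replace = TRUE))
      if (!identical(a, b)) break  # resample null reactions
    }
    reactants[[i]] <- a
    products[[i]] <- b
  }

  # coverage pass: attach each species absent from every reaction as a
  # product of a randomly chosen reaction (appending where a product slot is
  # free, otherwise displacing a product that remains covered elsewhere);
  # occurrence counts are tracked incrementally. Placements never uncover a
  # species, so one pass over the uncovered set suffices.
  occ <- tabulate(c(unlist(reactants), unlist(products)), nbins = N)
  for (s in which(occ == 0)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      i <- sample.int(M, 1L)
      b <- products[[i]]
      dropped <- 0L
      if (length(b) < 2) {
        b <- sort(c(b, s))
      } else {
        # replace one occurrence of a product that stays covered without it
        replaceable <- b[occ[b] > 1]
        if (length(replaceable) == 0) next
        dropped <- replaceable[sample.int(length(replaceable), 1L)]
        b <- sort(c(b[-match(dropped, b)], s))
      }
      if (identical(reactants[[i]], b)) next  # would create a null reaction
      products[[i]] <- b
      occ[s] <- occ[s] + 1L
      if (dropped > 0L) occ[dropped] <- occ[dropped] - 1L
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not cover every species; increase the reaction count",
           call. = FALSE)
    }
  }

  side_matrix <- function(sides) {
    i <- rep.int(seq_len(M), lengths(sides))
    as.matrix(Matrix::sparseMatrix(i = i, j = unlist(sides), x = 1,
                                   dims = c(M, N)))
  }
  A <- side_matrix(reactants)
  B <- side_matrix(products)

  X0 <- conc_range[1] + (conc_range[2] - conc_range[1]) * stats::runif(N)
  width <- logk_range[2] - logk_range[1]
  K <- 10^(logk_range[2] - width * (1 - stats::runif(M)))  # log10 k in [low, high)

  model <- new_reaction_model(
    A, B, K, X0,
    sampling_times = seq(0, t_max, length.out = max(n_samples, 1L))
  )
  model$generator_seed <- seed
  model
}
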