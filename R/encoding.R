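#' Build the compressed sparse polynomial encoding of the ODE system
#'
#' Under mass-action kinetics the system of ODEs derived from stoichiometry
#' is `dX/dt = (B - A)^T (K o X^A)`, where `o` is the entry-wise product and
#' `X^A` the vector-matrix exponentiation (component i equals
#' `prod_j X_j^{a_ij}`). Every ODE is a polynomial; this function stores the
#' system in a compressed form that drops all zero entries of `A` and of
#' `H = (B - A)^T`:
#'
#' \describe{
#'   \item{`vh_*`}{one quadruple per non-zero of `H`: the species index, the
#'     monomial row to read in the `oa` table, the signed coefficient
#'     `h_ji`, and the index of the kinetic constant of that monomial.}
#'   \item{`oh_first`/`oh_last`}{per species, the inclusive span of its
#'     quadruples; `first > last` marks a species whose derivative is
#'     identically zero.}
#'   \item{`va_*`}{one pair per non-zero of `A`: the reactant species index
#'     and its exponent (1 or 2; a dimerization reactant `2A` is a single
#'     entry with exponent 2, giving the plain mass-action rate `k X_A^2`).}
#'   \item{`oa_first`/`oa_last`}{per monomial row, the inclusive span of its
#'     reactant factors.}
#' }
#'
#' All stored indices are 0-based. Quadruples are ordered species-major and,
#' within a species, by ascending reaction index; reactant pairs are ordered
#' by reaction, then ascending species index, so the encoding of a given
#' model is deterministic.
#'
#' @param model a valid `reaction_model`.
#' @param compact_mode emulate 16-bit index storage: building an encoding
#'   whose species or reaction count reaches 65536 is refused. The default
#'   (`FALSE`) places no limit; the arithmetic is identical either way.
#' @return an object of class `ode_encoding`.
#' @seealso [evaluate_derivatives()], [evaluate_jacobian()]
#' @examples
#' dir <- system.file("extdata", "two_reaction_example", package = "massaction")
#' enc <- build_encoding(parse_model(dir))
#' evaluate_derivatives(enc, c(1, 0.5, 2))
#' @export
build_encoding <- function(model, compact_mode = FALSE) {
  A <- model$reactant_matrix
  B <- model$product_matrix
  M <- model$n_reactions
  N <- model$n_species
  if (compact_mode && (N >= 65536L || M >= 65536L)) {
    stop(sprintf(
      "compact (16-bit) indices limit the system to 65536 species and reactions (got %d x %d)",
      M, N), call. = FALSE)
  }

  H <- t(B - A)  # N x M; H[j, i] is the net stoichiometry of species j in reaction i

  # reactant factors, ordered by reaction then ascending species index
  va_species <- integer(0)
  va_exp <- integer(0)
  oa_first <- integer(M)
  oa_last <- integer(M)
  pos <- 0L
  for (i in seq_len(M)) {
    js <- which(A[i, ] != 0)
    oa_first[i] <- pos
    for (j in js) {
      va_species <- c(va_species, j - 1L)
      va_exp <- c(va_exp, as.integer(A[i, j]))
      pos <- pos + 1L
    }
    oa_last[i] <- pos - 1L  # first > last for an (invalid) empty reactant side
  }

  # quadruples, species-major, ascending reaction index within a species
  vh_species <- integer(0)
  vh_row <- integer(0)
  vh_coef <- numeric(0)
  vh_kidx <- integer(0)
  oh_first <- integer(N)
  oh_last <- integer(N)
  pos <- 0L
  for (j in seq_len(N)) {
    is <- which(H[j, ] != 0)
    oh_first[j] <- pos
    for (i in is) {
      vh_species <- c(vh_species, j - 1L)
      vh_row <- c(vh_row, i - 1L)
      vh_coef <- c(vh_coef, H[j, i])
      vh_kidx <- c(vh_kidx, i - 1L)
      pos <- pos + 1L
    }
    oh_last[j] <- pos - 1L
  }

  structure(
    list(
      vh_species = vh_species, vh_row = vh_row, vh_coef = vh_coef,
      vh_kidx = vh_kidx, oh_first = oh_first, oh_last = oh_last,
      va_species = va_species, va_exp = va_exp,
      oa_first = oa_first, oa_last = oa_last,
      constants = as.numeric(model$kinetic_constants),
      n_species = N, n_reactions = M,
      compact_mode = isTRUE(compact_mode),
      species_names = model$species_names
    ),
    class = "ode_encoding"
  )
}

#' @export
print.ode_encoding <- function(x, ...) {
  cat(sprintf(
    "Compressed ODE system: %d species, %d reactions, %d monomial terms, %d reactant factors%s\n",
    x$n_species, x$n_reactions, length(x$vh_coef), length(x$va_species),
    if (x$compact_mode) " (compact 16-bit indices)" else ""))
  invisible(x)
}

#' Dump the compressed encoding as a readable table
#'
#' One row per stored monomial: the species whose ODE it belongs to, its
#' signed coefficient, the kinetic-constant index, and the reactant factors
#' in `X_j^a` notation. Intended for debugging small systems.
#'
#' @param encoding an `ode_encoding`.
#' @return a data.frame with columns `species`, `coefficient`, `k_index`,
#'   `factors`.
#' @export
encoding_table <- function(encoding) {
  n <- length(encoding$vh_coef)
  factors <- character(n)
  for (t in seq_len(n)) {
    row <- encoding$vh_row[t] + 1L
    span <- seq.int(encoding$oa_first[row], encoding$oa_last[row]) + 1L
    factors[t] <- paste(sprintf("X%d^%d", encoding$va_species[span] + 1L,
                                encoding$va_exp[span]), collapse = " * ")
  }
  data.frame(
    species = encoding$vh_species + 1L,
    coefficient = encoding$vh_coef,
    k_index = encoding$vh_kidx + 1L,
    factors = factors,
    stringsAsFactors = FALSE
  )
}

#' Reconstruct the dense net-stoichiometry matrix from the encoding
#'
#' Expands the stored quadruples back into the dense `N x M` matrix
#' `H = (B - A)^T`; used to verify that compression loses nothing.
#'
#' @param encoding an `ode_encoding`.
#' @return an `N x M` numeric matrix.
#' @export
encoding_dense_H <- function(encoding) {
  H <- matrix(0, encoding$n_species, encoding$n_reactions)
  n <- length(encoding$vh_coef)
  for (t in seq_len(n)) {
    H[encoding$vh_species[t] + 1L, encoding$vh_row[t] + 1L] <- encoding$vh_coef[t]
  }
  H
}

#' Evaluate the ODE right-hand side from the compressed encoding
#'
#' Computes `f_j = sum_i h_ji k_i prod_r X_r^{a_ir}` for every species by
#' walking the stored spans; no dense matrix is formed.
#'
#' @param encoding an `ode_encoding`.
#' @param X numeric state vector of length `n_species`.
#' @return the derivative vector `dX/dt` of length `n_species`.
#' @export
evaluate_derivatives <- function(encoding, X) {
  X <- as.numeric(X)
  if (length(X) != encoding$n_species) {
    stop(sprintf("state has length %d, expected %d", length(X),
                 encoding$n_species), call. = FALSE)
  }
  cpp_eval_deriv(encoding, X)
}

#' Evaluate the exact Jacobian of the ODE right-hand side
#'
#' Each monomial is differentiated symbolically: an exponent-1 factor is
#' dropped, an exponent-2 factor `X_r^2` contributes `2 X_r`. No numerical
#' differencing is involved, so the result is exact to round-off.
#'
#' @param encoding an `ode_encoding`.
#' @param X numeric state vector of length `n_species`.
#' @return the `N x N` Jacobian matrix with entry `(j, r) = d f_j / d X_r`.
#' @export
evaluate_jacobian <- function(encoding, X) {
  X <- as.numeric(X)
  if (length(X) != encoding$n_species) {
    stop(sprintf("state has length %d, expected %d", length(X),
                 encoding$n_species), call. = FALSE)
  }
  cpp_eval_jacobian(encoding, X)
}
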