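#' Construct a kinetic model for an smFRET system
#'
#' A kinetic model is a continuous-time Markov chain over `n` conformational
#' states, each with a mean FRET efficiency. Off-diagonal entries of `rates`
#' hold the transition rate constants \eqn{k_{ij}} (per second, from state `i`
#' to state `j`); the diagonal is unused and kept at zero. On construction the
#' model is validated and brought to canonical form: states are ordered by
#' ascending FRET efficiency, ties broken by larger total exit rate first, so
#' that ground-truth and inferred models are directly comparable.
#'
#' @param rates square numeric matrix of rate constants in 1/s; diagonal
#'   entries are ignored and stored as zero.
#' @param fret numeric vector of per-state mean FRET efficiencies in `[0, 1]`.
#' @param state_labels optional character vector of state identifiers;
#'   defaults to `"S1"`, `"S2"`, ...
#'
#' @return An object of class `kinetic_model` with elements `n_states`,
#'   `rates`, `fret` and `state_labels`, in canonical state order.
#' @examples
#' m <- kinetic_model(rbind(c(0, 0.1), c(0.2, 0)), fret = c(0.3, 0.7))
#' stationary_distribution(m)
#' @export
kinetic_model <- function(rates, fret, state_labels = NULL) {
  rates <- as.matrix(rates)
  storage.mode(rates) <- "double"
  n <- length(fret)
  if (is.null(state_labels)) state_labels <- paste0("S", seq_len(n))
  m <- structure(
    list(n_states = n, rates = rates, fret = as.numeric(fret),
         state_labels = as.character(state_labels)),
    class = "kinetic_model")
  validate_model(m)
}

#' Validate a kinetic model and bring it to canonical state order
#'
#' Checks the model invariants (square rate matrix matching the number of
#' states, non-negative off-diagonal rates, FRET efficiencies in `[0, 1]`,
#' no absorbing state when more than one state exists) and permutes the
#' states into canonical order: ascending FRET efficiency, ties broken by
#' the larger total exit rate.
#'
#' @param model a `kinetic_model` or a bare list with the same fields.
#' @return The validated model in canonical order.
#' @export
validate_model <- function(model) {
  n <- model$n_states
  rates <- model$rates
  if (!is.matrix(rates) || nrow(rates) != ncol(rates) || nrow(rates) != n)
    stop("'rates' must be a square ", n, "x", n, " matrix", call. = FALSE)
  if (length(model$fret) != n)
    stop("'fret' must have one efficiency per state", call. = FALSE)
  off <- rates[row(rates) != col(rates)]
  if (any(!is.finite(off)) || any(off < 0))
    stop("off-diagonal rate constants must be finite and >= 0", call. = FALSE)
  if (any(model$fret < 0 | model$fret > 1))
    stop("FRET efficiencies must lie in [0, 1]", call. = FALSE)
  diag(rates) <- 0
  exit <- rowSums(rates)
  if (n > 1L && any(exit == 0))
    stop("absorbing state(s): ", paste(model$state_labels[exit == 0], collapse = ", "),
         " have no outgoing rate", call. = FALSE)
  # canonical order: ascending E, ties by larger exit rate first
  ord <- order(model$fret, -exit)
  model$rates <- rates[ord, ord, drop = FALSE]
  model$fret <- model$fret[ord]
  model$state_labels <- model$state_labels[ord]
  dimnames(model$rates) <- list(model$state_labels, model$state_labels)
  if (!inherits(model, "kinetic_model")) class(model) <- "kinetic_model"
  model
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic model with", x$n_states, "state(s)\n")
  cat("FRET efficiencies:", paste(sprintf("%s = %.3f", x$state_labels, x$fret),
                                  collapse = ", "), "\n")
  if (x$n_states > 1L) {
    cat("Rate constants (1/s), k[i, j] = i -> j:\n")
    print(round(x$rates, 6))
    if (is_detailed_balanced(x)) cat("Detailed balance: satisfied\n")
    else cat("Detailed balance: violated (non-equilibrium steady state)\n")
  }
  invisible(x)
}

# infinitesimal generator: off-diagonal k_ij, diagonal -sum_j k_ij
generator_matrix <- function(model) {
  Q <- model$rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of a kinetic model
#'
#' Solves \eqn{\pi Q = 0} with \eqn{\sum_i \pi_i = 1}, where `Q` is the
#' infinitesimal generator, by null-space computation on the transposed
#' generator. The long-run occupancy is the natural distribution for the
#' initial state of a simulated molecule.
#'
#' @param model a validated `kinetic_model`.
#' @param tol numeric tolerance for the residual check of \eqn{\pi Q = 0}.
#' @return Numeric probability vector, one entry per state.
#' @export
stationary_distribution <- function(model, tol = 1e-10) {
  n <- model$n_states
  if (n == 1L) return(stats::setNames(1, model$state_labels))
  if (!is_irreducible(model$rates)) {
    comp <- communicating_closed_states(model$rates)
    stop("rate matrix is reducible; states {",
         paste(model$state_labels[comp], collapse = ", "),
         "} cannot be left or cannot be reached", call. = FALSE)
  }
  Q <- generator_matrix(model)
  s <- svd(t(Q))
  pi_hat <- s$v[, n]
  pi_hat <- pi_hat / sum(pi_hat)
  if (any(pi_hat < -tol) || max(abs(as.numeric(pi_hat %*% Q))) > tol)
    stop("stationary distribution did not converge to tolerance ", tol, call. = FALSE)
  pi_hat <- pmax(pi_hat, 0)
  stats::setNames(pi_hat / sum(pi_hat), model$state_labels)
}

# strong connectivity of the directed graph with edges k_ij > 0
is_irreducible <- function(rates) {
  n <- nrow(rates)
  reach <- function(adj) {
    seen <- c(TRUE, rep(FALSE, n - 1L))
    queue <- 1L
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[i, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    seen
  }
  adj <- rates > 0
  all(reach(adj)) && all(reach(t(adj)))
}

# states from which the start state is unreachable or vice versa (diagnostics)
communicating_closed_states <- function(rates) {
  n <- nrow(rates)
  adj <- rates > 0
  seen <- c(TRUE, rep(FALSE, n - 1L)); queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[i, ] & !seen); seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  if (!all(seen)) which(!seen) else {
    seenb <- c(TRUE, rep(FALSE, n - 1L)); queue <- 1L
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[, i] & !seenb); seenb[nb] <- TRUE; queue <- c(queue, nb)
    }
    which(!seenb)
  }
}

#' Equilibrium constant of a two-state exchange
#'
#' For a two-state system with forward rate `k12` and backward rate `k21`,
#' the equilibrium constant is \eqn{K = k_{21}/k_{12}}, the ratio of
#' stationary occupancies \eqn{\pi_1/\pi_2}. Systematic over- or
#' under-estimation common to both rates cancels in `K`, which is why it is a
#' robust cross-check on inferred kinetics.
#'
#' @param k12,k21 rate constants in 1/s; `k12` must be strictly positive.
#' @return Dimensionless equilibrium constant.
#' @export
equilibrium_constant <- function(k12, k21) {
  if (any(k12 <= 0)) stop("k12 must be > 0 to form K = k21/k12", call. = FALSE)
  k21 / k12
}

#' Free energy driving a kinetic cycle
#'
#' For a directed cycle of states, e.g. `(1, 2, 3)`, computes the free-energy
#' difference per cycle traversal in units of \eqn{k_B T}:
#' \deqn{\Delta G = -\ln\frac{k_{21} k_{32} k_{13}}{k_{12} k_{23} k_{31}}.}
#' A value of zero means the cycle obeys detailed balance; a negative value
#' flags a net counter-clockwise flow sustained by external energy input
#' (a non-equilibrium steady state), as in driven molecular machines.
#'
#' @param model a validated `kinetic_model`.
#' @param cycle integer vector of state indices visited in order; the cycle
#'   closes from the last index back to the first.
#' @return A list of class `flow_result` with `delta_g` (in \eqn{k_B T}),
#'   `cycle` and `direction_convention`.
#' @export
cycle_flow_free_energy <- function(model, cycle = seq_len(model$n_states)) {
  cycle <- as.integer(cycle)
  if (length(cycle) < 3L) stop("a cycle needs at least 3 states", call. = FALSE)
  if (anyDuplicated(cycle)) stop("cycle states must be distinct", call. = FALSE)
  nxt <- c(cycle[-1L], cycle[1L])
  fwd <- model$rates[cbind(cycle, nxt)]   # k_{i -> next}
  rev <- model$rates[cbind(nxt, cycle)]   # k_{next -> i}
  if (any(fwd == 0) || any(rev == 0))
    stop("cycle flow undefined: a rate along the cycle is zero", call. = FALSE)
  structure(
    list(delta_g = -log(prod(rev) / prod(fwd)),
         cycle = cycle,
         direction_convention = paste0(
           "delta_g < 0: net flow along the listed order ",
           paste(cycle, collapse = " -> "), " -> ", cycle[1L])),
    class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("Cycle %s: delta G = %.4f kBT\n",
              paste(x$cycle, collapse = "-"), x$delta_g))
  cat(x$direction_convention, "\n")
  invisible(x)
}

#' Test a kinetic model for detailed balance
#'
#' Applies the Kolmogorov cycle criterion: a reversible (detailed-balanced)
#' chain has zero cycle free energy around every cycle. Fundamental cycles of
#' a spanning tree of the connectivity graph span all independent cycles, so
#' only those are checked. A transition with a forward but no backward rate
#' makes the model irreversible. Models whose connectivity graph has no
#' cycle (e.g. any two-state model or a linear chain) are detailed balanced
#' by construction.
#'
#' @param model a validated `kinetic_model`.
#' @param tol absolute tolerance on `|delta_g|` (in \eqn{k_B T}) per cycle.
#' @return `TRUE` or `FALSE`.
#' @export
is_detailed_balanced <- function(model, tol = 1e-9) {
  n <- model$n_states
  if (n < 2L) return(TRUE)
  k <- model$rates
  one_sided <- (k > 0) != (t(k) > 0)
  if (any(one_sided)) return(FALSE)
  adj <- (k > 0) | (t(k) > 0)
  # spanning forest by BFS; each non-tree edge closes one fundamental cycle
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  tree_edge <- matrix(FALSE, n, n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      for (j in which(adj[i, ] & !visited)) {
        visited[j] <- TRUE; parent[j] <- i
        tree_edge[i, j] <- tree_edge[j, i] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  path_to_root <- function(i) {
    p <- i
    while (!is.na(parent[i])) { i <- parent[i]; p <- c(p, i) }
    p
  }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (!adj[i, j] || tree_edge[i, j]) next
    pi_ <- path_to_root(i); pj <- path_to_root(j)
    common <- intersect(pi_, pj)
    meet <- common[1L]
    cyc <- c(rev(pi_[seq_len(match(meet, pi_))]), pj[seq_len(match(meet, pj) - 1L)])
    # cyc runs meet ... i, then j ... (just below meet); closing edge is i -> j
    cyc <- unique(cyc)
    if (length(cyc) >= 3L) {
      dg <- cycle_flow_free_energy(model, cyc)$delta_g
      if (abs(dg) > tol) return(FALSE)
    }
  }
  TRUE
}
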