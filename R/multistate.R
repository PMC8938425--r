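#' A linear free-energy chain for a multi-step register shift
#'
#' Ordered state free energies (GS first, kcal/mol, GS = 0 by convention)
#' and the absolute transition-state free energies between consecutive
#' states. Storing barriers as absolute TS energies makes forward and
#' backward rates share one saddle point, so detailed balance holds by
#' construction.
#'
#' @param state_energies Free energies of the states, kcal/mol.
#' @param barrier_energies Absolute transition-state free energies;
#'   length `length(state_energies) - 1`; every barrier must be at or
#'   above both adjacent state energies.
#' @param temperature_K Temperature (K). Default 278.15 (5 degC).
#' @param state_labels Optional names; default `GS, I1, ..., ES`.
#' @return List of class `"free_energy_chain"`.
#' @examples
#' free_energy_chain(c(0, 1.63), 14.67)
#' six_state_chain()
#' @export
free_energy_chain <- function(state_energies, barrier_energies,
                              temperature_K = 278.15,
                              state_labels = NULL) {
  n <- length(state_energies)
  stopifnot(n >= 2L, length(barrier_energies) == n - 1L,
            temperature_K > 0)
  lo <- pmax(state_energies[-n], state_energies[-1])
  if (any(barrier_energies < lo - 1e-12))
    stop("barrier(s) ", paste(which(barrier_energies < lo - 1e-12),
                              collapse = ", "),
         " lie below an adjacent state energy")
  if (is.null(state_labels)) {
    state_labels <- if (n == 2L) c("GS", "ES")
    else c("GS", paste0("I", seq_len(n - 2L)), "ES")
  }
  stopifnot(length(state_labels) == n)
  structure(list(state_labels = state_labels,
                 state_energies = state_energies,
                 barrier_energies = barrier_energies,
                 temperature_K = temperature_K),
            class = "free_energy_chain")
}

#' The bundled six-state upward pathway
#'
#' GS at 0, four intermediates at 2.90 kcal/mol (= 1.63 + 1.27, i.e.
#' ten-fold less populated than the ES so they stay invisible to
#' relaxation-dispersion experiments) and the ES at 1.63 kcal/mol, with
#' all five transition states at one common absolute height.
#'
#' @param barrier Common absolute TS free energy (kcal/mol);
#'   default 13.9.
#' @param temperature_K Temperature (K), default 278.15.
#' @return A [free_energy_chain()].
#' @export
six_state_chain <- function(barrier = 13.9, temperature_K = 278.15) {
  free_energy_chain(c(0, rep(2.90, 4), 1.63), rep(barrier, 5),
                    temperature_K = temperature_K)
}

#' Build the first-order rate matrix of a free-energy chain
#'
#' Nearest-neighbour hopping rates from transition-state theory,
#' `k(i -> i+-1) = (kB T / h) exp(-(TS - E_i)/RT)`. The generator `Q`
#' follows the column convention `dp/dt = Q p` (columns sum to zero); its
#' stationary distribution is the Boltzmann distribution of the state
#' energies, and detailed balance holds exactly.
#'
#' @param chain A [free_energy_chain()].
#' @param constants A [physical_constants()] list.
#' @return List of class `"rate_matrix"` with `generator` (n x n, s^-1),
#'   `stationary` (Boltzmann weights, sums to 1), `chain`, `constants`.
#' @examples
#' rm2 <- build_rate_matrix(free_energy_chain(c(0, 1.63), 14.67, 283.15))
#' rm2$generator[2, 1]  # forward rate, ~28 s^-1
#' @export
build_rate_matrix <- function(chain, constants = physical_constants()) {
  stopifnot(inherits(chain, "free_energy_chain"))
  E <- chain$state_energies
  TS <- chain$barrier_energies
  T_K <- chain$temperature_K
  n <- length(E)
  nu <- constants$kappa * constants$kB * T_K / constants$h
  RT <- constants$R * T_K
  kf <- nu * exp(-(TS - E[-n]) / RT)   # i -> i+1
  kb <- nu * exp(-(TS - E[-1]) / RT)   # i+1 -> i
  Q <- matrix(0, n, n, dimnames = list(chain$state_labels,
                                       chain$state_labels))
  for (i in seq_len(n - 1L)) {
    Q[i + 1L, i] <- kf[i]
    Q[i, i + 1L] <- kb[i]
  }
  diag(Q) <- -colSums(Q)
  pi0 <- exp(-E / RT)
  structure(list(generator = Q, stationary = pi0 / sum(pi0),
                 chain = chain, constants = constants),
            class = "rate_matrix")
}

#' Reduce a chain to apparent two-state exchange kinetics
#'
#' The apparent exchange rate is minus the slowest non-zero eigenvalue of
#' the generator (computed on the detailed-balance-symmetrized matrix for
#' numerical stability). The apparent ES population is the Boltzmann mass
#' of everything outside `gs_side` (intermediates are lumped with the ES;
#' they are constructed ten-fold below it so the choice moves populations
#' by well under 10% of pES). Then `k1_app = pES_app * kex_app` and the
#' apparent activation free energy follows from [eyring_dG()].
#'
#' @param matrix A [build_rate_matrix()] result.
#' @param gs_side Indices (or labels) of the states lumped into the
#'   ground state; default the first state only.
#' @return List of class `"apparent_two_state"` with `kex_app`, `k1_app`,
#'   `kminus1_app` (s^-1), `pES_app`, `dG_act_app` (kcal/mol),
#'   `spectral_gap` (ratio of next-slowest to slowest non-zero mode) and
#'   `gap_ok` (`FALSE`, with a warning, when the gap is < 10x and the
#'   two-state reduction is poor). Also the forward `committor` per
#'   state and the transition-path rates `k1_tp`, `kminus1_tp`,
#'   `kex_tp` -- the committor-corrected terminal-to-terminal rates that
#'   a first-passage simulation between GS and ES measures (they differ
#'   from the eigenvalue-lump rates by O(1/spectral_gap)).
#' @examples
#' app <- apparent_two_state(build_rate_matrix(six_state_chain()))
#' app$dG_act_app
#' @export
apparent_two_state <- function(matrix, gs_side = 1L) {
  stopifnot(inherits(matrix, "rate_matrix"))
  Q <- matrix$generator
  pi0 <- matrix$stationary
  n <- nrow(Q)
  if (is.character(gs_side))
    gs_side <- match(gs_side, matrix$chain$state_labels)
  stopifnot(all(gs_side %in% seq_len(n)))
  # symmetrize: S = D^{-1/2} Q D^{1/2} with D = diag(pi); symmetric under
  # detailed balance, same spectrum
  d <- sqrt(pi0)
  S <- Q * outer(1 / d, d)
  S <- (S + t(S)) / 2
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  kex_app <- -ev[2]
  gap <- if (n >= 3L) ev[3] / ev[2] else Inf
  gap_ok <- is.infinite(gap) || gap >= 10
  if (!gap_ok)
    warning("spectral gap ", signif(gap, 3),
            "x < 10x: two-state reduction is poor")
  pES_app <- sum(pi0[-gs_side])
  k1_app <- pES_app * kex_app
  # transition-path (committor-corrected) rates between the terminal
  # states: the quantity a first-passage simulation actually measures.
  # committor q solves sum_j k(i->j) (q_j - q_i) = 0 on interior states,
  # q(first) = 0, q(last) = 1; k(i->j) = Q[j, i]
  q <- numeric(n)
  q[n] <- 1
  if (n > 2L) {
    interior <- 2:(n - 1L)
    K <- t(Q)  # K[i, j] = rate i -> j
    A <- K[interior, interior, drop = FALSE]
    diag(A) <- diag(A) - rowSums(K[interior, , drop = FALSE])
    b <- -K[interior, n]
    q[interior] <- solve(A, b)
  }
  flux <- pi0[1] * Q[2, 1] * (q[2] - q[1])
  rho_A <- sum(pi0 * (1 - q))
  rho_B <- sum(pi0 * q)
  structure(list(
    kex_app = kex_app, k1_app = k1_app,
    kminus1_app = (1 - pES_app) * kex_app, pES_app = pES_app,
    dG_act_app = eyring_dG(k1_app, matrix$chain$temperature_K,
                           matrix$constants),
    committor = q,
    k1_tp = flux / rho_A, kminus1_tp = flux / rho_B,
    kex_tp = flux / rho_A + flux / rho_B,
    spectral_gap = gap, gap_ok = gap_ok
  ), class = "apparent_two_state")
}

#' Tune all barriers to hit a target apparent activation energy
#'
#' Applies one uniform additive shift to every transition-state energy
#' and bisects on the shift until the apparent two-state activation free
#' energy (from [apparent_two_state()]) matches `target_dG_act` to within
#' `tol`. The apparent barrier responds monotonically (and nearly 1:1) to
#' a uniform shift, so bisection always converges when the target is
#' reachable without pushing a barrier below an adjacent state.
#'
#' @param chain A [free_energy_chain()].
#' @param target_dG_act Target apparent activation free energy
#'   (kcal/mol).
#' @param tol Convergence tolerance (kcal/mol), default 1e-4.
#' @param constants A [physical_constants()] list.
#' @return The tuned `"free_energy_chain"`, with attribute `"shift"`
#'   recording the applied uniform shift.
#' @examples
#' tuned <- tune_barriers(six_state_chain(), 14.74)
#' max(tuned$barrier_energies)  # largest individual barrier after tuning
#' @export
tune_barriers <- function(chain, target_dG_act, tol = 1e-4,
                          constants = physical_constants()) {
  stopifnot(inherits(chain, "free_energy_chain"))
  app_at <- function(shift) {
    ch <- chain
    ch$barrier_energies <- chain$barrier_energies + shift
    suppressWarnings(
      apparent_two_state(build_rate_matrix(ch, constants))$dG_act_app)
  }
  # lowest admissible shift keeps every barrier at the adjacent-state max
  E <- chain$state_energies
  n <- length(E)
  floor_shift <- max(pmax(E[-n], E[-1]) - chain$barrier_energies)
  lo <- target_dG_act - app_at(0)  # near-1:1 response: good first guess
  lo <- max(lo - 1, floor_shift)
  hi <- lo + 2
  for (i in 1:60) {
    if (app_at(lo) <= target_dG_act) break
    lo <- max(lo - 2, floor_shift)
    if (lo == floor_shift && app_at(lo) > target_dG_act)
      stop("target apparent activation energy unreachable: barriers ",
           "cannot drop below adjacent states")
  }
  while (app_at(hi) < target_dG_act) hi <- hi + 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- app_at(mid)
    if (abs(v - target_dG_act) < tol) break
    if (v < target_dG_act) lo <- mid else hi <- mid
  }
  out <- chain
  out$barrier_energies <- chain$barrier_energies + mid
  attr(out, "shift") <- mid
  out
}

#' Accumulated barrier of a hypothetical concerted transition
#'
#' If every step of the chain had to be paid simultaneously (all base
#' pairs broken at once) the activation cost would be the sum over
#' forward steps of `TS_i - E_{i-1}`.
#'
#' @param chain A [free_energy_chain()].
#' @return Accumulated barrier in kcal/mol.
#' @examples
#' simultaneous_barrier(free_energy_chain(c(0, 1.63), 14.67))  # one step
#' @export
simultaneous_barrier <- function(chain) {
  stopifnot(inherits(chain, "free_energy_chain"))
  E <- chain$state_energies
  sum(chain$barrier_energies - E[-length(E)])
}

#' Mean first-passage time by exact stochastic simulation
#'
#' Gillespie-style continuous-time Markov sampling of paths from `start`
#' until absorption into any state of `absorb`; the stochastic oracle for
#' the spectral two-state reduction.
#'
#' @param matrix A [build_rate_matrix()] result.
#' @param start Starting state (index or label).
#' @param absorb Absorbing state(s) (indices or labels).
#' @param n_paths Number of paths (default 10000).
#' @param seed RNG seed (required, for reproducibility).
#' @return List with `mfpt` (s), `se` (standard error, s) and `n_paths`.
#' @examples
#' rm2 <- build_rate_matrix(free_energy_chain(c(0, 1.63), 14.0, 283.15))
#' gillespie_first_passage(rm2, 1, 2, n_paths = 500, seed = 1)
#' @export
gillespie_first_passage <- function(matrix, start, absorb,
                                    n_paths = 10000, seed) {
  stopifnot(inherits(matrix, "rate_matrix"))
  Q <- matrix$generator
  n <- nrow(Q)
  lab <- matrix$chain$state_labels
  if (is.character(start)) start <- match(start, lab)
  if (is.character(absorb)) absorb <- match(absorb, lab)
  stopifnot(start %in% seq_len(n), all(absorb %in% seq_len(n)),
            !(start %in% absorb))
  # off-diagonal rates out of each state
  rates <- lapply(seq_len(n), function(i) {
    r <- Q[, i]
    r[i] <- 0
    r
  })
  tot <- vapply(rates, sum, numeric(1))
  # reachability: on a chain any absorb state is reachable unless a rate
  # is exactly zero along the way
  if (any(tot[-absorb] == 0))
    stop("absorbing state not reachable: a transient state has no exits")
  with_seed(seed, {
    times <- numeric(n_paths)
    for (p in seq_len(n_paths)) {
      s <- start
      t <- 0
      while (!(s %in% absorb)) {
        t <- t + stats::rexp(1, tot[s])
        s <- sample.int(n, 1L, prob = rates[[s]])
      }
      times[p] <- t
    }
    list(mfpt = mean(times), se = stats::sd(times) / sqrt(n_paths),
         n_paths = n_paths)
  })
}
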