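# Independent oracles used across test files. These re-derive expected
# values by routes separate from the package implementation.

# Arrhenius expression evaluated directly (not via package helpers).
oracle_gamma_star <- function(T_leaf) {
  T_K <- T_leaf + 273.15
  42.75 * exp(37830 * (T_K - 298.15) / (298.15 * 8.314 * T_K))
}

# Forward steady state on the RuBP-limited branch via stats::uniroot,
# independent of the package bisection.
oracle_steady_state_rubp <- function(g_sc, g_m, J, R_d, gamma_star, C_a) {
  r_tot <- 1 / g_sc + 1 / g_m
  a_j <- function(C_c) J * (C_c - gamma_star) / (4 * C_c + 8 * gamma_star) - R_d
  f <- function(C_c) C_a - a_j(C_c) * r_tot - C_c
  C_c <- stats::uniroot(f, c(gamma_star + 1e-9, C_a), tol = 1e-12)$root
  A <- a_j(C_c)
  list(A_N = A, C_i = C_a - A / g_sc, C_c = C_c)
}

# Noise-free gas-exchange record for a leaf with known parameters,
# constructed without the package generator (fluorescence back-computed
# from the defining product formula).
oracle_gasex_record <- function(g_sc, g_m, J, R_d, T_leaf = 30, C_a = 400,
                                PPFD = 1800, leaf_id = "L1",
                                treatment = "C", day = 0) {
  gs <- oracle_gamma_star(T_leaf)
  ss <- oracle_steady_state_rubp(g_sc, g_m, J, R_d, gs, C_a)
  phi <- J / (PPFD * 0.5 * 0.93)
  tibble::tibble(
    leaf_id = leaf_id, treatment = treatment, day = day,
    A_N = ss$A_N, g_sw = g_sc * 1.6, C_i = ss$C_i, PPFD = PPFD,
    T_leaf = T_leaf, F_s = 2000 * (1 - phi), F_m_prime = 2000, R_d = R_d)
}

# Exhaustive count of non-adjacent vertex pairs (basis-set size oracle).
oracle_nonadjacent_pairs <- function(vertices, edges) {
  count <- 0L
  for (i in seq_along(vertices)) {
    for (j in seq_along(vertices)) {
      if (j <= i) next
      x <- vertices[i]; y <- vertices[j]
      adj <- any((edges$from == x & edges$to == y) |
                   (edges$from == y & edges$to == x))
      if (!adj) count <- count + 1L
    }
  }
  count
}

# Random DAG: orient edges of a random undirected graph along a random
# vertex permutation (always acyclic by construction).
random_dag <- function(n_vertices, p_edge = 0.4) {
  v <- paste0("V", seq_len(n_vertices))
  perm <- sample(v)
  from <- character(); to <- character()
  for (i in seq_len(n_vertices - 1)) {
    for (j in seq(i + 1, n_vertices)) {
      if (stats::runif(1) < p_edge) {
        from <- c(from, perm[i]); to <- c(to, perm[j])
      }
    }
  }
  causal_model(paste0("random", n_vertices), v,
               tibble::tibble(from = from, to = to))
}

# Partial correlation via explicit least-squares residuals (lm), the
# textbook construction, independent of the covariance-inverse route.
oracle_partial_cor_residuals <- function(data, x, y, cond) {
  if (length(cond) == 0) return(stats::cor(data[[x]], data[[y]]))
  fx <- stats::lm(stats::reformulate(cond, x), data = data)
  fy <- stats::lm(stats::reformulate(cond, y), data = data)
  stats::cor(stats::residuals(fx), stats::residuals(fy))
}
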