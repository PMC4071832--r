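test_that("DAG validation accepts chains and rejects cycles and unknowns", {
  chain <- causal_model("chain", c("X", "Y", "Z"),
                        list(c("X", "Y"), c("Y", "Z")))
  expect_s3_class(chain, "causal_model")

  expect_error(causal_model("loop", c("X", "Y"),
                            list(c("X", "Y"), c("Y", "X"))),
               class = "photolim_cyclic_model")
  expect_error(causal_model("bad", c("X", "Y"), list(c("X", "W"))),
               class = "photolim_invalid_model")
  expect_error(causal_model("dup", c("X", "X"), list()),
               class = "photolim_invalid_model")

  # the literal physiological wiring with a CA -> gm feedback closes a
  # directed cycle gm -> AN -> CA -> gm and must be refused
  expect_error(
    causal_model("model3_literal",
                 c("PIP1", "PIP2", "gs", "gm", "AN", "CA"),
                 list(c("PIP1", "PIP2"), c("PIP1", "gs"), c("PIP2", "gs"),
                      c("PIP2", "gm"), c("gs", "AN"), c("gm", "AN"),
                      c("AN", "CA"), c("CA", "gm"))),
    class = "photolim_cyclic_model")
})

test_that("basis set enumerates one claim per non-adjacent pair", {
  chain <- causal_model("chain", c("X", "Y", "Z"),
                        list(c("X", "Y"), c("Y", "Z")))
  bs <- basis_set(chain)
  expect_equal(nrow(bs), 1)
  expect_equal(c(bs$x, bs$y), c("X", "Z"))
  expect_equal(bs$conditioning_set[[1]], "Y")

  complete3 <- causal_model("complete", c("A", "B", "C"),
                            list(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_equal(nrow(basis_set(complete3)), 0)

  fixture <- model3_acyclic()
  bs3 <- basis_set(fixture)
  expect_equal(nrow(bs3), 8) # C(6,2) - 7 edges
  expect_equal(nrow(bs3),
               oracle_nonadjacent_pairs(fixture$vertices, fixture$edges))
  # claims condition on the union of both parents' sets
  pip1_ca <- bs3[bs3$x == "CA" | bs3$y == "CA", ]
  expect_true(all(vapply(pip1_ca$conditioning_set,
                         function(s) "AN" %in% s, TRUE)))
})

test_that("basis-set size equals pairs minus edges on random DAGs", {
  set.seed(51)
  for (i in 1:25) {
    m <- random_dag(sample(4:8, 1), p_edge = runif(1, 0.2, 0.7))
    v <- length(m$vertices); e <- nrow(m$edges)
    expect_equal(nrow(basis_set(m)), choose(v, 2) - e)
    expect_equal(nrow(basis_set(m)),
                 oracle_nonadjacent_pairs(m$vertices, m$edges))
  }
})

test_that("partial correlation matches the residual-regression construction", {
  set.seed(61)
  n <- 300
  d <- data.frame(x = rnorm(n))
  d$y <- 0.8 * d$x + rnorm(n)
  d$z <- 0.7 * d$y + rnorm(n)
  d$w <- rnorm(n)

  # empty conditioning set: the ordinary Pearson estimator
  pc0 <- partial_correlation(d, "x", "z", character())
  expect_equal(pc0$r, cor(d$x, d$z), tolerance = 1e-12)
  expect_equal(pc0$p,
               2 * pnorm(-abs(atanh(pc0$r) * sqrt(n - 3))), tolerance = 1e-12)

  # one- and two-variable conditioning sets against lm residuals
  for (cond in list("y", c("y", "w"))) {
    pc <- partial_correlation(d, "x", "z", cond)
    expect_equal(pc$r, oracle_partial_cor_residuals(d, "x", "z", cond),
                 tolerance = 1e-10)
  }

  # chain independence: x _||_ z | y at large n
  set.seed(62)
  big <- data.frame(x = rnorm(1e4))
  big$y <- 0.8 * big$x + rnorm(1e4)
  big$z <- 0.7 * big$y + rnorm(1e4)
  expect_lt(abs(partial_correlation(big, "x", "z", "y")$r), 0.05)

  d$x2 <- 2 * d$x
  expect_error(partial_correlation(d, "x", "z", "x2"),
               class = "photolim_zero_variance")
  expect_error(partial_correlation(d[1:4, ], "x", "z", "y"),
               class = "photolim_insufficient_data")
  d$const <- 1
  expect_error(partial_correlation(d, "x", "const", character()),
               class = "photolim_zero_variance")
})

test_that("Fisher's C combines p-values with the closed form", {
  expect_equal(fishers_c(c(1, 1, 1)), 0)
  expect_equal(fishers_c(c(0.5, 0.5)), -4 * log(0.5)) # 2.7726
  # monotone decreasing in each p
  expect_gt(fishers_c(c(0.1, 0.5)), fishers_c(c(0.2, 0.5)))
  expect_warning(fishers_c(c(0, 0.5)), "floored")
  expect_error(fishers_c(c(0.5, 1.2)), class = "photolim_invalid_input")
})

test_that("model p-value is the chi-squared upper tail", {
  expect_equal(model_pvalue(0, 16), 1)
  # quadrature oracle: integrate the chi-squared density directly
  quad <- function(C, df) {
    1 - stats::integrate(function(t) stats::dchisq(t, df), 0, C,
                         rel.tol = 1e-10)$value
  }
  expect_equal(model_pvalue(22.53, 16), quad(22.53, 16), tolerance = 1e-6)
  expect_equal(model_pvalue(12.92, 22), quad(12.92, 22), tolerance = 1e-6)
  expect_error(model_pvalue(10, 15), class = "photolim_invalid_input")
  expect_error(model_pvalue(-1, 16), class = "photolim_invalid_input")

  # p-value is uniform when the claim p-values are i.i.d. uniform
  set.seed(71)
  P <- replicate(1e4, model_pvalue(fishers_c(runif(4)), 8))
  expect_gt(stats::ks.test(P, "punif")$p.value, 0.01)
})

test_that("model testing combines claims and flags saturated models", {
  m <- model3_acyclic()
  d <- simulate_expression_sem(m, n = 400, seed = 81)
  res <- test_causal_model(m, d)
  expect_equal(res$df, 16)
  expect_equal(nrow(res$claims), 8)
  expect_equal(res$C, fishers_c(res$claims$p), tolerance = 1e-12)
  expect_equal(res$P, model_pvalue(res$C, res$df), tolerance = 1e-12)
  expect_equal(nrow(res$edge_correlations), 7)

  sat <- causal_model("saturated", c("A", "B", "C"),
                      list(c("A", "B"), c("A", "C"), c("B", "C")))
  rsat <- test_causal_model(sat, d[, 1:3] |>
                              stats::setNames(c("A", "B", "C")))
  expect_true(rsat$untestable)
  expect_equal(rsat$P, 1)
  expect_equal(rsat$df, 0)
})

test_that("a strong violating path is detected and the true model ranks first", {
  m <- model3_acyclic()
  gen <- causal_model("gen", m$vertices,
                      rbind(as.data.frame(m$edges),
                            data.frame(from = "PIP1", to = "CA")))
  co <- c(default_sem_coefficients(), "PIP1->CA" = 0.6)
  set.seed(91)
  rejected <- 0L; true_first <- 0L
  for (i in 1:40) {
    d_true <- simulate_expression_sem(m, n = 200)
    d_bad <- simulate_expression_sem(gen, n = 200, coefficients = co)
    if (test_causal_model(m, d_bad)$P < 0.05) rejected <- rejected + 1L
    cmp <- compare_causal_models(list(m, gen), d_true)
    if (cmp$model[1] == "model3_acyclic") true_first <- true_first + 1L
  }
  expect_gt(rejected / 40, 0.9)
  expect_gt(true_first / 40, 0.7)
})

test_that("model comparison ranks by P with edge-count tie-breaking", {
  m <- model3_acyclic()
  d <- simulate_expression_sem(m, n = 300, seed = 95)
  dup <- compare_causal_models(list(m, m), d)
  expect_equal(dup$P[1], dup$P[2])
  expect_equal(dup$C[1], dup$C[2])
  one <- compare_causal_models(list(m), d)
  expect_equal(nrow(one), 1)
  expect_equal(one$rank, 1)
})
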