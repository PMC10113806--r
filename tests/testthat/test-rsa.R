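# Theoretical RDMs, cross-run empirical RDMs, diagnostics, model correlations
# and the sub-RDM regression.

test_that("the eight theoretical RDMs are well-formed", {
  models <- theoretical_rdms()
  expect_length(models, 8)
  expect_named(models, LETTERS[1:8])
  for (m in models) {
    mat <- rdm_matrix(m)
    expect_equal(dim(mat), c(12, 12))
    expect_equal(mat, t(mat))
    expect_equal(rdm_mask(m), t(rdm_mask(m)))
    expect_true(all(diag(rdm_mask(m))))
  }
  # the task and variance-structure models predict every off-diagonal entry
  expect_equal(sum(rdm_mask(models$A)), 12)
  expect_equal(sum(rdm_mask(models$B)), 12)
  # detection-only models are defined exactly on the detection block
  expect_equal(sum(!rdm_mask(models$C)), 4 * 4 - 4)
})

test_that("G equals 1 - C on mutually defined entries (Spearman -1)", {
  models <- theoretical_rdms()
  C <- models$C; G <- models$G
  ok <- upper.tri(rdm_matrix(C)) & !rdm_mask(C) & !rdm_mask(G)
  expect_gte(sum(ok), 3)
  expect_equal(rdm_matrix(G)[ok], 1 - rdm_matrix(C)[ok])
  expect_equal(cor(rdm_matrix(G)[ok], rdm_matrix(C)[ok], method = "spearman"),
               -1)
})

test_that("empirical_rdm equals hand-computed cross-run Euclidean means", {
  # 2 runs x 2 conditions x 3 voxels, hand-set patterns
  pat <- array(0, dim = c(2, 2, 3),
               dimnames = list(c("run1", "run2"), c("c1", "c2"), NULL))
  pat[1, 1, ] <- c(0, 0, 0); pat[1, 2, ] <- c(3, 0, 0)
  pat[2, 1, ] <- c(0, 4, 0); pat[2, 2, ] <- c(0, 0, 12)
  er <- rdm_matrix(empirical_rdm(pat))
  d <- function(a, b) sqrt(sum((a - b)^2))
  # entry (1,2): mean of d(c1 run1, c2 run2) and d(c1 run2, c2 run1)
  expect_equal(er[1, 2],
               mean(c(d(pat[1, 1, ], pat[2, 2, ]), d(pat[2, 1, ], pat[1, 2, ]))))
  expect_equal(er[1, 1], d(pat[1, 1, ], pat[2, 1, ]))  # cross-run self-distance
  expect_equal(er[2, 2], d(pat[1, 2, ], pat[2, 2, ]))
  expect_lt(max(abs(er - t(er))), 1e-12)

  same <- array(1, dim = c(3, 4, 5))
  expect_true(all(rdm_matrix(empirical_rdm(same)) == 0))
  pat[2, 2, 1] <- NA
  expect_error(empirical_rdm(pat), "missing condition")
})

test_that("empirical_rdm is invariant to run relabelling and voxel permutation", {
  set.seed(8)
  pat <- simulate_patterns(runs = 4, generating_rdm = theoretical_rdms()$B,
                           pattern_noise_sd = 1, voxels = 30, seed = 8)
  base <- rdm_matrix(empirical_rdm(pat))
  expect_equal(rdm_matrix(empirical_rdm(pat[c(3, 1, 4, 2), , ])), base,
               tolerance = 1e-12)
  expect_equal(rdm_matrix(empirical_rdm(pat[, , sample(30)])), base,
               tolerance = 1e-12)
})

test_that("model correlations respect monotone transforms, sign, and ties", {
  models <- theoretical_rdms()
  E <- models$E
  emp_mat <- exp(2 * rdm_matrix(E))  # strictly monotone transform
  emp <- rdm(emp_mat, kind = "empirical", labels = rsa_conditions())
  expect_equal(unname(model_correlations(emp, E)), 1)
  neg <- rdm(max(emp_mat) - emp_mat + 1, kind = "empirical",
             labels = rsa_conditions())
  expect_equal(unname(model_correlations(neg, E)), -1)

  # toy 4-condition check against a brute-force rank correlation
  m_mod <- matrix(c(0, 1, 2, 3,
                    1, 0, 1, 2,
                    2, 1, 0, 1,
                    3, 2, 1, 0), 4, 4)
  set.seed(5)
  m_emp <- matrix(0, 4, 4)
  m_emp[upper.tri(m_emp)] <- runif(6)
  m_emp <- m_emp + t(m_emp)
  got <- model_correlations(rdm(m_emp, kind = "empirical"),
                            rdm(m_mod, kind = "theoretical"))
  ut <- upper.tri(m_mod)
  oracle <- cor(rank(m_emp[ut]), rank(m_mod[ut]))
  expect_equal(unname(got), oracle, tolerance = 1e-12)
})

test_that("masked entries never influence correlations or regressions", {
  set.seed(9)
  pat <- simulate_patterns(runs = 3, generating_rdm = theoretical_rdms()$E,
                           pattern_noise_sd = 1, seed = 9)
  emp <- empirical_rdm(pat)
  models <- theoretical_rdms()
  base_corr <- model_correlations(emp, models)
  base_reg <- subrdm_regression(emp)$betas

  # perturb every masked entry of model G wildly
  G2 <- models$G
  G2$mat[G2$mask] <- 99
  expect_equal(unname(model_correlations(emp, list(G = G2))["G"]),
               unname(base_corr["G"]))

  # perturb empirical entries outside the confidence-model domain
  dom <- subrdm_set()$domain
  emp2 <- emp
  emp2$mat[!dom & row(emp2$mat) != col(emp2$mat)] <- 1e6
  expect_equal(subrdm_regression(emp2)$betas, base_reg, tolerance = 1e-10)
})

test_that("sub-RDM set spans the confidence model with disjoint supports", {
  srs <- subrdm_set()
  expect_length(srs$predictors, 18)
  expect_equal(sum(srs$cells$kind == "within"), 6)
  expect_equal(sum(srs$cells$kind == "between"), 12)
  total <- Reduce(`+`, srs$predictors)
  E <- theoretical_rdms()$E
  dom_off <- srs$domain & row(total) != col(total)
  expect_equal(total[dom_off], rdm_matrix(E)[dom_off])
  # supports are disjoint: no entry belongs to two sub-RDMs
  overlap <- Reduce(`+`, lapply(srs$predictors, function(m) m > 0))
  expect_true(all(overlap <= 1))
  # every sub-RDM lives inside the model's unmasked domain
  for (m in srs$predictors) expect_true(all(m[!srs$domain] == 0))
})

test_that("sub-RDM regression recovers generating weights and combinations", {
  srs <- subrdm_set()
  labels <- rsa_conditions()
  set.seed(11)
  w_true <- setNames(runif(18, 0.5, 2), names(srs$predictors))
  est <- vapply(1:20, function(s) {
    set.seed(700 + s)
    m <- matrix(0, 12, 12)
    for (nm in names(srs$predictors))
      m <- m + w_true[nm] * srs$predictors[[nm]]
    noise <- matrix(rnorm(144, sd = 0.2), 12, 12)
    m <- m + 3 + noise + t(noise)
    m <- pmax(m, 0)
    subrdm_regression(rdm((m + t(m)) / 2, kind = "empirical",
                          labels = labels), srs)$betas
  }, numeric(18))
  means <- rowMeans(est)
  ses <- apply(est, 1, sd) / sqrt(20)
  expect_true(all(abs(means - w_true) < 4 * ses + 1e-8))

  # combinations are plain averages of the named betas
  one <- subrdm_regression(rdm(Reduce(`+`, srs$predictors) + 1,
                               kind = "empirical", labels = labels), srs)
  expect_equal(unname(one$combinations["det_tilt_response_specific"]),
               mean(one$betas[c("detection_yes__tilt_tilted",
                                "detection_no__tilt_vertical")]))
  expect_equal(unname(one$combinations["tilt_disc_response_invariant"]),
               mean(one$betas[grep("^discrimination_.*__tilt_",
                                   names(one$betas))]))
})

test_that("confidence splits label trials into the 12 conditions", {
  tr <- small_trials()
  lab <- confidence_split(tr)
  usable <- !tr$missed & !tr$excluded
  expect_true(all(is.na(lab[!usable])))
  expect_true(all(lab[usable] %in% rsa_conditions()))
  # per-response median: ratings <= the cell median go to "low"
  cell <- paste(tr$task, tr$response, sep = "_")
  for (cl in unique(cell[usable])) {
    sel <- usable & cell == cl
    med <- median(tr$confidence[sel])
    expect_true(all((tr$confidence[sel] <= med) ==
                      grepl("_low$", lab[sel])))
  }
  # response-invariant cutoff ignores the response-specific medians
  lab2 <- confidence_split(tr, mode = "response_invariant", cutoff = 3)
  expect_true(all((tr$confidence[usable] <= 3) == grepl("_low$", lab2[usable])))
})

test_that("diagnostics separate structure from noise and bound models", {
  models <- theoretical_rdms()
  # identical subjects: noise ceiling is exactly 1
  pat <- simulate_patterns(runs = 3, generating_rdm = models$E,
                           pattern_noise_sd = 1, seed = 3)
  er <- empirical_rdm(pat)
  diag_same <- rdm_diagnostics(list(er, er, er))
  expect_equal(diag_same$noise_ceiling_lower, 1)

  # structured patterns: off-diagonal ranks exceed diagonal ranks
  # (majority over seeds)
  wins <- vapply(1:20, function(s) {
    p <- simulate_patterns(runs = 3, generating_rdm = models$B,
                           pattern_noise_sd = 1, seed = 800 + s)
    d <- rdm_matrix(empirical_rdm(p))
    idx <- which(upper.tri(d, diag = TRUE))
    rk <- rank(d[idx]); on <- (row(d) == col(d))[idx]
    mean(rk[!on]) > mean(rk[on])
  }, logical(1))
  expect_gt(mean(wins), 0.5)

  # condition-permuted subjects share no structure: ceiling near zero
  set.seed(12)
  perm_rdms <- lapply(1:12, function(s) {
    p <- simulate_patterns(runs = 3, generating_rdm = models$B,
                           pattern_noise_sd = 1, seed = 900 + s)
    m <- rdm_matrix(empirical_rdm(p))
    pi <- sample(12)
    rdm(m[pi, pi], kind = "empirical", labels = rsa_conditions())
  })
  expect_lt(abs(rdm_diagnostics(perm_rdms)$noise_ceiling_lower), 0.25)
})
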