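test_that("simulation is deterministic given the seed", {
  a <- simulate_community(community_config(seed = 3, n_generations = 4))
  b <- simulate_community(community_config(seed = 3, n_generations = 4))
  expect_identical(a$pedigree$ind, b$pedigree$ind)
  expect_identical(a$unions, b$unions)
  c <- simulate_community(community_config(seed = 4, n_generations = 4))
  expect_false(identical(a$pedigree$ind, c$pedigree$ind))
})

test_that("config validation rejects bad inputs", {
  expect_error(community_config(p_levirate = 1.5), "probabilities")
  expect_error(community_config(n_generations = 0), "n_generations")
  expect_error(community_config(mortality_table = c("inf I" = 1)),
               "age categories")
  bad_mort <- DEFAULT <- community_config()$mortality_table
  bad_mort[1] <- bad_mort[1] + 0.1
  expect_error(community_config(mortality_table = bad_mort), "sum to 1")
  expect_error(community_config(founder_ancestry = c(EastAsian = 0.5,
                                                     European = 0.1,
                                                     Steppe = 0.1)),
               "sum to 1")
})

test_that("population collapse yields an extinction signal, not a crash", {
  com <- simulate_community(community_config(
    seed = 1, founder_couples = 1, fertility_mean = 0.2))
  expect_true(com$extinct)
  expect_lt(com$generations_completed, 6)
})

test_that("forced exogamy leaves every mother without on-site ancestors", {
  com <- simulate_nonextinct(list(p_daughter_leaves = 1, p_local_union = 0,
                                  n_generations = 4), seed = 40)
  exo <- exogamy_stats(com$pedigree)
  expect_gt(exo$mothers_total, 0)
  expect_equal(exo$fraction, 1)
})

test_that("disabling polygyny, levirate and local unions gives only single unions", {
  com <- simulate_nonextinct(list(p_polygyny = 0, p_levirate = 0,
                                  p_local_union = 0, n_generations = 4),
                             seed = 50)
  expect_true(all(com$unions$type == "primary"))
  un <- enumerate_unions(com$pedigree)
  expect_equal(un$summary$n_multi, 0L)
  expect_equal(un$summary$ratio_label, "all single")
})

test_that("uniparental markers propagate without violation in simulated pedigrees", {
  for (s in 61:63) {
    com <- simulate_community(community_config(seed = s, n_generations = 4))
    expect_length(validate_pedigree(com$pedigree), 0)
  }
})

test_that("male-line ancestry converges to the bride pool geometrically", {
  # with founder males at a0 and all brides at ab, expected male ancestry
  # at generation g is ab + (a0 - ab) * 2^-(g-1)
  a0 <- c(EastAsian = 1, European = 0, Steppe = 0)
  ab <- c(EastAsian = 0.6, European = 0.3, Steppe = 0.1)
  reps <- lapply(71:78, function(s) {
    simulate_community(community_config(
      seed = s, n_generations = 5, founder_couples = 6,
      p_daughter_leaves = 1, p_local_union = 0,
      founder_ancestry = a0, bride_ancestry = ab))
  })
  for (g in 2:4) {
    vals <- unlist(lapply(reps, function(com) {
      ind <- com$pedigree$ind
      sel <- ind$sex == "male" & ind$generation == g & !is.na(ind$father)
      ind$anc_EastAsian[sel]
    }))
    expected <- ab[["EastAsian"]] + (a0[["EastAsian"]] - ab[["EastAsian"]]) *
      2^-(g - 1)
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - expected), 3 * se + 1e-9,
              label = sprintf("generation %d ancestry", g))
  }
})

test_that("dominant founder Y lineage stays dominant among males", {
  shares <- vapply(81:90, function(s) {
    com <- simulate_community(community_config(seed = s))
    if (com$extinct) return(NA_real_)
    ind <- com$pedigree$ind
    males <- ind[ind$sex == "male" & ind$sampled, ]
    mean(males$y_hap == "Y-C2b")
  }, numeric(1))
  expect_gt(mean(shares, na.rm = TRUE), 0.6)
})

test_that("observation layer: zero noise reproduces truth, noise rate calibrates", {
  obs <- std_observed()
  expect_identical(obs$degrees$degree, obs$truth$degree)

  # drop_unsampled with full sampling keeps everybody
  com <- std_community()
  expect_setequal(obs$metadata$id,
                  com$pedigree$ind$id[com$pedigree$ind$sampled])

  # invalid confusion matrices are rejected
  M <- degree_confusion_matrix(0.05)
  expect_equal(rowSums(M), rep(1, 8), ignore_attr = TRUE)
  bad <- M; bad[1, 1] <- 0.5
  expect_error(observe(com, degree_noise = bad), "sum to 1")
  nonadj <- degree_confusion_matrix(0)
  nonadj[1, 1] <- 0.9; nonadj[1, 4] <- 0.1
  expect_error(observe(com, degree_noise = nonadj), "adjacent")

  # 5% adjacent-swap noise perturbs ~5% of records
  noisy <- observe(com, degree_noise = 0.05, include_ibd = FALSE, seed = 9)
  frac <- mean(noisy$degrees$degree != noisy$truth$degree)
  expect_gt(nrow(noisy$degrees), 1000)
  expect_lt(abs(frac - 0.05), 0.01)
  # and only to adjacent degrees
  dn <- degree_numeric(noisy$degrees$degree)
  tn <- degree_numeric(noisy$truth$degree)
  expect_true(all(abs(dn - tn) <= 1))
})

test_that("levirate truth events involve a relative of the deceased", {
  com <- simulate_nonextinct(list(p_levirate = 0.5), seed = 95)
  lev <- com$levirates
  expect_gt(nrow(lev), 0)
  K <- kinship_matrix(com$pedigree)
  ind <- com$pedigree$ind
  for (k in seq_len(nrow(lev))) {
    related <- K[lev$partner[k], lev$deceased[k]] >= 1 / 8
    step <- identical(ind$father[match(lev$partner[k], ind$id)],
                      lev$deceased[k])
    expect_true(related || step)
    # widow and new partner are never kin (consanguinity avoidance)
    expect_equal(K[lev$partner[k], lev$widow[k]], 0)
  }
})
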