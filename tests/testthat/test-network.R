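synth_metadata <- function(n, sites = "S1", status_frac = 0.3, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("N%03d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    site = sample(rep(sites, length.out = n)),
    status_items = ifelse(runif(n) < status_frac,
                          sample(c("belt_set", "coat_clasp"), n, replace = TRUE),
                          NA_character_),
    stringsAsFactors = FALSE)
}

# plant a Bernoulli tie network with given log-odds terms
plant_network <- function(meta, beta, seed = 1) {
  net <- build_binary_network(kinweave:::empty_ibd_records(), meta)
  X <- cbind(1, net$sex_pairing == "FM", net$sex_pairing == "MM",
             net$status_count == 1, net$status_count == 2)
  eta <- drop(X %*% beta)
  set.seed(seed)
  net$tie <- runif(nrow(net)) < plogis(eta)
  net
}

test_that("dyad universe is complete with explicit zeros and logged exclusions", {
  meta <- synth_metadata(10)
  net <- build_binary_network(kinweave:::empty_ibd_records(), meta)
  expect_equal(nrow(net), choose(10, 2))
  expect_false(any(net$tie))
  expect_true(all(net$same_site))

  meta$sex[1] <- "unknown"
  net2 <- build_binary_network(kinweave:::empty_ibd_records(), meta)
  expect_equal(nrow(net2), choose(10, 2) - 9)
  expect_equal(attr(net2, "n_excluded"), 9L)
})

test_that("tie rules: long-segment count versus segment-length threshold", {
  meta <- synth_metadata(4)
  ibd <- ibd_record(c("N001", "N001", "N002"), c("N002", "N003", "N003"),
                    total_cM = c(300, 120, 40),
                    n_segments = c(12L, 6L, 2L),
                    n_segments_gt20 = c(4L, 2L, 0L),
                    longest_cM = c(45, 25, 15))
  cfg <- analysis_config()
  long <- build_binary_network(ibd, meta, rule = "long_segments", config = cfg)
  expect_equal(sum(long$tie), 1L)  # only the pair with > 2 long segments
  sumr <- build_binary_network(ibd, meta, rule = "sum_threshold", config = cfg)
  expect_equal(sum(sumr$tie), 2L)  # any segment above 16 cM
  # a threshold above every segment empties the network
  cfg2 <- analysis_config(network_segment_cM = 100)
  expect_equal(sum(build_binary_network(ibd, meta, rule = "sum_threshold",
                                        config = cfg2)$tie), 0L)
})

test_that("degree-1 simulated pairs are tied under both rules at zero noise", {
  com <- std_community()
  obs <- std_observed()
  d1 <- obs$degrees[obs$degrees$degree == "1", ]
  cfg <- analysis_config()
  for (rule in c("long_segments", "sum_threshold")) {
    net <- build_binary_network(obs$ibd, obs$metadata, rule = rule,
                                config = cfg)
    key <- paste(net$id_a, net$id_b)
    tied <- net$tie[match(paste(d1$id_a, d1$id_b), key)]
    expect_gte(mean(tied, na.rm = TRUE), 0.99)
  }
})

test_that("intercept-only fit equals the observed density odds", {
  meta <- synth_metadata(40)
  net <- plant_network(meta, c(-1, 0, 0, 0, 0), seed = 2)
  fit <- fit_dyadic_ergm(net, terms = character(0))
  dens <- mean(net$tie)
  expect_equal(fit$coefficients$fold[1], dens / (1 - dens), tolerance = 1e-6)
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
})

test_that("single-covariate fold equals the 2x2 odds ratio in closed form", {
  meta <- synth_metadata(60, status_frac = 0)
  net <- plant_network(meta, c(-1.5, 0, log(2.2), 0, 0), seed = 3)
  net$mm <- net$sex_pairing == "MM"
  fit <- fit_dyadic_ergm(net, terms = "mm")
  tab <- table(net$mm, net$tie)
  or <- (tab["TRUE", "TRUE"] / tab["TRUE", "FALSE"]) /
    (tab["FALSE", "TRUE"] / tab["FALSE", "FALSE"])
  expect_equal(fit$coefficients$fold[fit$coefficients$term == "mm"], or,
               tolerance = 1e-6)
})

test_that("the dyadic fit agrees with independent maximisers", {
  meta <- synth_metadata(20)
  net <- plant_network(meta, c(-0.8, log(1.4), log(2.5), 0, 0), seed = 4)
  fit <- fit_dyadic_ergm(net, terms = "sex_pairing")

  # independent route 1: generic optimiser on the Bernoulli likelihood
  X <- cbind(1, net$sex_pairing == "FM", net$sex_pairing == "MM")
  y <- as.numeric(net$tie)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(fit$coefficients$estimate, opt$par, tolerance = 1e-4)

  # independent route 2: glm as the established reference
  ref <- glm(y ~ X - 1, family = binomial())
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)

  # duplicating every dyad leaves the coefficients unchanged
  fit2 <- fit_dyadic_ergm(rbind(net, net), terms = "sex_pairing")
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("separation and aliased terms are flagged, not crashed", {
  meta <- synth_metadata(12)
  net <- build_binary_network(kinweave:::empty_ibd_records(), meta)
  net$tie <- net$sex_pairing == "MM"  # perfectly predictive level
  expect_warning(fit <- fit_dyadic_ergm(net, terms = "sex_pairing"),
                 "separation")
  expect_true(fit$separation)
  net$dup <- as.numeric(net$sex_pairing == "MM")
  net$tie <- seq_len(nrow(net)) %% 3 == 0
  fit2 <- fit_dyadic_ergm(net, terms = c("sex_pairing", "dup"))
  expect_true("dup" %in% fit2$dropped ||
                any(grepl("sex_pairing", fit2$dropped)))
})

test_that("model selection minimises AIC with ties broken to fewer terms", {
  meta <- synth_metadata(50)
  net <- plant_network(meta, c(-1, log(1.4), log(2.5), 0, 0), seed = 5)
  best <- select_model(net, candidates = list(
    "sex_pairing", "status_count", c("sex_pairing", "status_count")))
  tab <- attr(best, "aic_table")
  expect_equal(best$aic, min(tab$aic))
  single <- select_model(net, candidates = list("sex_pairing"))
  expect_equal(single$coefficients,
               fit_dyadic_ergm(net, "sex_pairing")$coefficients)
})

test_that("site network weights average cross-site sharing and respect labels", {
  meta <- synth_metadata(12, sites = c("A", "B", "C"))
  # no cross-site sharing at all
  sn0 <- build_site_network(kinweave:::empty_ibd_records(), meta)
  expect_true(all(sn0$W == 0))
  # increasing cross-site sharing raises the corresponding weight
  a_ids <- meta$id[meta$site == "A"]
  b_ids <- meta$id[meta$site == "B"]
  mk_ibd <- function(total) {
    ibd_record(a_ids[1:2], b_ids[1:2], total_cM = total,
               n_segments = 2L, n_segments_gt20 = 1L, longest_cM = total / 2)
  }
  w <- vapply(c(0, 50, 200), function(tt) {
    build_site_network(mk_ibd(rep(tt, 2)), meta)$W["A", "B"]
  }, numeric(1))
  expect_true(all(diff(w) > 0))
  # relabelling sites permutes the matrix consistently
  meta2 <- meta
  meta2$site <- c(A = "Z", B = "B", C = "C")[meta$site]
  sn1 <- build_site_network(mk_ibd(c(100, 100)), meta)
  sn2 <- build_site_network(mk_ibd(c(100, 100)), meta2)
  expect_equal(sn2$W["Z", "B"], sn1$W["A", "B"])
})

test_that("QAP test is calibrated, maximal on self-covariate and exact for tiny n", {
  set.seed(6)
  n <- 6
  W <- matrix(runif(n * n), n); W <- W + t(W); diag(W) <- 0
  # the covariate equal to the weights is maximally significant
  res <- site_covariate_test(W, W, n_permutations = 199, seed = 1)
  expect_equal(res$p_value, 1 / 200)
  # constant covariate: explicit null result
  res0 <- site_covariate_test(W, matrix(1, n, n), n_permutations = 99)
  expect_null(res0$statistic)
  expect_equal(res0$note, "constant covariate")

  # the observed statistic matches the established Mantel implementation
  set.seed(66)
  C2 <- matrix(runif(n * n), n); C2 <- C2 + t(C2); diag(C2) <- 0
  res2 <- site_covariate_test(W, C2, n_permutations = 99, seed = 3)
  ref <- suppressWarnings(vegan::mantel(as.dist(W), as.dist(C2),
                                        permutations = 99))
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-12)

  # exact enumeration oracle at n = 4: compare against all 24 relabellings
  n <- 4
  set.seed(7)
  W4 <- matrix(runif(16), 4); W4 <- W4 + t(W4); diag(W4) <- 0
  C4 <- matrix(runif(16), 4); C4 <- C4 + t(C4); diag(C4) <- 0
  perms <- rbind(1:4)
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  lw <- W4[lower.tri(W4)]
  r_obs <- cor(lw, C4[lower.tri(C4)])
  r_all <- apply(perms, 1, function(p) {
    Cp <- C4[p, p]; cor(lw, Cp[lower.tri(Cp)])
  })
  p_exact <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  res4 <- site_covariate_test(W4, C4, n_permutations = 1999, seed = 2)
  expect_equal(res4$p_value, p_exact, tolerance = 0.05)
})

test_that("between-site rates split by sex pairing and conserve density", {
  meta <- synth_metadata(16, sites = c("A", "B"))
  net <- build_binary_network(kinweave:::empty_ibd_records(), meta)
  set.seed(8)
  net$tie <- runif(nrow(net)) < 0.2
  tab <- sexed_between_site_summary(net)
  expect_equal(nrow(tab), 6L)
  expect_equal(sum(tab$n_dyads), nrow(net))
  expect_equal(sum(tab$n_ties) / sum(tab$n_dyads), mean(net$tie))
  # all ties within-site leaves the between rates at zero
  net$tie <- net$tie & net$same_site
  tab2 <- sexed_between_site_summary(net)
  btw <- tab2[tab2$scope == "between", ]
  expect_true(all(btw$n_ties == 0))
})

test_that("female exogamy drives between-site female connectivity", {
  # construct a two-community dataset: brides moved between sites, so
  # female-involving cross-site pairs carry the IBD links
  meta <- synth_metadata(24, sites = c("A", "B"), seed = 9)
  fa <- meta$id[meta$sex == "female" & meta$site == "A"]
  mb <- meta$id[meta$sex == "male" & meta$site == "B"]
  fb <- meta$id[meta$sex == "female" & meta$site == "B"]
  ibd <- ibd_record(
    c(fa[1:3], fa[1]), c(mb[1:3], fb[1]),
    total_cM = 200, n_segments = 8L, n_segments_gt20 = 4L, longest_cM = 40)
  net <- build_binary_network(ibd, meta)
  tab <- sexed_between_site_summary(net)
  btw <- tab[tab$scope == "between", ]
  rate_f <- sum(btw$n_ties[btw$sex_pairing %in% c("FF", "FM")]) /
    sum(btw$n_dyads[btw$sex_pairing %in% c("FF", "FM")])
  rate_mm <- btw$n_ties[btw$sex_pairing == "MM"] /
    btw$n_dyads[btw$sex_pairing == "MM"]
  expect_gt(rate_f, rate_mm)
})
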