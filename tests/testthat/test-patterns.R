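test_that("demographic profile conserves headcount and keeps unknowns explicit", {
  com <- std_community()
  prof <- demographic_profile(com$pedigree)
  expect_equal(sum(prof), sum(com$pedigree$ind$sampled))
  # planted unknown age category lands in the explicit column
  ped <- com$pedigree
  ped$ind$age_category[match(ped$ind$id[ped$ind$sampled][1], ped$ind$id)] <- NA
  prof2 <- demographic_profile(ped)
  expect_equal(sum(prof2[, "unknown", ]), 1)
  expect_equal(sum(prof2), sum(ped$ind$sampled))
})

test_that("union enumeration flags multi-reproductive parents and half-unions", {
  ped <- pedigree(data.frame(
    id = c("f", "m1", "m2", "c1", "c2", "h"),
    sex = c("male", "female", "female", "male", "female", "male"),
    father = c(NA, NA, NA, "f", "f", NA),
    mother = c(NA, NA, NA, "m1", "m2", "m1")))
  # h has one known parent -> half-union, excluded from the ratio
  ped$ind$father[ped$ind$id == "h"] <- NA
  un <- enumerate_unions(ped)
  expect_equal(un$summary$n_relations, 2L)
  expect_equal(un$summary$n_multi, 2L)  # both unions share the father
  expect_true(all(un$unions$father_multi))
  expect_false(any(un$unions$mother_multi))
  expect_equal(nrow(un$half_unions), 1L)
  expect_equal(un$half_unions$parent, "m1")
})

test_that("union totals are invariant to row order and relabelling", {
  com <- std_community()
  ped <- com$pedigree
  un1 <- enumerate_unions(ped)$summary
  shuffled <- ped
  set.seed(1)
  shuffled$ind <- shuffled$ind[sample(nrow(shuffled$ind)), ]
  un2 <- enumerate_unions(shuffled)$summary
  expect_equal(un1, un2)
})

test_that("levirate detection requires related partners", {
  # two full brothers sharing a widow: levirate
  ped <- pedigree(data.frame(
    id = c("gf", "gm", "b1", "b2", "w", "k1", "k2"),
    sex = c("male", "female", "male", "male", "female", "male", "female"),
    father = c(NA, NA, "gf", "gf", NA, "b1", "b2"),
    mother = c(NA, NA, "gm", "gm", NA, "w", "w")))
  lev <- detect_levirate(ped)
  expect_equal(lev$n_levirate, 1L)
  expect_true(all(lev$unions$levirate[lev$unions$mother == "w"]))
  expect_false(any(lev$unions$levirate[lev$unions$mother != "w"]))

  # unrelated partners: multi-reproductive but not levirate
  ped2 <- pedigree(data.frame(
    id = c("p1", "p2", "w", "k1", "k2"),
    sex = c("male", "male", "female", "male", "female"),
    father = c(NA, NA, NA, "p1", "p2"),
    mother = c(NA, NA, NA, "w", "w")))
  lev2 <- detect_levirate(ped2)
  expect_equal(lev2$n_levirate, 0L)
  expect_equal(nrow(lev2$mothers), 1L)

  # stepson arrangement: the second partner is the first partner's son
  # by another woman
  ped3 <- pedigree(data.frame(
    id = c("p1", "ow", "son", "w", "k1", "k2"),
    sex = c("male", "female", "male", "female", "male", "female"),
    father = c(NA, NA, "p1", NA, "p1", "son"),
    mother = c(NA, NA, "ow", NA, "w", "w")))
  lev3 <- detect_levirate(ped3)
  expect_equal(lev3$n_levirate, 1L)
})

test_that("lineage classification calls chains and handles shallow pedigrees", {
  chain4 <- pedigree(data.frame(
    id = c("a", "b", "c", "d", "w1", "w2", "w3"),
    sex = c(rep("male", 4), rep("female", 3)),
    father = c(NA, "a", "b", "c", NA, NA, NA),
    mother = c(NA, "w1", "w2", "w3", NA, NA, NA)))
  lin <- classify_lineages(chain4)
  expect_equal(lin$lines$class, "patrilineage")
  expect_equal(lin$lines$span, 3L)  # a, b, c reproduce; d does not

  mchain <- pedigree(data.frame(
    id = c("a", "b", "c", "d", "h1", "h2", "h3"),
    sex = c(rep("female", 4), rep("male", 3)),
    father = c(NA, "h1", "h2", "h3", NA, NA, NA),
    mother = c(NA, "a", "b", "c", NA, NA, NA)))
  expect_equal(classify_lineages(mchain)$lines$class[1], "matrilineage")

  shallow <- pedigree(data.frame(
    id = c("f", "m", "c"), sex = c("male", "female", "male"),
    father = c(NA, NA, "f"), mother = c(NA, NA, "m")))
  lin0 <- classify_lineages(shallow)
  expect_equal(nrow(lin0$lines), 0L)
  expect_null(lin0$proportions)
})

test_that("patrilocal simulations are patrilineage-dominant", {
  wins <- 0L; n <- 0L
  for (s in 141:150) {
    com <- simulate_community(community_config(seed = s, p_son_stays = 0.9))
    if (com$extinct) next
    lin <- classify_lineages(com$pedigree)
    if (is.null(lin$proportions)) next
    n <- n + 1L
    if (lin$proportions[["patrilineage"]] > lin$proportions[["matrilineage"]]) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins / n, 0.95)
})

test_that("exogamy fractions: founder mothers count as ancestor-free", {
  ped <- pedigree(data.frame(
    id = c("f", "m", "c"), sex = c("male", "female", "male"),
    father = c(NA, NA, "f"), mother = c(NA, NA, "m")))
  exo <- exogamy_stats(ped)
  expect_equal(exo$mothers_total, 1L)
  expect_equal(exo$fraction, 1)
  # a sampled maternal grandmother removes the ancestor-free status
  ped2 <- pedigree(data.frame(
    id = c("gm2", "f", "m", "c"), sex = c("female", "male", "female", "male"),
    father = c(NA, NA, NA, "f"), mother = c(NA, NA, "gm2", "m")))
  exo2 <- exogamy_stats(ped2)
  expect_equal(exo2$mothers_without_ancestors, 1L)  # gm2 herself
  expect_equal(exo2$mothers_total, 2L)
})

test_that("juvenile sex ratio uses interval midpoints and flags empty cells", {
  meta <- data.frame(
    id = sprintf("i%02d", 1:30),
    sex = c(rep("male", 15), rep("female", 10), rep("unknown", 5)),
    age_low = 10, age_high = 14, stringsAsFactors = FALSE)
  jsr <- juvenile_sex_ratio(meta)
  expect_equal(jsr$ratio, 1.5)
  expect_equal(jsr$n_unknown_sex, 5L)
  expect_equal(jsr$ratio_label, "1.5:1")
  meta$sex[16:25] <- "male"
  jsr2 <- juvenile_sex_ratio(meta)
  expect_true(jsr2$infinite)
  expect_equal(jsr2$ratio, Inf)
  # equal counts give 1:1
  meta2 <- data.frame(id = c("a", "b"), sex = c("male", "female"),
                      age_low = c(7, 7), age_high = c(17, 17))
  expect_equal(juvenile_sex_ratio(meta2)$ratio, 1)
})

test_that("consanguinity verdicts from pedigree and ROH routes agree", {
  com <- std_community()
  con <- consanguinity_check(com$pedigree)
  expect_equal(con$verdict, "consanguinity absent")
  expect_true(all(con$individuals$F == 0))

  # planted cousin marriage flags the child at F = 1/16
  ped <- pedigree(cousin_marriage_df())
  con2 <- consanguinity_check(ped)
  expect_equal(con2$verdict, "consanguinity present")
  expect_equal(con2$individuals$F[con2$individuals$id == "x"], 1 / 16)

  # genomic route on the same pedigree
  com0 <- structure(list(pedigree = ped), class = "simulated_community")
  set.seed(3)
  flags <- replicate(25, {
    comx <- drop_genomes(com0)
    roh <- data.frame(id = "x",
                      total_roh_cM = sum(extract_roh(comx, "x", 4)$length_cM))
    chk <- consanguinity_check(ped, roh_table = roh)
    chk$individuals$flag_roh[chk$individuals$id == "x"]
  })
  expect_gt(mean(flags), 0.8)
})

test_that("pattern statistics equal simulator truth on zero-noise data", {
  com <- std_community()
  ped <- com$pedigree
  truth_unions <- com$unions[com$unions$n_children > 0, ]
  un <- enumerate_unions(ped)
  expect_equal(un$summary$n_relations, nrow(truth_unions))
  lev <- detect_levirate(ped, un)
  # a levirate is detectable only when both of the widow's unions left
  # children in the pedigree
  detectable <- unique(com$levirates$widow[vapply(com$levirates$widow,
    function(w) sum(truth_unions$mother == w) >= 2, logical(1))])
  expect_setequal(lev$mothers$mother[lev$mothers$levirate], detectable)
  # exogamous brides in truth have no on-site ancestors
  exo <- exogamy_stats(ped)
  ind <- ped$ind
  truth_mothers <- unique(truth_unions$mother)
  truth_mothers <- truth_mothers[ind$sampled[match(truth_mothers, ind$id)]]
  expect_equal(exo$mothers_total, length(truth_mothers))
})
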